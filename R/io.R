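# Readers and writers for every schema the pipeline touches, plus a
# config-driven pipeline runner. All files are plain text: CSV for tabular
# schemas, JSON for dose results, YAML for geometry/physics/rules blocks.

.check_columns <- function(df, req, file) {
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("file '", file, "' missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read / write colony-count CSV
#'
#' Schema: `arm,dose_gy,cells_seeded,colonies,replicate`. Reading an
#' empty-but-headered file yields an empty table, not an error.
#'
#' @param path File path.
#' @return `read_colony_csv`: a validated colony-record data.frame.
#' @export
read_colony_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("arm", "dose_gy", "cells_seeded", "colonies",
                       "replicate"), path)
  if (nrow(df)) validate_colony_records(df)
  df
}

#' @rdname read_colony_csv
#' @param records Colony-record data.frame.
#' @export
write_colony_csv <- function(records, path) {
  validate_colony_records(records)
  utils::write.csv(records[, c("arm", "dose_gy", "cells_seeded", "colonies",
                               "replicate")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write deposition-event CSV
#'
#' Schema: `primary_id,step,kind,x_nm,y_nm,z_nm,energy_ev` with `kind` one
#' of `ionization`, `excitation`, `blob`, `annihilation`. An unknown kind
#' is rejected with the offending line number.
#'
#' @param path File path.
#' @return `read_events_csv`: an event data.frame with `kind` as factor.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("primary_id", "step", "kind", "x_nm", "y_nm", "z_nm",
                       "energy_ev"), path)
  bad <- which(!df$kind %in% .kind_levels)
  if (length(bad))
    stop("file '", path, "': unknown event kind '", df$kind[bad[1]],
         "' at data line ", bad[1], call. = FALSE)
  df$kind <- factor(df$kind, levels = .kind_levels)
  df
}

#' @rdname read_events_csv
#' @param events Event data.frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("primary_id", "step", "kind", "x_nm", "y_nm",
                              "z_nm", "energy_ev")], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a dose result as JSON
#'
#' @param result A `dose_result`.
#' @param path File path.
#' @export
write_dose_result_json <- function(result, path) {
  stopifnot(inherits(result, "dose_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_result_json
#' @export
read_dose_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "dose_result")
}

#' Write / read a damage summary CSV
#'
#' Schema: `species,energy_ev,seed,n_primaries,ssb_count,dsb_count,
#' ssb_per_1e6,dsb_per_1e6,let_kev_um`.
#'
#' @param summary A `damage_summary`.
#' @param path File path.
#' @export
write_damage_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_damage_summary_csv
#' @export
read_damage_summary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("species", "energy_ev", "seed", "n_primaries",
                       "ssb_count", "dsb_count", "ssb_per_1e6",
                       "dsb_per_1e6", "let_kev_um"), path)
  structure(df, class = c("damage_summary", "data.frame"))
}

#' Serialize geometry, physics and scoring blocks to YAML
#'
#' `*_to_yaml` write a YAML block; `*_from_yaml` rebuild the validated
#' object, so configuration round-trips losslessly.
#'
#' @param x The object (`dna_geometry`, `physics_model`, `scoring_rules`
#'   or `radionuclide`).
#' @param path File path.
#' @export
config_to_yaml <- function(x, path) {
  yaml::write_yaml(c(list(.class = class(x)[1]), unclass(x)), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  switch(cls,
    dna_geometry = dna_geometry(x$n_bases, x$total_length, x$outer_diameter,
                                x$base_diameter, x$twist_per_base),
    physics_model = physics_model(x$mfp_energy_ev, x$mfp_nm, x$elastic_ratio,
                                  x$elastic_sigma_deg, x$loss,
                                  x$transport_cutoff_ev, x$blob_sigma_nm,
                                  x$annih_n_ionizations, x$annih_energy_ev,
                                  x$core_annihilation_prob),
    scoring_rules = scoring_rules(x$ssb_threshold_ev,
                                  x$dsb_max_base_separation,
                                  x$dsb_requires_opposite_strands,
                                  x$accumulation),
    radionuclide = radionuclide_from_list(x),
    stop("unknown config class '", cls, "' in ", path, call. = FALSE))
}

#' Run the pipeline from a configuration
#'
#' Executes the stages named in the config in order: `dosimetry`
#' (absorbed dose + dose-rate table), `survival` (LQ fits and, with two
#' arms, RBE), `simulation` (track campaign + damage scoring). Each
#' stage's outputs are written under `out_dir` along with the fully
#' resolved configuration; completed stage outputs survive a later stage
#' failure.
#'
#' @param config A named list (or path to a YAML file) with any of the
#'   blocks `dosimetry` (`nuclide` = `"f18"` or a record list, `a0_mbq`,
#'   `hours`, `volume_ml`), `survival` (`csv`, `reference_arm`,
#'   `test_arm`, `sf_level`), `simulation` (`species`, `energies_ev`,
#'   `n_primaries`, `seeds`, optional `physics`/`geometry`/`rules`
#'   overrides).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config))
    stop("config must be a non-empty list or YAML path", call. = FALSE)
  known <- c("dosimetry", "survival", "simulation")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (!is.null(config$dosimetry)) {
    cc <- config$dosimetry
    nuc <- if (identical(cc$nuclide, "f18") || is.null(cc$nuclide))
      builtin_f18() else radionuclide_from_list(cc$nuclide)
    plan <- irradiation_plan(nuc, A0 = cc$a0_mbq * 1e6,
                             duration = cc$hours * 3600,
                             medium_volume = cc$volume_ml)
    dres <- absorbed_dose(plan)
    write_dose_result_json(dres, file.path(out_dir, "dose_result.json"))
    tt <- seq(0, plan$duration, length.out = 101)
    utils::write.csv(data.frame(t_s = tt,
                                dose_rate_gy_per_s = dose_rate_profile(plan, tt)),
                     file.path(out_dir, "dose_rate_profile.csv"),
                     row.names = FALSE)
    results$dosimetry <- dres
  }

  if (!is.null(config$survival)) {
    cc <- config$survival
    records <- read_colony_csv(cc$csv)
    ref_arm <- cc$reference_arm %||% unique(records$arm)[1]
    ref_fit <- fit_lq(survival_fractions(records, ref_arm))
    out <- list(reference = list(arm = ref_arm, alpha = ref_fit$alpha,
                                 beta = ref_fit$beta,
                                 alpha_beta_ratio = ref_fit$alpha_beta_ratio))
    if (!is.null(cc$test_arm)) {
      test_fit <- fit_lq(survival_fractions(records, cc$test_arm))
      rb <- rbe(ref_fit, test_fit, sf_level = cc$sf_level %||% 0.5)
      out$test <- list(arm = cc$test_arm, alpha = test_fit$alpha,
                       beta = test_fit$beta)
      out$rbe <- unclass(rb)
    }
    jsonlite::write_json(out, file.path(out_dir, "survival_result.json"),
                         auto_unbox = TRUE, digits = NA)
    results$survival <- out
  }

  if (!is.null(config$simulation)) {
    cc <- config$simulation
    geom <- if (is.null(cc$geometry)) dna_geometry() else
      do.call(dna_geometry, cc$geometry)
    model <- if (is.null(cc$physics)) physics_model() else
      do.call(physics_model, cc$physics)
    rules <- if (is.null(cc$rules)) scoring_rules() else
      do.call(scoring_rules, cc$rules)
    camp <- run_campaign(species = cc$species %||% c("electron", "positron"),
                         energies_ev = cc$energies_ev %||% c(250, 500, 1000),
                         n_primaries = cc$n_primaries %||% 1000L,
                         seeds = cc$seeds %||% 1L,
                         model = model, source = source_volume(geom))
    summ <- score_campaign(camp, geom, rules)
    write_damage_summary_csv(summ, file.path(out_dir, "damage_summary.csv"))
    utils::write.csv(aggregate_damage(summ),
                     file.path(out_dir, "damage_aggregate.csv"),
                     row.names = FALSE)
    results$simulation <- summ
  }

  # resolved configuration next to the outputs, for provenance
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(results)
}
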