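# Synthetic inputs with the statistical structure each pipeline stage
# assumes: LQ-distributed clonogenic survival with Poisson colony noise,
# deposition-event streams with known per-volume energy totals, and paired
# two-arm studies with a constructed RBE.

#' Generate a synthetic clonogenic colony-count dataset
#'
#' Colonies at each dose/replicate are drawn as
#' `Poisson(cells_seeded * PE * SF(D))`, truncated at `cells_seeded`, with
#' `SF(D) = exp(-(alpha D + beta D^2))`. Poisson noise is the standard
#' clonogenic model in the regime where colonies are far fewer than seeded
#' cells; a binomial variant is available. Deterministic given `seed`.
#'
#' @param alpha,beta LQ parameters (Gy^-1, Gy^-2).
#' @param doses Dose levels (Gy); must include 0 so the consuming
#'   reduction can normalise to plating efficiency.
#' @param cells_seeded Cells per dish: scalar or one value per dose
#'   (higher seeding at higher doses mirrors assay practice).
#' @param plating_efficiency Fraction of untreated cells forming colonies,
#'   in `(0, 1]`.
#' @param replicates Replicates per dose.
#' @param seed Integer seed.
#' @param arm Arm label for the records.
#' @param noise `"poisson"` (default) or `"binomial"`.
#' @return A colony-record data.frame (see [colony_records()]).
#' @export
make_survival_dataset <- function(alpha, beta, doses = c(0, 2.5, 5, 7.5),
                                  cells_seeded = c(100, 400, 2000, 10000),
                                  plating_efficiency = 0.6,
                                  replicates = 3L, seed = 1L, arm = "xray",
                                  noise = c("poisson", "binomial")) {
  noise <- match.arg(noise)
  if (!0 %in% doses) stop("doses must include the 0 Gy control", call. = FALSE)
  if (plating_efficiency <= 0 || plating_efficiency > 1)
    stop("plating_efficiency must lie in (0, 1]", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("alpha, beta must be >= 0", call. = FALSE)
  cells_seeded <- rep_len(cells_seeded, length(doses))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (i in seq_along(doses)) {
    sf <- exp(-(alpha * doses[i] + beta * doses[i]^2))
    mu <- cells_seeded[i] * plating_efficiency * sf
    for (r in seq_len(replicates)) {
      col <- if (noise == "poisson")
        min(stats::rpois(1, mu), cells_seeded[i])
      else
        stats::rbinom(1, cells_seeded[i], plating_efficiency * sf)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, dose_gy = doses[i], cells_seeded = cells_seeded[i],
        colonies = col, replicate = r)
    }
  }
  out <- do.call(rbind, rows)
  validate_colony_records(out)
  out
}

# save/restore the global RNG state so generators are pure in (spec, seed)
# without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic deposition-event stream
#'
#' Builds a reproducible event stream for scoring tests. Two spatial
#' modes: `"uniform_in_source"` scatters events uniformly in the source
#' cylinder; `"at_volumes"` places events exactly at the centres of the
#' volumes listed in `placements`, giving a stream with fully known
#' per-volume energy totals.
#'
#' @param geom A `dna_geometry`.
#' @param n_primaries Number of primary ids to spread events over.
#' @param events_per_primary Mean of the Poisson number of events per
#'   primary (uniform mode).
#' @param energy_mean_ev Mean of the exponential event energy (uniform
#'   mode).
#' @param spatial `"uniform_in_source"` or `"at_volumes"`.
#' @param placements For `"at_volumes"`: data.frame with columns
#'   `primary_id`, `region`, `strand`, `base_index`, `energy_ev`.
#' @param source A `source_volume` (uniform mode).
#' @param seed Integer seed (uniform mode).
#' @return An event data.frame: `primary_id`, `step`, `kind`, `x_nm`,
#'   `y_nm`, `z_nm`, `energy_ev`.
#' @export
make_event_stream <- function(geom, n_primaries = 100L,
                              events_per_primary = 3,
                              energy_mean_ev = 25,
                              spatial = c("uniform_in_source", "at_volumes"),
                              placements = NULL,
                              source = source_volume(geom), seed = 1L) {
  stopifnot(inherits(geom, "dna_geometry"))
  spatial <- match.arg(spatial)
  if (spatial == "at_volumes") {
    if (is.null(placements))
      stop("at_volumes mode needs a placements data.frame", call. = FALSE)
    xyz <- t(mapply(function(reg, s, b)
      volume_center(geom, reg, s, b),
      as.character(placements$region), placements$strand,
      placements$base_index))
    return(data.frame(primary_id = placements$primary_id,
                      step = seq_len(nrow(placements)),
                      kind = factor("ionization", levels = .kind_levels),
                      x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3],
                      energy_ev = placements$energy_ev))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- stats::rpois(n_primaries, events_per_primary)
  n <- sum(counts)
  pts <- sample_source_points(source, n)
  data.frame(primary_id = rep(seq_len(n_primaries) - 1L, counts),
             step = sequence(counts),
             kind = factor("ionization", levels = .kind_levels),
             x_nm = pts$positions[, 1], y_nm = pts$positions[, 2],
             z_nm = pts$positions[, 3],
             energy_ev = stats::rexp(n, 1 / energy_mean_ev))
}

#' Construct a two-arm study with a known RBE
#'
#' Builds a reference arm from `(alpha, beta)` and a test arm whose LQ
#' parameters are scaled as `alpha * rbe_truth`, `beta * rbe_truth^2`, so
#' the whole test curve is the reference curve stretched in dose by
#' `1 / rbe_truth` and the isoeffect-dose ratio at every survival level is
#' exactly `rbe_truth`. With `rbe_truth = 1` and equal designs the two
#' arms are statistically identical.
#'
#' @param rbe_truth Constructed RBE (> 0).
#' @param alpha,beta Reference-arm LQ parameters.
#' @param doses_ref,doses_test Dose grids for each arm (the defaults
#'   mirror a 0-7.5 Gy X-ray design and a 0/10-30 Gy radionuclide
#'   design).
#' @param cells_seeded_ref,cells_seeded_test Cells per dish per dose.
#' @param plating_efficiency,replicates,seed Shared design parameters.
#' @return List with `reference` and `test` colony-record data.frames
#'   (arms `"xray"` and `"f18"`).
#' @export
make_two_arm_study <- function(rbe_truth, alpha = 0.2, beta = 0.0546,
                               doses_ref = c(0, 2.5, 5, 7.5),
                               doses_test = c(0, 10, 15, 20, 25, 30),
                               cells_seeded_ref = c(100, 400, 2000, 10000),
                               cells_seeded_test = NULL,
                               plating_efficiency = 0.6,
                               replicates = 3L, seed = 1L) {
  if (rbe_truth <= 0) stop("rbe_truth must be positive", call. = FALSE)
  a_t <- alpha * rbe_truth
  b_t <- beta * rbe_truth^2
  if (is.null(cells_seeded_test)) {
    # seed more cells where survival is lower, keeping expected colony
    # counts in a countable range
    sf <- exp(-(a_t * doses_test + b_t * doses_test^2))
    cells_seeded_test <- pmin(pmax(ceiling(60 / (plating_efficiency * sf) /
                                             10) * 10, 100), 1e6)
  }
  list(
    reference = make_survival_dataset(alpha, beta, doses_ref,
                                      cells_seeded_ref, plating_efficiency,
                                      replicates, seed = seed, arm = "xray"),
    test = make_survival_dataset(a_t, b_t, doses_test, cells_seeded_test,
                                 plating_efficiency, replicates,
                                 seed = seed + 1L, arm = "f18"))
}
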