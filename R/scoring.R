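# SSB/DSB scoring of deposition-event streams on the linear DNA geometry.
#
# Default rules: energy is accumulated per backbone volume (strand, base)
# per primary history; a volume whose accumulated energy reaches 17.5 eV
# carries one single-strand break. Two SSBs on opposite strands at most 10
# bases apart form a double-strand break; pairing is a greedy sweep in
# ascending base index taking the nearest eligible partner, each SSB used
# at most once. Both thresholds are inclusive and configurable.

#' Scoring rules for strand-break induction
#'
#' @param ssb_threshold_ev Energy (eV) a backbone volume must accumulate
#'   to carry an SSB (inclusive; default 17.5, the ionization-threshold
#'   convention).
#' @param dsb_max_base_separation Maximum base-index separation (inclusive)
#'   between two SSBs forming a DSB (default 10).
#' @param dsb_requires_opposite_strands A DSB needs its two SSBs on
#'   opposite strands (default `TRUE`; physically a double-strand break
#'   severs both strands).
#' @param accumulation `"per_volume_per_primary"` (default: sum energy per
#'   backbone volume over the history before thresholding) or
#'   `"per_event"` (each single deposition must reach the threshold).
#' @return An object of class `scoring_rules`.
#' @export
scoring_rules <- function(ssb_threshold_ev = 17.5,
                          dsb_max_base_separation = 10L,
                          dsb_requires_opposite_strands = TRUE,
                          accumulation = c("per_volume_per_primary",
                                           "per_event")) {
  if (ssb_threshold_ev <= 0) stop("threshold must be positive", call. = FALSE)
  if (dsb_max_base_separation < 0)
    stop("separation must be >= 0", call. = FALSE)
  structure(
    list(ssb_threshold_ev = ssb_threshold_ev,
         dsb_max_base_separation = as.integer(dsb_max_base_separation),
         dsb_requires_opposite_strands = dsb_requires_opposite_strands,
         accumulation = match.arg(accumulation)),
    class = "scoring_rules")
}

#' @export
print.scoring_rules <- function(x, ...) {
  cat(sprintf("<scoring_rules> SSB >= %g eV (%s); DSB <= %d bases%s\n",
              x$ssb_threshold_ev, x$accumulation, x$dsb_max_base_separation,
              if (x$dsb_requires_opposite_strands) ", opposite strands" else ""))
  invisible(x)
}

#' Score single-strand breaks from deposition events
#'
#' Classifies events into DNA volumes and applies the SSB rule. Only
#' backbone volumes can break; base-region depositions never create
#' breaks. Events of every kind (spur ionizations, terminal blobs,
#' annihilation ionizations) contribute energy. The function is a pure
#' function of its inputs.
#'
#' @param events Deposition-event data.frame with columns `primary_id`,
#'   `x_nm`, `y_nm`, `z_nm`, `energy_ev` (one or several primaries).
#' @param geom A `dna_geometry`.
#' @param rules A `scoring_rules`.
#' @return A data.frame of strand breaks: `primary_id`, `strand`,
#'   `base_index`, `accumulated_energy`.
#' @export
score_ssbs <- function(events, geom, rules = scoring_rules()) {
  stopifnot(inherits(geom, "dna_geometry"), inherits(rules, "scoring_rules"))
  req <- c("primary_id", "x_nm", "y_nm", "z_nm", "energy_ev")
  missing <- setdiff(req, names(events))
  if (length(missing))
    stop("event stream missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  empty <- data.frame(primary_id = numeric(0), strand = integer(0),
                      base_index = integer(0), accumulated_energy = numeric(0))
  if (!nrow(events)) return(empty)
  cls <- classify_points(geom, cbind(events$x_nm, events$y_nm, events$z_nm))
  keep <- cls$region == "backbone"
  if (!any(keep)) return(empty)
  df <- data.frame(primary_id = events$primary_id[keep],
                   strand = cls$strand[keep],
                   base_index = cls$base_index[keep],
                   energy = events$energy_ev[keep])
  if (rules$accumulation == "per_volume_per_primary") {
    key <- interaction(df$primary_id, df$strand, df$base_index, drop = TRUE)
    acc <- rowsum(df$energy, key)
    first <- !duplicated(key)
    out <- data.frame(primary_id = df$primary_id[first],
                      strand = df$strand[first],
                      base_index = df$base_index[first],
                      accumulated_energy = acc[match(key[first],
                                                     rownames(acc)), 1])
  } else {
    out <- data.frame(primary_id = df$primary_id, strand = df$strand,
                      base_index = df$base_index,
                      accumulated_energy = df$energy)
  }
  out <- out[out$accumulated_energy >= rules$ssb_threshold_ev, , drop = FALSE]
  out <- out[order(out$primary_id, out$base_index, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy DSB pairing within one primary history: sweep breaks in ascending
# base index (ties: strand 0 first) and pair each unconsumed break with its
# nearest eligible unconsumed partner (ties: lower base index, then lower
# strand); every break is consumed at most once
.pair_dsbs_one <- function(strand, base_index, max_sep, opposite) {
  n <- length(strand)
  if (n < 2L) return(0L)
  o <- order(base_index, strand)
  strand <- strand[o]; base_index <- base_index[o]
  consumed <- logical(n)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    if (consumed[i]) next
    cand <- which(!consumed & seq_len(n) > i &
                    abs(base_index - base_index[i]) <= max_sep &
                    (if (opposite) strand != strand[i] else TRUE))
    if (!length(cand)) next
    d <- abs(base_index[cand] - base_index[i])
    j <- cand[order(d, base_index[cand], strand[cand])][1]
    consumed[i] <- consumed[j] <- TRUE
    count <- count + 1L
  }
  count
}

#' Score double-strand breaks from a strand-break table
#'
#' Pairs SSBs within each primary history under the proximity rule
#' (opposite strands, base separation at most `dsb_max_base_separation`,
#' inclusive). Pairing is a deterministic greedy sweep; for this
#' two-strand proximity structure it attains the maximum matching, which
#' the test suite verifies against exhaustive search.
#'
#' @param breaks Strand-break data.frame from [score_ssbs()].
#' @param rules A `scoring_rules`.
#' @return Data.frame `primary_id`, `dsb_count` (primaries with no DSB and
#'   no breaks are absent).
#' @export
score_dsbs <- function(breaks, rules = scoring_rules()) {
  stopifnot(inherits(rules, "scoring_rules"))
  if (!nrow(breaks))
    return(data.frame(primary_id = numeric(0), dsb_count = integer(0)))
  counts <- vapply(split(breaks, breaks$primary_id), function(b)
    .pair_dsbs_one(b$strand, b$base_index, rules$dsb_max_base_separation,
                   rules$dsb_requires_opposite_strands),
    integer(1))
  data.frame(primary_id = as.numeric(names(counts)),
             dsb_count = unname(counts))
}

#' Score a whole campaign and summarise damage frequencies
#'
#' Applies SSB and DSB scoring to every run of a [run_campaign()] result
#' (which must have been run with `record_events = TRUE`) and reports
#' counts and frequencies per million primaries, with mean LET per run.
#'
#' @param campaign A `track_campaign` with recorded events.
#' @param geom The `dna_geometry` scored against.
#' @param rules A `scoring_rules`.
#' @return An object of class `damage_summary`: data.frame with one row
#'   per (species, energy, seed): `species`, `energy_ev`, `seed`,
#'   `n_primaries`, `ssb_count`, `dsb_count`, `ssb_per_1e6`, `dsb_per_1e6`,
#'   `let_kev_um`.
#' @export
score_campaign <- function(campaign, geom = dna_geometry(),
                           rules = scoring_rules()) {
  stopifnot(inherits(campaign, "track_campaign"))
  rows <- lapply(campaign, function(r) {
    if (is.null(r$events))
      stop("campaign was run without record_events = TRUE", call. = FALSE)
    br <- score_ssbs(r$events, geom, rules)
    ssb <- nrow(br)
    dsb <- sum(score_dsbs(br, rules)$dsb_count)
    data.frame(species = r$species, energy_ev = r$energy_ev, seed = r$seed,
               n_primaries = r$n_primaries,
               ssb_count = ssb, dsb_count = dsb,
               ssb_per_1e6 = ssb * 1e6 / r$n_primaries,
               dsb_per_1e6 = dsb * 1e6 / r$n_primaries,
               let_kev_um = mean(r$let, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, rules = rules, class = c("damage_summary", "data.frame"))
}

#' Aggregate a damage summary across seeds
#'
#' Mean and spread (max minus min across seeds) of the per-million
#' frequencies and LET for each (species, energy).
#'
#' @param summary A `damage_summary`.
#' @return Data.frame with one row per (species, energy): means and
#'   spreads of `ssb_per_1e6`, `dsb_per_1e6`, `let_kev_um`, and `n_seeds`.
#' @export
aggregate_damage <- function(summary) {
  stopifnot(inherits(summary, "damage_summary"))
  sp <- split(summary, list(summary$species, summary$energy_ev), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(s) data.frame(
    species = s$species[1], energy_ev = s$energy_ev[1],
    n_seeds = nrow(s),
    ssb_per_1e6 = mean(s$ssb_per_1e6),
    ssb_spread = max(s$ssb_per_1e6) - min(s$ssb_per_1e6),
    dsb_per_1e6 = mean(s$dsb_per_1e6),
    dsb_spread = max(s$dsb_per_1e6) - min(s$dsb_per_1e6),
    let_kev_um = mean(s$let_kev_um),
    let_spread = max(s$let_kev_um) - min(s$let_kev_um))))
  out <- out[order(out$species, out$energy_ev), ]
  rownames(out) <- NULL
  out
}

#' Relative difference between two damage summaries
#'
#' Percentage difference `100 * (A - B) / B` of a frequency column at each
#' energy and, integrated over the shared energy grid by the trapezoid
#' rule, `100 * (I_A - I_B) / I_B`. Used to compare the positron and
#' electron campaigns.
#'
#' @param summary_a,summary_b Aggregated damage tables (one row per
#'   energy, same species within each) sharing the same energy grid, e.g.
#'   the per-species subsets of [aggregate_damage()].
#' @param column Frequency column to compare (default `"ssb_per_1e6"`).
#' @return List with `per_energy` (data.frame `energy_ev`, `a`, `b`,
#'   `pct_diff`; `NA` where `b` is zero) and `integral_pct`.
#' @export
relative_difference <- function(summary_a, summary_b,
                                column = "ssb_per_1e6") {
  a <- summary_a[order(summary_a$energy_ev), ]
  b <- summary_b[order(summary_b$energy_ev), ]
  if (!isTRUE(all.equal(a$energy_ev, b$energy_ev)))
    stop("energy grids do not match", call. = FALSE)
  av <- a[[column]]; bv <- b[[column]]
  pct <- ifelse(bv == 0, NA_real_, 100 * (av - bv) / bv)
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  ia <- trap(a$energy_ev, av); ib <- trap(b$energy_ev, bv)
  list(per_energy = data.frame(energy_ev = a$energy_ev, a = av, b = bv,
                               pct_diff = pct),
       integral_pct = if (length(av) == 1L) pct else
         if (ib == 0) NA_real_ else 100 * (ia - ib) / ib)
}
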