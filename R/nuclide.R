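# Radionuclide decay data and elementary decay math.
#
# Internal unit conventions: times in seconds, energies in eV for track
# physics; nuclide records keep beta energies in keV (the unit in which
# decay tables quote them) and convert at the point of use.

#' Joules per electronvolt (CODATA exact value)
#' @keywords internal
EV_TO_JOULE <- 1.602176634e-19

#' Construct a radionuclide record
#'
#' Holds the decay parameters needed for decaying-source dosimetry of a
#' beta-plus emitter: half-life, beta-plus branching ratio and the mean and
#' maximum kinetic energies of the emitted positron. Range-in-water fields
#' are optional metadata and do not enter any calculation.
#'
#' @param name Character label, e.g. `"F-18"`.
#' @param half_life Half-life in seconds.
#' @param branching_beta_plus Fraction of decays through the beta-plus
#'   channel, in `[0, 1]`.
#' @param mean_beta_energy Mean beta-plus kinetic energy in keV.
#' @param max_beta_energy Maximum (endpoint) beta-plus energy in keV.
#' @param mean_range_water,max_range_water Optional ranges in water (mm).
#' @return An object of class `radionuclide`.
#' @examples
#' f18 <- radionuclide("F-18", half_life = 109.77 * 60,
#'                     branching_beta_plus = 0.9673,
#'                     mean_beta_energy = 249.8, max_beta_energy = 633.5)
#' decay_constant(f18)
#' @export
radionuclide <- function(name, half_life, branching_beta_plus,
                         mean_beta_energy, max_beta_energy,
                         mean_range_water = NA_real_,
                         max_range_water = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("half_life must be a positive number of seconds", call. = FALSE)
  if (branching_beta_plus < 0 || branching_beta_plus > 1)
    stop("branching_beta_plus must lie in [0, 1]", call. = FALSE)
  if (mean_beta_energy <= 0 || max_beta_energy <= 0 ||
      mean_beta_energy >= max_beta_energy)
    stop("beta energies must be positive with mean < max", call. = FALSE)
  structure(
    list(name = name,
         half_life = as.numeric(half_life),
         branching_beta_plus = as.numeric(branching_beta_plus),
         mean_beta_energy = as.numeric(mean_beta_energy),
         max_beta_energy = as.numeric(max_beta_energy),
         mean_range_water = as.numeric(mean_range_water),
         max_range_water = as.numeric(max_range_water)),
    class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s\n", x$name))
  cat(sprintf("  half-life: %.4g s (%.4g min)\n", x$half_life, x$half_life / 60))
  cat(sprintf("  beta+ branching: %.4f\n", x$branching_beta_plus))
  cat(sprintf("  beta+ energy: mean %.4g keV, max %.4g keV\n",
              x$mean_beta_energy, x$max_beta_energy))
  if (!is.na(x$mean_range_water))
    cat(sprintf("  range in water: mean %.3g mm, max %.3g mm\n",
                x$mean_range_water, x$max_range_water))
  invisible(x)
}

#' Built-in fluorine-18 record
#'
#' Evaluated decay data for F-18: half-life 109.77 min, beta-plus branching
#' ratio 0.9673 (remainder electron capture), mean positron energy
#' 249.8 keV, endpoint energy 633.5 keV, with mean/maximum ranges in water
#' of about 0.6 and 2.4 mm.
#'
#' @return A `radionuclide` object for F-18.
#' @export
builtin_f18 <- function() {
  radionuclide("F-18",
               half_life = 109.77 * 60,
               branching_beta_plus = 0.9673,
               mean_beta_energy = 249.8,
               max_beta_energy = 633.5,
               mean_range_water = 0.6,
               max_range_water = 2.4)
}

#' Decay constant
#'
#' `lambda = ln(2) / t_half` in s^-1.
#'
#' @param nuclide A `radionuclide` object.
#' @return Decay constant in s^-1.
#' @export
decay_constant <- function(nuclide) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (nuclide$half_life <= 0)
    stop("half-life must be positive", call. = FALSE)
  log(2) / nuclide$half_life
}

#' Activity remaining after a decay time
#'
#' `A(t) = A0 * exp(-lambda * t)`.
#'
#' @param nuclide A `radionuclide` object.
#' @param A0 Initial activity (Bq), non-negative.
#' @param t Elapsed time in seconds, non-negative (vectorised).
#' @return Activity in Bq.
#' @export
activity_at <- function(nuclide, A0, t) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (any(A0 < 0)) stop("A0 must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  A0 * exp(-decay_constant(nuclide) * t)
}

#' Build a radionuclide record from a named list
#'
#' Accepts the plain-list representation produced by reading a YAML or JSON
#' block with fields `name`, `half_life` (s), `branching_beta_plus`,
#' `mean_beta_energy` (keV), `max_beta_energy` (keV) and optionally
#' `mean_range_water` / `max_range_water` (mm).
#'
#' @param x A named list.
#' @return A `radionuclide` object.
#' @export
radionuclide_from_list <- function(x) {
  req <- c("name", "half_life", "branching_beta_plus",
           "mean_beta_energy", "max_beta_energy")
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("missing radionuclide fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  radionuclide(x$name, x$half_life, x$branching_beta_plus,
               x$mean_beta_energy, x$max_beta_energy,
               if (is.null(x$mean_range_water)) NA_real_ else x$mean_range_water,
               if (is.null(x$max_range_water)) NA_real_ else x$max_range_water)
}

#' @export
as.list.radionuclide <- function(x, ...) unclass(x)
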