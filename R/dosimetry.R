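# Decaying-source dosimetry for a radionuclide uniformly mixed into a small
# medium volume. The absorbed dose follows the cumulated-activity formalism
#
#   D = A_tilde * Ebar * kappa / m
#   A_tilde = A0 * integral_0^T exp(-lambda t) dt = A0 (1 - exp(-lambda T)) / lambda
#
# with Ebar the mean beta+ kinetic energy (J), kappa the beta+ branching
# ratio and m the medium mass (kg). All beta+ kinetic energy is assumed
# absorbed locally (absorbed fraction 1); annihilation photons are not
# included — over a few-mL flask they mostly escape, and the model is
# documented accordingly.

#' Define an irradiation plan
#'
#' A plan bundles the nuclide, the initial activity, the irradiation
#' duration and the medium volume/mass. When only the volume is given the
#' mass defaults to unit density (1 g/mL, water-equivalent medium). When
#' both are given they must agree at unit density within 1% unless
#' `check_density = FALSE`.
#'
#' @param nuclide A `radionuclide` object.
#' @param A0 Initial activity in Bq (non-negative).
#' @param duration Irradiation time in seconds (positive).
#' @param medium_volume Medium volume in mL (optional if mass given).
#' @param medium_mass Medium mass in kg (optional if volume given).
#' @param check_density Verify mass/volume consistency at 1 g/mL.
#' @return An object of class `irradiation_plan`.
#' @examples
#' plan <- irradiation_plan(builtin_f18(), A0 = 52.4e6,
#'                          duration = 18 * 3600, medium_volume = 2)
#' absorbed_dose(plan)
#' @export
irradiation_plan <- function(nuclide, A0, duration,
                             medium_volume = NULL, medium_mass = NULL,
                             check_density = TRUE) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (A0 < 0) stop("A0 must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (is.null(medium_volume) && is.null(medium_mass))
    stop("give medium_volume (mL) or medium_mass (kg)", call. = FALSE)
  if (is.null(medium_mass)) medium_mass <- medium_volume / 1000  # 1 g/mL
  if (is.null(medium_volume)) medium_volume <- medium_mass * 1000
  if (medium_mass <= 0) stop("medium mass must be positive", call. = FALSE)
  if (check_density &&
      abs(medium_mass - medium_volume / 1000) > 0.01 * medium_mass)
    stop("medium mass and volume disagree at unit density by > 1%; ",
         "pass check_density = FALSE to override", call. = FALSE)
  structure(
    list(nuclide = nuclide, A0 = A0, duration = duration,
         medium_volume = medium_volume, medium_mass = medium_mass),
    class = "irradiation_plan")
}

#' @export
print.irradiation_plan <- function(x, ...) {
  cat(sprintf("<irradiation_plan> %s, A0 = %.4g MBq, T = %.4g h, %g mL (%g kg)\n",
              x$nuclide$name, x$A0 / 1e6, x$duration / 3600,
              x$medium_volume, x$medium_mass))
  invisible(x)
}

#' Cumulated activity (total number of decays)
#'
#' Closed-form time integral of a purely decaying source:
#' `A0 * (1 - exp(-lambda T)) / lambda`. As `T -> Inf` this tends to
#' `A0 / lambda`.
#'
#' @param nuclide A `radionuclide` object.
#' @param A0 Initial activity (Bq).
#' @param T_s Integration time in seconds (positive).
#' @return Number of decays (Bq.s, dimensionless count).
#' @export
cumulated_activity <- function(nuclide, A0, T_s) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (A0 < 0) stop("A0 must be non-negative", call. = FALSE)
  if (any(T_s <= 0)) stop("integration time must be positive", call. = FALSE)
  lam <- decay_constant(nuclide)
  A0 * (1 - exp(-lam * T_s)) / lam
}

# mean beta+ energy in joules times branching ratio: J deposited per decay
.energy_per_decay_j <- function(nuclide) {
  nuclide$mean_beta_energy * 1e3 * EV_TO_JOULE * nuclide$branching_beta_plus
}

#' Absorbed dose for an irradiation plan
#'
#' Dose to the medium from the beta-plus channel, assuming local absorption
#' of the full positron kinetic energy:
#' `D = A_tilde * Ebar * kappa / m` (Gy).
#'
#' @param plan An `irradiation_plan`.
#' @return An object of class `dose_result` with fields
#'   `cumulated_activity` (decays), `dose` (Gy), `initial_dose_rate` (Gy/s)
#'   and `mean_dose_rate` (Gy/s).
#' @export
absorbed_dose <- function(plan) {
  stopifnot(inherits(plan, "irradiation_plan"))
  if (plan$medium_mass <= 0) stop("medium mass must be positive", call. = FALSE)
  atilde <- cumulated_activity(plan$nuclide, plan$A0, plan$duration)
  epd <- .energy_per_decay_j(plan$nuclide)
  dose <- atilde * epd / plan$medium_mass
  structure(
    list(cumulated_activity = atilde,
         dose = dose,
         initial_dose_rate = plan$A0 * epd / plan$medium_mass,
         mean_dose_rate = dose / plan$duration),
    class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> dose %.4g Gy over %.4g decays\n",
              x$dose, x$cumulated_activity))
  cat(sprintf("  dose rate: initial %.4g mGy/min, mean %.4g mGy/min\n",
              x$initial_dose_rate * 6e4, x$mean_dose_rate * 6e4))
  invisible(x)
}

#' Initial activity required for a target dose
#'
#' Exact algebraic inverse of [absorbed_dose()]:
#' `A0 = D * m * lambda / (Ebar * kappa * (1 - exp(-lambda T)))`.
#'
#' @param nuclide A `radionuclide` object.
#' @param target_dose Target absorbed dose (Gy, positive).
#' @param T_s Irradiation time (s).
#' @param mass Medium mass (kg).
#' @return Required initial activity in Bq.
#' @export
required_initial_activity <- function(nuclide, target_dose, T_s, mass) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (target_dose <= 0) stop("target_dose must be positive", call. = FALSE)
  if (T_s <= 0) stop("irradiation time must be positive", call. = FALSE)
  if (mass <= 0) stop("mass must be positive", call. = FALSE)
  lam <- decay_constant(nuclide)
  target_dose * mass * lam /
    (.energy_per_decay_j(nuclide) * (1 - exp(-lam * T_s)))
}

#' Dose-rate profile over the irradiation
#'
#' Instantaneous dose rate `Ddot(t) = A0 exp(-lambda t) * Ebar * kappa / m`
#' at the requested times. Its integral over `[0, duration]` equals the
#' absorbed dose.
#'
#' @param plan An `irradiation_plan`.
#' @param times Times in seconds, all within `[0, duration]`.
#' @return Numeric vector of dose rates in Gy/s.
#' @export
dose_rate_profile <- function(plan, times) {
  stopifnot(inherits(plan, "irradiation_plan"))
  if (any(times < 0 | times > plan$duration))
    stop("times must lie within [0, duration]", call. = FALSE)
  plan$A0 * exp(-decay_constant(plan$nuclide) * times) *
    .energy_per_decay_j(plan$nuclide) / plan$medium_mass
}
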