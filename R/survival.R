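# Clonogenic assay reduction and linear-quadratic (LQ) survival analysis.
#
# Colony-count tables use the long data.frame schema
#   arm, dose_gy, cells_seeded, colonies, replicate
# Survival fractions are normalised to the 0 Gy plating efficiency; LQ fits
# are weighted least squares of ln SF on (D, D^2) through the origin, the
# standard linearisation of SF = exp(-(alpha D + beta D^2)).

#' Build a colony-count record table
#'
#' Convenience constructor/validator for the long colony-count schema used
#' throughout the package.
#'
#' @param arm Arm label (e.g. `"xray"`, `"f18"`), recycled.
#' @param dose_gy Dose per record (Gy).
#' @param cells_seeded Cells seeded per dish (positive integer).
#' @param colonies Colonies counted (non-negative, at most `cells_seeded`).
#' @param replicate Replicate index, recycled.
#' @return A validated `data.frame` with the five schema columns.
#' @export
colony_records <- function(arm, dose_gy, cells_seeded, colonies, replicate = 1L) {
  df <- data.frame(arm = as.character(arm), dose_gy = as.numeric(dose_gy),
                   cells_seeded = as.numeric(cells_seeded),
                   colonies = as.numeric(colonies),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  validate_colony_records(df)
  df
}

#' Validate a colony-record table
#' @param df A data.frame with columns arm, dose_gy, cells_seeded,
#'   colonies, replicate.
#' @return The validated data.frame, invisibly usable in a pipeline.
#' @export
validate_colony_records <- function(df) {
  req <- c("arm", "dose_gy", "cells_seeded", "colonies", "replicate")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("colony table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$cells_seeded <= 0))
    stop("cells_seeded must be positive", call. = FALSE)
  if (any(df$colonies < 0))
    stop("colonies must be non-negative", call. = FALSE)
  if (any(df$colonies > df$cells_seeded))
    stop("colonies cannot exceed cells_seeded", call. = FALSE)
  if (any(df$dose_gy < 0))
    stop("dose_gy must be non-negative", call. = FALSE)
  invisible(df)
}

#' Survival fractions from colony counts
#'
#' Computes the plating efficiency `PE` as the mean colonies/cells ratio of
#' the unirradiated (0 Gy) replicates, then the survival fraction at each
#' dose as `SF(D) = mean(colonies/cells at D) / PE`. The standard error
#' propagates the replicate scatter at the dose and in the control:
#' `SE(SF) = SF * sqrt(cv_D^2 + cv_0^2)` with `cv` the standard error of
#' the mean divided by the mean. Doses at which no replicate formed a
#' colony are flagged `below_detection` and are excluded from log-domain
#' fitting.
#'
#' @param records Colony-record data.frame (see [colony_records()]).
#' @param arm Optional arm label to subset; required if several arms are
#'   present.
#' @return An object of class `survival_curve`: a data.frame with columns
#'   `dose_gy`, `sf`, `sf_err`, `n_rep`, `below_detection`, plus attributes
#'   `pe` (plating efficiency) and `arm`. The 0 Gy row has `sf = 1` by
#'   construction.
#' @export
survival_fractions <- function(records, arm = NULL) {
  validate_colony_records(records)
  if (is.null(arm)) {
    arms <- unique(records$arm)
    if (length(arms) > 1L)
      stop("several arms present (", paste(arms, collapse = ", "),
           "); pick one with `arm`", call. = FALSE)
    arm <- arms
  }
  records <- records[records$arm == arm, , drop = FALSE]
  if (!nrow(records)) stop("no records for arm '", arm, "'", call. = FALSE)
  ctrl <- records[records$dose_gy == 0, , drop = FALSE]
  if (!nrow(ctrl))
    stop("arm '", arm, "' has no 0 Gy control replicates", call. = FALSE)

  ratio0 <- ctrl$colonies / ctrl$cells_seeded
  pe <- mean(ratio0)
  if (pe <= 0) stop("plating efficiency is zero in arm '", arm, "'", call. = FALSE)
  cv0 <- if (length(ratio0) > 1L)
    stats::sd(ratio0) / sqrt(length(ratio0)) / pe else 0

  doses <- sort(unique(records$dose_gy))
  out <- do.call(rbind, lapply(doses, function(d) {
    sub <- records[records$dose_gy == d, , drop = FALSE]
    if (d == 0)
      return(data.frame(dose_gy = 0, sf = 1, sf_err = cv0,
                        n_rep = nrow(sub), below_detection = FALSE))
    ratio <- sub$colonies / sub$cells_seeded
    m <- mean(ratio)
    sf <- m / pe
    cvd <- if (nrow(sub) > 1L && m > 0)
      stats::sd(ratio) / sqrt(nrow(sub)) / m else 0
    data.frame(dose_gy = d, sf = sf,
               sf_err = sf * sqrt(cvd^2 + cv0^2),
               n_rep = nrow(sub),
               below_detection = all(sub$colonies == 0))
  }))
  # 0 Gy is exactly 1 by the normalisation; its sf_err records the control cv
  out$sf[out$dose_gy == 0] <- 1
  rownames(out) <- NULL
  structure(out, pe = pe, arm = arm,
            class = c("survival_curve", "data.frame"))
}

#' Assemble a survival curve from precomputed points
#'
#' For data already reduced to survival fractions (e.g. digitised or
#' synthetic noiseless curves).
#'
#' @param dose_gy Doses (Gy).
#' @param sf Survival fractions in `(0, 1]`.
#' @param sf_err Optional standard errors (same length); `NA`/zero errors
#'   lead to an unweighted fit.
#' @param arm Arm label.
#' @return A `survival_curve` object.
#' @export
survival_curve <- function(dose_gy, sf, sf_err = NA_real_, arm = "arm") {
  stopifnot(length(dose_gy) == length(sf))
  if (any(sf < 0 | sf > 1)) stop("sf must lie in [0, 1]", call. = FALSE)
  out <- data.frame(dose_gy = as.numeric(dose_gy), sf = as.numeric(sf),
                    sf_err = as.numeric(rep_len(sf_err, length(sf))),
                    n_rep = NA_integer_, below_detection = sf <= 0)
  structure(out, pe = NA_real_, arm = arm,
            class = c("survival_curve", "data.frame"))
}

#' Fit the linear-quadratic survival model
#'
#' Fits `SF = exp(-(alpha D + beta D^2))` by weighted least squares of
#' `ln SF` on `(D, D^2)` through the origin, the standard linearisation in
#' radiobiology. Weights are `1 / (sf_err / sf)^2` (inverse variance of
#' `ln SF` by the delta method); if no usable errors are present the fit is
#' unweighted. `alpha` and `beta` are constrained non-negative by default:
#' if the unconstrained solution leaves the physical region, the fit is
#' repeated with the offending coefficient pinned at zero and the feasible
#' model with the smallest weighted residual sum of squares is returned.
#'
#' The 0 Gy point and any below-detection points (zero colonies) are
#' excluded: the model passes through `SF(0) = 1` by construction and
#' `ln SF` is undefined at 0.
#'
#' @param curve A `survival_curve`.
#' @param constrain Constrain `alpha, beta >= 0` (default `TRUE`).
#' @return An object of class `lq_fit`: list with `alpha` (Gy^-1), `beta`
#'   (Gy^-2), `covariance` (2x2), `alpha_beta_ratio` (Gy), `df_residual`,
#'   and the fitting data.
#' @export
fit_lq <- function(curve, constrain = TRUE) {
  stopifnot(inherits(curve, "survival_curve"))
  pts <- curve[curve$dose_gy > 0 & !curve$below_detection & curve$sf > 0, ,
               drop = FALSE]
  if (any(curve$below_detection))
    warning("excluding ", sum(curve$below_detection),
            " below-detection point(s) from the log-domain fit")
  if (length(unique(pts$dose_gy)) < 3L)
    stop("need at least 3 distinct positive doses to fit alpha and beta",
         call. = FALSE)
  D <- pts$dose_gy
  y <- log(pts$sf)
  w <- if (all(is.na(pts$sf_err)) || all(pts$sf_err == 0, na.rm = TRUE)) {
    rep(1, length(D))
  } else {
    relerr <- pts$sf_err / pts$sf
    relerr[is.na(relerr) | relerr <= 0] <- stats::median(relerr[relerr > 0],
                                                         na.rm = TRUE)
    1 / relerr^2
  }

  fit_with <- function(use_alpha, use_beta) {
    X <- cbind(if (use_alpha) -D else NULL, if (use_beta) -D^2 else NULL)
    if (is.null(X)) return(NULL)
    fit <- stats::lm.wfit(X, y, w)
    co <- fit$coefficients
    p <- length(co)
    dfres <- length(D) - p
    rss <- sum(w * fit$residuals^2)
    sigma2 <- if (dfres > 0) rss / dfres else NA_real_
    XtWX <- crossprod(X * sqrt(w))
    vc_small <- if (is.na(sigma2)) matrix(NA_real_, p, p) else
      sigma2 * solve(XtWX)
    alpha <- if (use_alpha) co[[1]] else 0
    beta <- if (use_beta) co[[if (use_alpha) 2 else 1]] else 0
    vc <- matrix(0, 2, 2, dimnames = list(c("alpha", "beta"),
                                          c("alpha", "beta")))
    idx <- c(if (use_alpha) 1L, if (use_beta) 2L)
    vc[idx, idx] <- vc_small
    list(alpha = alpha, beta = beta, covariance = vc, rss = rss,
         df_residual = dfres, feasible = alpha >= 0 && beta >= 0)
  }

  full <- fit_with(TRUE, TRUE)
  chosen <- full
  if (constrain && !full$feasible) {
    cands <- Filter(function(f) !is.null(f) && f$feasible,
                    list(fit_with(TRUE, FALSE), fit_with(FALSE, TRUE)))
    if (!length(cands)) {
      chosen <- full
      chosen$alpha <- max(chosen$alpha, 0)
      chosen$beta <- max(chosen$beta, 0)
    } else {
      chosen <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]
    }
  }
  structure(
    list(alpha = unname(chosen$alpha), beta = unname(chosen$beta),
         covariance = chosen$covariance,
         alpha_beta_ratio = if (chosen$beta > 0)
           unname(chosen$alpha / chosen$beta) else Inf,
         df_residual = chosen$df_residual,
         constrained = constrain,
         data = data.frame(dose_gy = D, log_sf = y, weight = w),
         arm = attr(curve, "arm")),
    class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> %s: alpha = %.4g Gy^-1, beta = %.4g Gy^-2, alpha/beta = %.4g Gy\n",
              x$arm %||% "", x$alpha, x$beta, x$alpha_beta_ratio))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted LQ survival fraction
#' @param fit An `lq_fit`.
#' @param dose_gy Doses (Gy), vectorised.
#' @return Survival fractions.
#' @export
predict_sf <- function(fit, dose_gy) {
  stopifnot(inherits(fit, "lq_fit"))
  exp(-(fit$alpha * dose_gy + fit$beta * dose_gy^2))
}

#' Confidence interval for the alpha/beta ratio
#'
#' Delta-method interval on `alpha/beta` from the fit covariance, using a
#' t quantile at the fit's residual degrees of freedom.
#'
#' @param fit An `lq_fit`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`, or `NA`s when the ratio or its
#'   variance is undefined.
#' @export
alpha_beta_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lq_fit"))
  a <- fit$alpha; b <- fit$beta; vc <- fit$covariance
  if (b <= 0 || any(is.na(vc)) || fit$df_residual < 1)
    return(c(lower = NA_real_, upper = NA_real_))
  g <- c(1 / b, -a / b^2)  # gradient of a/b
  se <- sqrt(drop(t(g) %*% vc %*% g))
  q <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  c(lower = a / b - q * se, upper = a / b + q * se)
}

#' Dose producing a stated survival fraction
#'
#' Positive root of `beta D^2 + alpha D + ln(sf_level) = 0`, reducing to
#' `-ln(sf_level)/alpha` for a purely exponential curve (`beta = 0`).
#'
#' @param fit An `lq_fit`.
#' @param sf_level Survival fraction in `(0, 1)`.
#' @return Dose in Gy.
#' @export
dose_at_sf <- function(fit, sf_level) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(sf_level <= 0 | sf_level >= 1))
    stop("sf_level must lie strictly in (0, 1)", call. = FALSE)
  L <- log(sf_level)
  if (fit$alpha <= 0 && fit$beta <= 0)
    stop("degenerate fit (alpha = beta = 0) has no finite isoeffect dose",
         call. = FALSE)
  if (fit$beta == 0) return(-L / fit$alpha)
  (-fit$alpha + sqrt(fit$alpha^2 - 4 * fit$beta * L)) / (2 * fit$beta)
}

#' Dose at a survival level by log-linear interpolation of measured points
#'
#' Interpolates `dose` linearly in `ln SF` between measured curve points
#' (the piecewise-exponential reading of a survival curve). Useful when an
#' LQ fit represents the data poorly, e.g. a nearly linear radionuclide
#' curve.
#'
#' @param curve A `survival_curve`.
#' @param sf_level Survival fraction in `(0, 1)`.
#' @return List with `dose` (Gy) and `extrapolated` flag (TRUE when
#'   `sf_level` lies outside the measured SF range).
#' @export
dose_at_sf_interp <- function(curve, sf_level) {
  stopifnot(inherits(curve, "survival_curve"))
  if (sf_level <= 0 || sf_level >= 1)
    stop("sf_level must lie strictly in (0, 1)", call. = FALSE)
  pts <- curve[!curve$below_detection & curve$sf > 0, , drop = FALSE]
  pts <- pts[order(pts$dose_gy), ]
  ls <- log(pts$sf); target <- log(sf_level)
  extrapolated <- target < min(ls) || target > max(ls)
  # ln SF is monotone non-increasing in dose for usable curves; invert on
  # the negated (increasing) axis to get dose(ln SF)
  d <- stats::approx(x = -ls, y = pts$dose_gy, xout = -target, rule = 2,
                     ties = "ordered")$y
  if (extrapolated && target < min(ls)) {
    # extend the last log-linear segment beyond the deepest measured point
    n <- nrow(pts)
    slope <- (pts$dose_gy[n] - pts$dose_gy[n - 1]) / (ls[n] - ls[n - 1])
    d <- pts$dose_gy[n] + slope * (target - ls[n])
  }
  list(dose = d, extrapolated = extrapolated)
}

#' Relative biological effectiveness at a survival level
#'
#' `RBE = D_reference(sf_level) / D_test(sf_level)`: the ratio of
#' reference-radiation dose to test-radiation dose producing the same
#' survival. The test arm may be an `lq_fit` (default route) or a
#' `survival_curve`, in which case the isoeffect dose is read off by
#' log-linear interpolation of the measured points (`method` is then
#' forced to `"interp"`).
#'
#' @param reference_fit `lq_fit` for the reference arm (e.g. X-ray).
#' @param test `lq_fit` or `survival_curve` for the test arm.
#' @param sf_level Survival fraction at which to compare (default 0.5).
#' @param method `"fit"` (LQ isoeffect dose) or `"interp"`.
#' @param level Confidence level for the delta-method RBE interval.
#' @return An object of class `rbe_result`: list with `sf_level`,
#'   `dose_reference`, `dose_test`, `rbe`, `rbe_ci` (NA for the interp
#'   route), and `extrapolated`.
#' @export
rbe <- function(reference_fit, test, sf_level = 0.5,
                method = c("fit", "interp"), level = 0.95) {
  stopifnot(inherits(reference_fit, "lq_fit"))
  method <- match.arg(method)
  d_ref <- dose_at_sf(reference_fit, sf_level)
  extrap <- FALSE
  rbe_ci <- c(lower = NA_real_, upper = NA_real_)
  if (inherits(test, "survival_curve")) method <- "interp"
  if (method == "interp") {
    if (!inherits(test, "survival_curve"))
      stop("interp method needs a survival_curve test arm", call. = FALSE)
    di <- dose_at_sf_interp(test, sf_level)
    d_test <- di$dose
    extrap <- di$extrapolated
  } else {
    stopifnot(inherits(test, "lq_fit"))
    d_test <- dose_at_sf(test, sf_level)
    v_ref <- .dose_at_sf_var(reference_fit, sf_level)
    v_test <- .dose_at_sf_var(test, sf_level)
    if (is.finite(v_ref) && is.finite(v_test)) {
      # delta method on log RBE = log d_ref - log d_test; the two variance
      # components carry very few residual degrees of freedom each (often
      # 1 for a 4-dose design), where a normal or Satterthwaite interval
      # is anticonservative, so use the conservative minimum-df t rule for
      # the Behrens-Fisher problem
      c_ref <- v_ref / d_ref^2
      c_test <- v_test / d_test^2
      se_log <- sqrt(c_ref + c_test)
      df_ref <- max(reference_fit$df_residual %||% Inf, 1)
      df_test <- max(test$df_residual %||% Inf, 1)
      q <- stats::qt(1 - (1 - level) / 2, min(df_ref, df_test))
      r <- d_ref / d_test
      rbe_ci <- c(lower = r * exp(-q * se_log), upper = r * exp(q * se_log))
    }
  }
  if (extrap)
    warning("sf_level outside the measured range of the test arm; ",
            "isoeffect dose extrapolated")
  structure(
    list(sf_level = sf_level, dose_reference = d_ref, dose_test = d_test,
         rbe = d_ref / d_test, rbe_ci = rbe_ci, method = method,
         extrapolated = extrap),
    class = "rbe_result")
}

# variance of the LQ isoeffect dose by the delta method; gradients from the
# implicit equation beta D^2 + alpha D + ln(sf) = 0
.dose_at_sf_var <- function(fit, sf_level) {
  if (is.null(fit$covariance) || any(is.na(fit$covariance)))
    return(NA_real_)
  D <- dose_at_sf(fit, sf_level)
  denom <- 2 * fit$beta * D + fit$alpha
  g <- c(-D / denom, -D^2 / denom)
  drop(t(g) %*% fit$covariance %*% g)
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("<rbe_result> RBE = %.4g at SF = %g (D_ref = %.4g Gy / D_test = %.4g Gy)\n",
              x$rbe, x$sf_level, x$dose_reference, x$dose_test))
  if (!all(is.na(x$rbe_ci)))
    cat(sprintf("  CI: [%.4g, %.4g]\n", x$rbe_ci[1], x$rbe_ci[2]))
  if (x$extrapolated) cat("  (extrapolated beyond measured SF range)\n")
  invisible(x)
}
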