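# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or quadrature, sharing no code with the package
# paths they check.

# trapezoid quadrature of the decaying activity integral
quad_cumulated_activity <- function(half_life_s, A0, T_s, dt = 0.1) {
  lam <- log(2) / half_life_s
  t <- seq(0, T_s, by = dt)
  if (t[length(t)] < T_s) t <- c(t, T_s)
  a <- A0 * exp(-lam * t)
  sum(diff(t) * (head(a, -1) + tail(a, -1)) / 2)
}

# bisection root of beta*D^2 + alpha*D + log(sf) = 0 on [0, hi]
bisect_dose_at_sf <- function(alpha, beta, sf, hi = 1e4, tol = 1e-12) {
  f <- function(D) beta * D^2 + alpha * D + log(sf)
  lo <- 0
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force point classification: loops over every scoring volume and
# tests membership from the sector definition via dot products with the
# sector centre direction (independent of the vectorised modular
# arithmetic in the package)
oracle_classify_one <- function(geom, p) {
  rb <- geom$base_diameter / 2
  ro <- geom$outer_diameter / 2
  r <- sqrt(p[1]^2 + p[2]^2)
  if (p[3] < 0 || p[3] >= geom$total_length || r > ro)
    return(list(region = "outside", strand = NA, base_index = NA))
  k <- min(floor(p[3] / geom$rise_per_base), geom$n_bases - 1)
  for (s in 0:1) {
    centre <- (s * 180 + k * geom$twist_per_base) * pi / 180
    cvec <- c(cos(centre), sin(centre))
    # signed azimuth of p relative to the sector centre, in (-180, 180]
    ang <- atan2(p[2], p[1]) - centre
    ang <- ((ang + pi) %% (2 * pi)) - pi
    ang_deg <- ang * 180 / pi
    if (r <= rb) {
      if (ang_deg >= -90 && ang_deg < 90)
        return(list(region = "base", strand = s, base_index = k))
    } else {
      if (ang_deg >= -45 && ang_deg < 45)
        return(list(region = "backbone", strand = s, base_index = k))
    }
  }
  list(region = "outside", strand = NA, base_index = NA)
}

# exhaustive maximum-cardinality DSB pairing by recursion (feasible for
# small break sets); pairs must sit on opposite strands (optionally) and
# within max_sep bases
oracle_max_dsbs <- function(strand, base_index, max_sep, opposite = TRUE) {
  n <- length(strand)
  if (n < 2) return(0L)
  best <- 0L
  recurse <- function(avail, count) {
    if (count + length(avail) %/% 2 <= best) return()
    best <<- max(best, count)
    if (length(avail) < 2) return()
    i <- avail[1]
    rest <- avail[-1]
    # branch: leave i unpaired
    recurse(rest, count)
    for (j in rest) {
      if (abs(base_index[i] - base_index[j]) <= max_sep &&
          (!opposite || strand[i] != strand[j])) {
        recurse(setdiff(rest, j), count + 1L)
      }
    }
  }
  recurse(seq_len(n), 0L)
  best
}

# naive SSB scoring: per primary, re-accumulate energy per backbone volume
# with explicit loops over events
oracle_score_ssbs <- function(events, geom, threshold) {
  out <- list()
  for (pid in unique(events$primary_id)) {
    ev <- events[events$primary_id == pid, , drop = FALSE]
    acc <- new.env()
    for (i in seq_len(nrow(ev))) {
      cl <- oracle_classify_one(geom, c(ev$x_nm[i], ev$y_nm[i], ev$z_nm[i]))
      if (cl$region != "backbone") next
      key <- paste(cl$strand, cl$base_index)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        ev$energy_ev[i]
    }
    for (key in ls(acc)) {
      if (acc[[key]] >= threshold) {
        sb <- as.integer(strsplit(key, " ")[[1]])
        out[[length(out) + 1L]] <- data.frame(
          primary_id = pid, strand = sb[1], base_index = sb[2],
          accumulated_energy = acc[[key]])
      }
    }
  }
  if (!length(out))
    return(data.frame(primary_id = numeric(0), strand = integer(0),
                      base_index = integer(0),
                      accumulated_energy = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$primary_id, df$base_index, df$strand), ]
  rownames(df) <- NULL
  df
}

# standard F-18 fixtures
f18 <- posidose::builtin_f18()
F18_HALF_LIFE_S <- 109.77 * 60
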