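# Linear DNA scoring geometry.
#
# A 100-base straight double helix abstraction: the molecule is a cylinder
# of outer diameter 2.37 nm and length 34 nm along z, cut into one axial
# slab per base (rise 0.34 nm). Within each slab the inner cylinder
# (diameter 1 nm) holds two half-cylinder base volumes and the surrounding
# annulus holds two quarter-cylinder backbone volumes, one per strand,
# diametrically opposed. Untwisted by default; an optional per-base twist
# rotates the sector pattern helically.
#
# Boundary conventions: axial and azimuthal intervals are half-open with
# the lower bound inclusive; radially the base region is r <= base radius
# and the backbone annulus is base radius < r <= outer radius.

#' Construct the linear DNA scoring geometry
#'
#' @param n_bases Number of base pairs (default 100).
#' @param total_length Total length along the axis in nm (default 34).
#' @param outer_diameter Outer (backbone) diameter in nm (default 2.37).
#' @param base_diameter Inner (base) diameter in nm (default 1.0).
#' @param twist_per_base Azimuthal rotation of the sector pattern per base
#'   step, degrees (default 0; 36 gives a B-DNA-like helical twist).
#' @return An object of class `dna_geometry`. The axis runs along z from 0
#'   to `total_length`; base index 0 starts at z = 0.
#' @examples
#' geom <- dna_geometry()
#' classify_points(geom, cbind(0.8, 0, 17))  # backbone, strand 0, base 50
#' @export
dna_geometry <- function(n_bases = 100L, total_length = 34,
                         outer_diameter = 2.37, base_diameter = 1.0,
                         twist_per_base = 0) {
  if (n_bases < 1L) stop("n_bases must be >= 1", call. = FALSE)
  if (total_length <= 0 || outer_diameter <= 0 || base_diameter <= 0)
    stop("all dimensions must be positive", call. = FALSE)
  if (base_diameter >= outer_diameter)
    stop("base_diameter must be smaller than outer_diameter", call. = FALSE)
  structure(
    list(n_bases = as.integer(n_bases),
         total_length = total_length,
         outer_diameter = outer_diameter,
         base_diameter = base_diameter,
         rise_per_base = total_length / n_bases,
         twist_per_base = twist_per_base),
    class = "dna_geometry")
}

#' @export
print.dna_geometry <- function(x, ...) {
  cat(sprintf(
    "<dna_geometry> %d bases, %g nm long (rise %g nm), outer/base diameter %g/%g nm, twist %g deg/base\n",
    x$n_bases, x$total_length, x$rise_per_base,
    x$outer_diameter, x$base_diameter, x$twist_per_base))
  invisible(x)
}

#' Classify 3-D points into DNA scoring volumes
#'
#' Maps each point to `(region, strand, base_index)`. Backbone
#' quarter-cylinder sectors are centred at azimuth 0 (strand 0) and 180
#' degrees (strand 1); base half-cylinders cover azimuth [-90, 90) for
#' strand 0 and [90, 270) for strand 1. Points beyond the outer radius,
#' outside the axial extent, or in the annulus gaps between backbone
#' sectors are `outside`. The mapping is pure and deterministic.
#'
#' @param geom A `dna_geometry`.
#' @param xyz Numeric matrix with columns x, y, z (nm); a single point may
#'   be given as a length-3 vector.
#' @return A data.frame with columns `region` (factor: backbone, base,
#'   outside), `strand` (0, 1 or NA) and `base_index` (0-based or NA).
#' @export
classify_points <- function(geom, xyz) {
  stopifnot(inherits(geom, "dna_geometry"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  stopifnot(ncol(xyz) == 3)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  n <- length(x)
  r_base <- geom$base_diameter / 2
  r_out <- geom$outer_diameter / 2
  r2 <- x^2 + y^2

  region <- rep("outside", n)
  strand <- rep(NA_integer_, n)
  base_index <- rep(NA_integer_, n)

  in_axial <- z >= 0 & z < geom$total_length
  idx <- which(in_axial & r2 <= r_out^2)
  if (length(idx)) {
    k <- pmin(as.integer(floor(z[idx] / geom$rise_per_base)), geom$n_bases - 1L)
    # azimuth relative to the (possibly twisted) sector frame, in [0, 360)
    phi <- (atan2(y[idx], x[idx]) * 180 / pi -
              k * geom$twist_per_base) %% 360
    r2i <- r2[idx]
    is_base <- r2i <= r_base^2
    # base half-cylinders: strand 0 covers [-90, 90) i.e. [270,360)+[0,90)
    s_base <- ifelse(phi >= 90 & phi < 270, 1L, 0L)
    # backbone quarter-cylinders: strand 0 [-45, 45), strand 1 [135, 225)
    in_q0 <- (phi >= 315 | phi < 45)
    in_q1 <- (phi >= 135 & phi < 225)
    is_backbone <- !is_base & (in_q0 | in_q1)
    region[idx[is_base]] <- "base"
    strand[idx[is_base]] <- s_base[is_base]
    base_index[idx[is_base]] <- k[is_base]
    region[idx[is_backbone]] <- "backbone"
    strand[idx[is_backbone]] <- ifelse(in_q0[is_backbone], 0L, 1L)
    base_index[idx[is_backbone]] <- k[is_backbone]
  }
  data.frame(region = factor(region, levels = c("backbone", "base", "outside")),
             strand = strand, base_index = base_index)
}

#' Representative interior point of a scoring volume
#'
#' Returns a point safely inside the requested backbone or base volume —
#' handy for constructing deposition events with a known classification.
#'
#' @param geom A `dna_geometry`.
#' @param region `"backbone"` or `"base"`.
#' @param strand 0 or 1.
#' @param base_index 0-based base index.
#' @return Length-3 numeric xyz (nm).
#' @export
volume_center <- function(geom, region = c("backbone", "base"), strand,
                          base_index) {
  stopifnot(inherits(geom, "dna_geometry"))
  region <- match.arg(region)
  if (!strand %in% c(0L, 1L)) stop("strand must be 0 or 1", call. = FALSE)
  if (base_index < 0 || base_index >= geom$n_bases)
    stop("base_index out of range", call. = FALSE)
  r <- if (region == "backbone")
    (geom$base_diameter / 2 + geom$outer_diameter / 2) / 2
  else geom$base_diameter / 4
  phi <- (strand * 180 + base_index * geom$twist_per_base) * pi / 180
  z <- (base_index + 0.5) * geom$rise_per_base
  c(r * cos(phi), r * sin(phi), z)
}

#' Define the volumetric particle source
#'
#' A cylinder coaxial with the DNA axis that fully encloses the scoring
#' geometry. By default the radius is twice the DNA outer radius and the
#' cylinder extends one outer radius beyond each DNA end, a compact
#' enclosure consistent with a source volume drawn around the molecule;
#' both dimensions are configurable and are recorded in campaign output.
#'
#' @param geom A `dna_geometry`.
#' @param radius Source radius in nm (default `outer_diameter`).
#' @param z_min,z_max Axial extent in nm (defaults `-outer_radius` and
#'   `total_length + outer_radius`).
#' @return An object of class `source_volume`.
#' @export
source_volume <- function(geom, radius = geom$outer_diameter,
                          z_min = -geom$outer_diameter / 2,
                          z_max = geom$total_length + geom$outer_diameter / 2) {
  stopifnot(inherits(geom, "dna_geometry"))
  if (radius < geom$outer_diameter / 2 || z_min > 0 ||
      z_max < geom$total_length)
    stop("source volume must enclose the DNA model", call. = FALSE)
  structure(list(radius = radius, z_min = z_min, z_max = z_max),
            class = "source_volume")
}

#' @export
print.source_volume <- function(x, ...) {
  cat(sprintf("<source_volume> cylinder r = %g nm, z in [%g, %g] nm\n",
              x$radius, x$z_min, x$z_max))
  invisible(x)
}

#' Sample uniform source points and isotropic directions
#'
#' Positions are uniform in the source cylinder (emissions inside the DNA
#' scoring volumes are permitted — the source overlaps the molecule);
#' directions are isotropic unit vectors. Uses the current R random number
#' stream.
#'
#' @param src A `source_volume`.
#' @param n Number of samples.
#' @return List with `positions` (n x 3) and `directions` (n x 3, unit
#'   rows).
#' @export
sample_source_points <- function(src, n) {
  stopifnot(inherits(src, "source_volume"))
  r <- src$radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, src$z_min, src$z_max)
  positions <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  # isotropic: cos(theta) uniform on [-1, 1]
  ct <- stats::runif(n, -1, 1)
  st <- sqrt(1 - ct^2)
  az <- stats::runif(n, 0, 2 * pi)
  directions <- cbind(x = st * cos(az), y = st * sin(az), z = ct)
  list(positions = positions, directions = directions)
}
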