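# Tetrahedral color space for a four-cone (UVS-type) avian retina.
#
# Conventions: the achromatic point of equal cone stimulation sits at the
# origin; the uv vertex lies on the positive z-axis; each vertex is at
# distance 0.75 from the origin (circumradius of the stimulation simplex).

#' Relative cone stimulation of a reflectance spectrum
#'
#' Quantum catch of each cone class under an ideal (spectrally flat)
#' illuminant, `Q_i = integral R(lambda) C_i(lambda) dlambda` by the
#' trapezoid rule, normalized to sum to one. Because the sensitivity
#' curves have unit area, a flat spectrum stimulates all cones equally
#' (the achromatic point), and scaling a spectrum by any positive constant
#' leaves the stimulation unchanged (intensity invariance).
#'
#' @param spectrum A [reflectance_spectrum] (interpolated onto the
#'   canonical grid if needed).
#' @param vs A `visual_system`; default [bird_visual_system()].
#' @return Named numeric vector `c(uv, s, m, l)`, class `cone_stimulation`.
#' @export
cone_stimulation <- function(spectrum, vs = bird_visual_system()) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            inherits(vs, "visual_system"))
  sp <- interpolate_spectrum(spectrum, vs$wavelengths)
  w <- trap_weights(vs$wavelengths)
  q <- colSums(w * sp$reflectance * vs$curves)
  tot <- sum(q)
  if (tot <= 0)
    stop("undefined color: spectrum produces zero quantum catch",
         call. = FALSE)
  structure(q / tot, class = "cone_stimulation")
}

#' Cartesian color-space coordinates from cone stimulation
#'
#' Places the achromatic point \{1/4, 1/4, 1/4, 1/4\} at the origin and the
#' uv vertex on the positive z-axis:
#' `x = ((1 - 2s - m - uv)/2) * sqrt(3/2)`,
#' `y = (-1 + 3m + uv) / (2*sqrt(2))`,
#' `z = uv - 1/4`.
#' Every vertex lies at distance 0.75 from the origin and the tetrahedron
#' edge length is `sqrt(3/2)`.
#'
#' @param stim Named vector `c(uv, s, m, l)` (sums to 1), or a matrix /
#'   data frame with those columns (one row per color).
#' @return Named numeric `c(x, y, z)`, or a matrix for multiple colors.
#' @export
tetra_cartesian <- function(stim) {
  if (is.null(dim(stim))) {
    stopifnot(length(stim) == 4L)
    s4 <- rbind(as.numeric(stim))
    if (!is.null(names(stim))) colnames(s4) <- names(stim)
  } else s4 <- as.matrix(stim)
  if (!is.null(colnames(s4)) && all(c("uv", "s", "m", "l") %in% colnames(s4)))
    s4 <- s4[, c("uv", "s", "m", "l"), drop = FALSE]
  if (ncol(s4) != 4L) stop("need four cone stimulation values", call. = FALSE)
  if (any(abs(rowSums(s4) - 1) > 1e-8))
    stop("cone stimulations must sum to 1", call. = FALSE)
  uv <- s4[, 1L]; s <- s4[, 2L]; m <- s4[, 3L]
  out <- cbind(x = ((1 - 2 * s - m - uv) / 2) * sqrt(1.5),
               y = (-1 + 3 * m + uv) / (2 * sqrt(2)),
               z = uv - 0.25)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Cone stimulation from Cartesian coordinates
#'
#' Inverse of [tetra_cartesian()]. Points outside the tetrahedron give
#' (invalid) negative stimulations; no clipping is applied.
#'
#' @param xyz Numeric length-3 vector or n x 3 matrix of coordinates.
#' @return Named numeric `c(uv, s, m, l)` or an n x 4 matrix.
#' @export
tetra_stimulation <- function(xyz) {
  p <- as_xyz(xyz)
  uv <- p[, 3L] + 0.25
  m <- (2 * sqrt(2) * p[, 2L] + 1 - uv) / 3
  s <- (1 - 2 * p[, 1L] / sqrt(1.5) - m - uv) / 2
  out <- cbind(uv = uv, s = s, m = m, l = 1 - uv - s - m)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Spherical hue/saturation coordinates of a color point
#'
#' Hue is the direction of the color vector: `theta` (longitude, in
#' `(-pi, pi]`) is the angular displacement from the positive x-axis, which
#' runs between the m (green) and l (red) sectors; `phi` (latitude, in
#' `[-pi/2, pi/2]`) is the displacement from the horizontal xy-plane and
#' equals the uv-component of hue. Saturation `r` is the length of the
#' color vector (distance from the achromatic origin). At the achromatic
#' point the angles are undefined and reported as 0 with
#' `achromatic = TRUE`.
#'
#' @param xyz Numeric length-3 vector or n x 3 matrix.
#' @param tol Radius below which a point is flagged achromatic.
#' @return Data frame with columns `theta`, `phi`, `r`, `achromatic`.
#' @export
tetra_spherical <- function(xyz, tol = 1e-12) {
  p <- as_xyz(xyz)
  r <- sqrt(rowSums(p^2))
  achrom <- r < tol
  theta <- ifelse(achrom, 0, atan2(p[, 2L], p[, 1L]))
  phi <- ifelse(achrom, 0, asin(pmin(1, pmax(-1, p[, 3L] / r))))
  # atan2(0, 0) = 0 already handles the poles: theta 0 by convention
  data.frame(theta = theta, phi = phi, r = r, achromatic = achrom)
}

#' Cartesian coordinates from spherical hue/saturation
#'
#' Inverse of [tetra_spherical()]; round-trips to better than 1e-10.
#'
#' @param theta,phi,r Spherical coordinates (radians, radians, length).
#' @return Numeric `c(x, y, z)` or an n x 3 matrix.
#' @export
spherical_to_cartesian <- function(theta, phi, r) {
  out <- cbind(x = r * cos(phi) * cos(theta),
               y = r * cos(phi) * sin(theta),
               z = r * sin(phi))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Color contrast between two egg colors
#'
#' The mimicry metric: Euclidean distance between two colors in
#' tetrahedral color space. Symmetric, zero only for identical colors,
#' and satisfies the triangle inequality.
#'
#' @param p1,p2 Length-3 vectors, or equal-sized n x 3 matrices (rowwise
#'   contrasts).
#' @return Non-negative numeric contrast(s).
#' @export
color_contrast <- function(p1, p2) {
  a <- as_xyz(p1); b <- as_xyz(p2)
  if (nrow(a) != nrow(b))
    stop("p1 and p2 must contain the same number of colors", call. = FALSE)
  sqrt(rowSums((a - b)^2))
}

# Robinson pseudocylindrical projection: classic coefficient table at 5
# degree latitude intervals (X scales the parallel length, Y the distance
# of the parallel from the equator), cubic-spline interpolated.
.robinson_lat <- seq(0, 90, by = 5)
.robinson_X <- c(1.0000, 0.9986, 0.9954, 0.9900, 0.9822, 0.9730, 0.9600,
                 0.9427, 0.9216, 0.8962, 0.8679, 0.8350, 0.7986, 0.7597,
                 0.7186, 0.6732, 0.6213, 0.5722, 0.5322)
.robinson_Y <- c(0.0000, 0.0620, 0.1240, 0.1860, 0.2480, 0.3100, 0.3720,
                 0.4340, 0.4958, 0.5571, 0.6176, 0.6769, 0.7346, 0.7903,
                 0.8435, 0.8936, 0.9394, 0.9761, 1.0000)

#' Robinson projection of hue-sphere coordinates
#'
#' Flattens the hue sphere for visualization: maps (longitude `theta`,
#' latitude `phi`) on a unit sphere to planar coordinates with the standard
#' cartographic Robinson projection (`px = 0.8487 * X(|phi|) * theta`,
#' `py = 1.3523 * Y(|phi|) * sign(phi)`), using the published coefficient
#' table at 5-degree latitude intervals with cubic-spline interpolation.
#' The projection is symmetric about the equator and central meridian.
#'
#' @param theta Longitudes, radians in `(-pi, pi]`.
#' @param phi Latitudes, radians in `[-pi/2, pi/2]`.
#' @return Matrix with columns `px`, `py`.
#' @export
robinson_project <- function(theta, phi) {
  stopifnot(length(theta) == length(phi))
  if (any(abs(phi) > pi / 2 + 1e-9) || any(abs(theta) > pi + 1e-9))
    stop("angles out of range", call. = FALSE)
  lat <- pmin(abs(phi) * 180 / pi, 90)
  fx <- splinefun(.robinson_lat, .robinson_X, method = "fmm")
  fy <- splinefun(.robinson_lat, .robinson_Y, method = "fmm")
  cbind(px = 0.8487 * fx(lat) * theta,
        py = 1.3523 * fy(lat) * sign(phi))
}

#' Maximum in-gamut saturation along a hue direction
#'
#' Distance from the achromatic origin to the tetrahedron boundary along a
#' given direction (ray-simplex intersection in stimulation space). Equals
#' the circumradius 0.75 toward a vertex and the inradius 0.25 toward the
#' center of a face.
#'
#' @param direction Nonzero length-3 vector (need not be normalized).
#' @return Scalar maximum saturation.
#' @export
gamut_max_saturation <- function(direction) {
  u <- as.numeric(direction)
  stopifnot(length(u) == 3L)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("zero direction", call. = FALSE)
  u <- u / nu
  # stimulation-space displacement per unit step along u
  duv <- u[3L]
  dm <- (2 * sqrt(2) * u[2L] - duv) / 3
  ds <- (-2 * u[1L] / sqrt(1.5) - dm - duv) / 2
  d <- c(duv, ds, dm, -duv - ds - dm)
  neg <- d < 0
  if (!any(neg)) stop("direction never exits the simplex", call. = FALSE)
  min(0.25 / -d[neg])
}

#' Map spectra to a tidy table of color coordinates
#'
#' Convenience wrapper running [cone_stimulation()], [tetra_cartesian()]
#' and [tetra_spherical()] over a list of spectra.
#'
#' @param spectra List of [reflectance_spectrum] objects.
#' @param vs A `visual_system`.
#' @return Data frame with identifiers and columns
#'   `uv, s, m, l, x, y, z, theta, phi, r`.
#' @export
spectra_to_colors <- function(spectra, vs = bird_visual_system()) {
  stopifnot(length(spectra) >= 1L)
  stim <- t(vapply(spectra, cone_stimulation, numeric(4L), vs = vs))
  colnames(stim) <- c("uv", "s", "m", "l")
  xyz <- tetra_cartesian(stim)
  if (is.null(dim(xyz))) xyz <- rbind(xyz)
  sph <- tetra_spherical(xyz)
  grab <- function(field)
    vapply(spectra, function(s) as.character(s[[field]]), character(1L))
  meta <- data.frame(egg_id = grab("egg_id"), clutch_id = grab("clutch_id"),
                     population_id = grab("population_id"),
                     species = grab("species"))
  cbind(meta, as.data.frame(stim), as.data.frame(xyz),
        sph[, c("theta", "phi", "r")])
}
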