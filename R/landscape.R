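# Monte-Carlo selection landscapes: the average acceptance probability a
# hypothetical parasite egg color would enjoy against a host clutch-color
# distribution, swept over the host-occupied region of color space.

# Unwrap circular hue longitudes onto a contiguous arc: the occupied arc
# is the complement of the largest empty gap on the circle, and `u` is
# the position of each angle along that arc (0 at the arc start). For
# data that do not straddle the +/-pi cut this reduces to theta - min.
unwrap_theta <- function(theta) {
  s <- sort(theta)
  n <- length(s)
  gaps <- c(diff(s), s[1L] + 2 * pi - s[n])
  gi <- which.max(gaps)
  start <- if (gi == n) s[1L] else s[gi + 1L]
  list(u = (theta - start) %% (2 * pi), start = start,
       arc = 2 * pi - max(gaps))
}

wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Sample hypothetical parasite egg colors from the host-occupied space
#'
#' Draws colors evenly distributed for hue and saturation over the host's
#' envelope: `theta` uniform on the observed hue-longitude arc, `phi`
#' uniform on the observed phi range, and saturation uniform on
#' (0, r_max] where r_max is the smaller of the gamut boundary along the
#' drawn hue direction and the largest observed host saturation. Hue
#' longitude is treated circularly: the observed arc is the complement of
#' the largest empty gap on the hue circle, so hosts whose hues straddle
#' the +/-pi cut are handled correctly. All samples are inside the
#' tetrahedron by construction and the set is reproducible from `seed`.
#'
#' @param clutch_colors Host clutch colors (>= 3 clutches).
#' @param n Number of colors to sample.
#' @param seed Optional RNG seed (restored on exit).
#' @return Data frame of class `sampled_colors` with columns
#'   `theta, phi, r, x, y, z`; `seed`, `n` and the envelope arc
#'   (`arc_start`, `arc_length`) kept as attributes.
#' @export
sample_host_space <- function(clutch_colors, n = 3000, seed = NULL) {
  p <- as_xyz(clutch_colors)
  if (nrow(p) < 3L) stop("need at least 3 clutches to define an envelope",
                         call. = FALSE)
  sph <- tetra_spherical(p)
  uw <- unwrap_theta(sph$theta)
  ph_rng <- range(sph$phi)
  r_max_obs <- max(sph$r)
  if (uw$arc == 0 || diff(ph_rng) == 0 || r_max_obs == 0)
    stop("degenerate host envelope (zero range)", call. = FALSE)
  with_seed(seed, {
    theta <- wrap_angle(uw$start + runif(n, 0, uw$arc))
    phi <- runif(n, ph_rng[1L], ph_rng[2L])
    dirs <- spherical_to_cartesian(theta, phi, rep(1, n))
    if (is.null(dim(dirs))) dirs <- rbind(dirs)
    gmax <- vapply(seq_len(n), function(i) gamut_max_saturation(dirs[i, ]),
                   numeric(1L))
    r <- runif(n, 0, pmin(gmax, r_max_obs))
    xyz <- dirs * r
    out <- data.frame(theta = theta, phi = phi, r = r,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    attr(out, "seed") <- seed
    attr(out, "n") <- n
    attr(out, "arc_start") <- uw$start
    attr(out, "arc_length") <- uw$arc
    class(out) <- c("sampled_colors", "data.frame")
    out
  })
}

#' Acceptance landscape over sampled parasite egg colors
#'
#' For every sampled color, the mean over host clutches of the acceptance
#' probability `1 - predict_rejection(contrast)`. The hue longitude axis
#' is then summarized by equal-count theta bins whose means are joined by
#' an interpolating cubic spline (the curve passes through the bin means
#' exactly). Binning happens on the contiguous hue arc (see
#' [sample_host_space()]); when the arc straddles the +/-pi cut, the
#' reported `theta` axis continues past pi so the curve stays contiguous.
#'
#' @param samples Output of [sample_host_space()] (or any data frame with
#'   `theta`, `x`, `y`, `z`).
#' @param clutch_colors Host clutch colors.
#' @param model Fitted univariate `discrimination_model`.
#' @param bins Number of equal-count theta bins.
#' @param curve_points Resolution of the interpolated curve.
#' @return List of class `landscape_curve`: `samples` (theta + per-sample
#'   mean acceptance), `bins` (bin mean theta/acceptance/count), `curve`
#'   (splined theta grid and acceptance).
#' @export
acceptance_landscape <- function(samples, clutch_colors, model, bins = 50,
                                 curve_points = 512L) {
  stopifnot(inherits(model, "discrimination_model"))
  d <- cross_contrasts(samples, clutch_colors)
  acc <- 1 - matrix(predict_rejection(model, as.vector(d)), nrow = nrow(d))
  mean_acc <- rowMeans(acc)
  uw <- unwrap_theta(samples$theta)
  theta <- uw$start + uw$u          # contiguous axis, may extend past pi
  bins <- max(2L, min(bins, floor(length(theta) / 2)))
  br <- unique(quantile(theta, probs = seq(0, 1, length.out = bins + 1L)))
  bin_id <- cut(theta, breaks = br, include.lowest = TRUE)
  bin_theta <- tapply(theta, bin_id, mean)
  bin_acc <- tapply(mean_acc, bin_id, mean)
  bin_n <- as.vector(table(bin_id))
  ok <- !is.na(bin_theta)
  bin_theta <- as.numeric(bin_theta[ok]); bin_acc <- as.numeric(bin_acc[ok])
  sf <- splinefun(bin_theta, bin_acc, method = "natural")
  grid <- seq(min(bin_theta), max(bin_theta), length.out = curve_points)
  structure(
    list(samples = data.frame(theta = theta, acceptance = mean_acc),
         bins = data.frame(theta = bin_theta, acceptance = bin_acc,
                           n = bin_n[ok]),
         curve = data.frame(theta = grid, acceptance = sf(grid)),
         spline = sf),
    class = "landscape_curve")
}

#' @export
print.landscape_curve <- function(x, ...) {
  cat("Acceptance landscape:", nrow(x$samples), "sampled colors,",
      nrow(x$bins), "theta bins\n  mean acceptance:",
      sprintf("%.3f", mean(x$samples$acceptance)),
      " range of bin means:",
      sprintf("%.3f-%.3f", min(x$bins$acceptance), max(x$bins$acceptance)),
      "\n")
  invisible(x)
}

#' Exclude a central hue band from a clutch set
#'
#' Removes clutches whose hue longitude lies strictly between the
#' `lo_pct`-th and `hi_pct`-th empirical percentiles of theta
#' (linear-interpolation quantiles, R type 7), computed along the
#' contiguous hue arc so populations straddling the +/-pi cut are
#' handled correctly. Used to construct increasingly bimodal subsets of
#' a host distribution.
#'
#' @param clutches Data frame with a `theta` column (e.g. from
#'   [synth_population()] or [spectra_to_colors()]).
#' @param lo_pct,hi_pct Percentile bounds, `0 <= lo_pct < hi_pct <= 100`.
#' @return The reduced data frame; removed indices in attribute
#'   `"removed"`, the percentile values in `"band"`.
#' @export
exclude_theta_band <- function(clutches, lo_pct, hi_pct) {
  stopifnot(is.data.frame(clutches), "theta" %in% names(clutches))
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100) &&
      !(lo_pct == 0 && hi_pct == 0))
    stop("need 0 <= lo_pct < hi_pct <= 100", call. = FALSE)
  if (lo_pct == hi_pct) return(clutches)
  uw <- unwrap_theta(clutches$theta)
  q <- quantile(uw$u, c(lo_pct, hi_pct) / 100, type = 7, names = FALSE)
  removed <- which(uw$u > q[1L] & uw$u < q[2L])
  if (length(removed) == nrow(clutches))
    stop("band covers all clutches", call. = FALSE)
  out <- clutches[setdiff(seq_len(nrow(clutches)), removed), , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "band") <- wrap_angle(uw$start + q)
  out
}

#' Host-side selection gradient imposed by parasite eggs
#'
#' For each host clutch: the average color contrast to the observed
#' parasite eggs and the predicted probability that this host would
#' reject a parasite egg at that average contrast. Robinson hue
#' coordinates are attached for map-style coloring of the host hue
#' distribution by expected parasitism outcome.
#'
#' @param clutch_colors Host clutch colors.
#' @param cuckoo_colors Parasite egg colors (>= 1).
#' @param model Fitted univariate `discrimination_model`.
#' @return Data frame with one row per clutch: `mean_contrast`,
#'   `rejection_prob`, `theta`, `phi`, `px`, `py`.
#' @export
host_selection_gradient <- function(clutch_colors, cuckoo_colors, model) {
  stopifnot(inherits(model, "discrimination_model"))
  ck <- as_xyz(cuckoo_colors)
  if (nrow(ck) < 1L) stop("need at least one parasite egg", call. = FALSE)
  d <- cross_contrasts(clutch_colors, ck)
  mc <- rowMeans(d)
  sph <- tetra_spherical(as_xyz(clutch_colors))
  proj <- robinson_project(sph$theta, sph$phi)
  data.frame(clutch = seq_along(mc), mean_contrast = mc,
             rejection_prob = predict_rejection(model, mc),
             theta = sph$theta, phi = sph$phi,
             px = proj[, "px"], py = proj[, "py"])
}

#' Count separated peaks of a landscape curve
#'
#' Counts local maxima of the splined acceptance curve that are separated
#' from any higher peak by a dip of at least `prominence`. Two maxima
#' joined by a shallow dip count as one plateau; a curve under weak
#' discrimination should therefore report a single peak even when the
#' host hue distribution is bimodal.
#'
#' @param landscape A `landscape_curve`, or a numeric vector of curve
#'   values.
#' @param prominence Minimum dip depth separating distinct peaks
#'   (acceptance-probability units). The default 0.05 sits well above the
#'   Monte-Carlo noise of equal-count bin means at the default sampling
#'   effort (about 0.02), so noise wiggles are not reported as peaks.
#' @return Integer number of distinct peaks (>= 1 for a non-constant
#'   curve).
#' @export
count_landscape_peaks <- function(landscape, prominence = 0.05) {
  y <- if (inherits(landscape, "landscape_curve"))
    landscape$curve$acceptance else as.numeric(landscape)
  n <- length(y)
  if (n < 3L) return(1L)
  # local maxima (plateau-tolerant via run-length collapse)
  rl <- rle(y)
  v <- rl$values
  k <- length(v)
  if (k == 1L) return(1L)
  idx_max <- which(diff(sign(diff(c(-Inf, v, -Inf)))) == -2)
  if (length(idx_max) <= 1L) return(length(idx_max))
  # merge adjacent peaks whose separating valley is shallower than
  # `prominence` below the lower of the two peaks
  peaks <- v[idx_max]
  valleys <- vapply(seq_len(length(idx_max) - 1L), function(i)
    min(v[idx_max[i]:idx_max[i + 1L]]), numeric(1L))
  count <- 1L
  cur_peak <- peaks[1L]
  for (i in seq_along(valleys)) {
    if (min(cur_peak, peaks[i + 1L]) - valleys[i] >= prominence) {
      count <- count + 1L
      cur_peak <- peaks[i + 1L]
    } else {
      cur_peak <- max(cur_peak, peaks[i + 1L])
    }
  }
  count
}
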