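#' Cone spectral sensitivity templates for a UVS-type retina
#'
#' Builds average ultraviolet-sensitive (UVS-type) cone sensitivity curves
#' from the Govardovskii A1 visual-pigment alpha-band template, one curve
#' per cone class (uv, s, m, l), on the canonical 300--700 nm grid. Each
#' curve is normalized to unit area (trapezoid rule) so that a spectrally
#' flat reflectance is exactly achromatic.
#'
#' These curves are a constructed stand-in for measured average UVS
#' sensitivities (which are published as supplementary material elsewhere
#' and not redistributable here); any measured curve set can be supplied to
#' [bird_visual_system()] instead.
#'
#' @param peaks Named numeric vector of peak wavelengths (nm) for the four
#'   cone classes. Defaults are typical averages for UVS-type passerine
#'   retinas.
#' @param grid Wavelength grid, nm.
#' @return An object of class `visual_system`.
#' @export
uvs_sensitivity_curves <- function(peaks = c(uv = 371, s = 448,
                                             m = 503, l = 563),
                                   grid = canonical_grid()) {
  stopifnot(length(peaks) == 4L,
            all(c("uv", "s", "m", "l") %in% names(peaks)))
  curves <- vapply(c("uv", "s", "m", "l"), function(cone) {
    govardovskii_alpha(grid, peaks[[cone]])
  }, numeric(length(grid)))
  new_visual_system(grid, curves, source = "govardovskii-template")
}

# Govardovskii et al. A1 pigment alpha-band absorbance template.
govardovskii_alpha <- function(wl, lambda_max) {
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

new_visual_system <- function(wavelengths, curves, source = "user") {
  stopifnot(is.matrix(curves), ncol(curves) == 4L,
            nrow(curves) == length(wavelengths))
  colnames(curves) <- c("uv", "s", "m", "l")
  if (any(curves < 0)) stop("sensitivity curves must be non-negative",
                            call. = FALSE)
  w <- trap_weights(wavelengths)
  area <- colSums(w * curves)
  if (any(area <= 0)) stop("sensitivity curve with zero area", call. = FALSE)
  curves <- sweep(curves, 2L, area, "/")
  structure(list(wavelengths = as.numeric(wavelengths), curves = curves,
                 source = source),
            class = "visual_system")
}

#' Load the avian visual system used for color-space mapping
#'
#' Returns the four unit-area cone sensitivity curves on the canonical
#' grid. By default the bundled synthetic UVS-type curve set
#' (`uvs_cone_sensitivities_synthetic.csv`, built with
#' [uvs_sensitivity_curves()]) is loaded; pass `path` to use measured
#' curves instead (CSV with columns `wavelength`, `uv`, `s`, `m`, `l`).
#' Curves on other grids are linearly interpolated and renormalized to
#' unit area.
#'
#' @param path Optional CSV of sensitivity curves replacing the bundled set.
#' @return An object of class `visual_system`.
#' @export
bird_visual_system <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0(".vs_cache", envir = the)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "uvs_cone_sensitivities_synthetic.csv",
                        package = "eggmimicry", mustWork = TRUE)
    use_cache <- TRUE
  } else use_cache <- FALSE
  df <- read.csv(path)
  for (cn in c("wavelength", "uv", "s", "m", "l"))
    if (!cn %in% names(df))
      stop("sensitivity file must have columns wavelength, uv, s, m, l",
           call. = FALSE)
  grid <- canonical_grid()
  if (min(df$wavelength) > min(grid) || max(df$wavelength) < max(grid))
    stop("sensitivity curves do not cover the canonical grid", call. = FALSE)
  curves <- vapply(c("uv", "s", "m", "l"), function(cn)
    approx(df$wavelength, df[[cn]], xout = grid)$y, numeric(length(grid)))
  vs <- new_visual_system(grid, curves, source = path)
  if (use_cache) assign(".vs_cache", vs, envir = the)
  vs
}

# package-local mutable state (visual-system cache)
the <- new.env(parent = emptyenv())

#' @export
print.visual_system <- function(x, ...) {
  pk <- x$wavelengths[apply(x$curves, 2L, which.max)]
  cat("Avian visual system (UVS-type), 4 unit-area cone sensitivities\n",
      " grid: ", min(x$wavelengths), "-", max(x$wavelengths), " nm\n",
      " peaks (uv,s,m,l): ", paste(pk, collapse = ", "), " nm\n", sep = "")
  invisible(x)
}
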