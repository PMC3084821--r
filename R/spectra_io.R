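#' Canonical wavelength grid
#'
#' All color-space computations in this package are carried out on a common
#' 300--700 nm grid with 1-nm spacing, covering the spectral support of an
#' ultraviolet-sensitive (UVS-type) avian retina. Input spectra measured on
#' other grids are linearly interpolated onto it.
#'
#' @return Integer vector of wavelengths in nm (300, 301, ..., 700).
#' @export
canonical_grid <- function() 300:700

#' Construct a reflectance spectrum
#'
#' A `reflectance_spectrum` holds the (replicate-averaged) fractional
#' reflectance of one egg measurement on a strictly increasing wavelength
#' grid, together with identifying metadata.
#'
#' @param wavelengths Strictly increasing numeric vector, nm.
#' @param reflectance Numeric vector of the same length; finite and >= 0
#'   (unitless fractional reflectance).
#' @param egg_id,clutch_id,population_id,species Identifiers (optional).
#' @param year,latitude_deg,longitude_deg Optional collection metadata.
#' @param n_replicates Number of raw measurements averaged into this spectrum.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance,
                                 egg_id = NA_character_,
                                 clutch_id = NA_character_,
                                 population_id = NA_character_,
                                 species = NA_character_,
                                 year = NA_integer_,
                                 latitude_deg = NA_real_,
                                 longitude_deg = NA_real_,
                                 n_replicates = 1L) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance must have the same length", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("non-monotone wavelengths", call. = FALSE)
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("reflectance values must be finite", call. = FALSE)
  if (any(reflectance < 0))
    stop("reflectance values must be non-negative", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         egg_id = egg_id, clutch_id = clutch_id,
         population_id = population_id, species = species,
         year = year, latitude_deg = latitude_deg,
         longitude_deg = longitude_deg,
         n_replicates = as.integer(n_replicates)),
    class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat("Reflectance spectrum", if (!is.na(x$egg_id)) paste0("'", x$egg_id, "'"),
      "\n  range:", min(x$wavelengths), "-", max(x$wavelengths), "nm,",
      length(x$wavelengths), "points\n  reflectance: ",
      sprintf("%.4f-%.4f", min(x$reflectance), max(x$reflectance)),
      "\n  replicates averaged:", x$n_replicates, "\n")
  invisible(x)
}

#' Interpolate a spectrum onto a wavelength grid
#'
#' Linear interpolation onto `grid` (default the canonical 1-nm grid). The
#' spectrum must cover the requested grid; no extrapolation is performed.
#'
#' @param spectrum A [reflectance_spectrum].
#' @param grid Target wavelength grid, nm.
#' @return A [reflectance_spectrum] on `grid`.
#' @export
interpolate_spectrum <- function(spectrum, grid = canonical_grid()) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (min(spectrum$wavelengths) > min(grid) ||
      max(spectrum$wavelengths) < max(grid))
    stop("spectrum does not cover the requested wavelength grid (",
         min(grid), "-", max(grid), " nm)", call. = FALSE)
  if (length(spectrum$wavelengths) == length(grid) &&
      all(spectrum$wavelengths == grid))
    return(spectrum)
  r <- approx(spectrum$wavelengths, spectrum$reflectance, xout = grid)$y
  out <- spectrum
  out$wavelengths <- as.numeric(grid)
  out$reflectance <- r
  out
}

#' Read a wide table of reflectance spectra
#'
#' Reads a CSV with one wavelength column and one column per measurement.
#' Small negative reflectance values (instrument noise) within
#' `neg_tolerance` are clipped to zero with a warning; larger negatives are
#' an error. Spectra are returned on the canonical grid (linear
#' interpolation) unless `grid = NULL`.
#'
#' @param path CSV file path.
#' @param metadata Optional data frame keyed by `egg_id` whose remaining
#'   columns (e.g. `clutch_id`, `population_id`, `species`, `year`,
#'   `latitude_deg`, `longitude_deg`) are joined onto each spectrum.
#' @param wavelength_col Name of the wavelength column.
#' @param neg_tolerance Most negative reflectance accepted (then clipped).
#' @param grid Target grid for interpolation, or `NULL` to keep the file grid.
#' @return List of [reflectance_spectrum] objects, in file column order.
#' @export
read_spectra_table <- function(path, metadata = NULL,
                               wavelength_col = "wavelength",
                               neg_tolerance = 0.001,
                               grid = canonical_grid()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (!wavelength_col %in% names(df))
    stop("missing wavelength column '", wavelength_col, "'", call. = FALSE)
  wl <- suppressWarnings(as.numeric(df[[wavelength_col]]))
  if (anyNA(wl)) stop("wavelength column is not numeric", call. = FALSE)
  if (any(diff(wl) <= 0)) stop("non-monotone wavelengths", call. = FALSE)
  meas_cols <- setdiff(names(df), wavelength_col)
  if (length(meas_cols) == 0L)
    stop("no measurement columns found", call. = FALSE)
  n_clipped <- 0L
  spectra <- lapply(meas_cols, function(cn) {
    r <- as.numeric(df[[cn]])
    if (any(r < -neg_tolerance))
      stop("negative reflectance beyond tolerance (", neg_tolerance,
           ") in column '", cn, "'", call. = FALSE)
    if (any(r < 0)) {
      n_clipped <<- n_clipped + sum(r < 0)
      r[r < 0] <- 0
    }
    sp <- reflectance_spectrum(wl, r, egg_id = cn)
    if (!is.null(metadata)) {
      i <- match(cn, metadata$egg_id)
      if (!is.na(i)) {
        for (f in intersect(names(metadata),
                            c("clutch_id", "population_id", "species",
                              "year", "latitude_deg", "longitude_deg")))
          sp[[f]] <- metadata[[f]][i]
      }
    }
    if (!is.null(grid)) sp <- interpolate_spectrum(sp, grid)
    sp
  })
  if (n_clipped > 0L)
    warning("clipped ", n_clipped,
            " small negative reflectance value(s) to zero", call. = FALSE)
  names(spectra) <- meas_cols
  spectra
}

#' Write spectra to a wide CSV table
#'
#' Inverse of [read_spectra_table()]: all spectra must share one wavelength
#' grid. Values round-trip through the file to better than 1e-9.
#'
#' @param spectra List of [reflectance_spectrum] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wavelengths
  for (sp in spectra)
    if (!identical(length(sp$wavelengths), length(wl)) ||
        any(sp$wavelengths != wl))
      stop("all spectra must share one wavelength grid", call. = FALSE)
  ids <- vapply(seq_along(spectra), function(i) {
    id <- spectra[[i]]$egg_id
    if (is.na(id)) paste0("spectrum_", i) else id
  }, character(1L))
  df <- data.frame(wavelength = wl, check.names = FALSE)
  for (i in seq_along(spectra)) df[[ids[i]]] <- spectra[[i]]$reflectance
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate measurements of one egg
#'
#' Pointwise arithmetic mean of replicate spectra sharing a wavelength grid
#' (the standard reduction of four or eight probe placements per egg to a
#' single spectrum). Metadata are carried over from the first replicate and
#' the replicate count is recorded.
#'
#' @param measurements List of [reflectance_spectrum] objects on identical
#'   grids (normally sharing an `egg_id`).
#' @return A single [reflectance_spectrum].
#' @export
average_replicates <- function(measurements) {
  if (length(measurements) < 1L) stop("empty input", call. = FALSE)
  stopifnot(all(vapply(measurements, inherits, logical(1L),
                       "reflectance_spectrum")))
  wl <- measurements[[1L]]$wavelengths
  for (sp in measurements)
    if (length(sp$wavelengths) != length(wl) || any(sp$wavelengths != wl))
      stop("mismatched wavelength grids", call. = FALSE)
  refl <- rowMeans(vapply(measurements, `[[`, numeric(length(wl)),
                          "reflectance"))
  out <- measurements[[1L]]
  out$reflectance <- refl
  out$n_replicates <- sum(vapply(measurements, `[[`, integer(1L),
                                 "n_replicates"))
  out
}

#' Read an egg-exchange trial table
#'
#' Each row is one experiment: contrast covariates plus a binary outcome.
#' Accepted outcome encodings are 0/1 (1 = rejection) and the labels
#' accept/acceptance/reject/rejection (case-insensitive). Rows missing a
#' required covariate are dropped with a message.
#'
#' @param path CSV file path.
#' @param required Columns that must be non-missing for a row to be kept.
#' @return Data frame of trials with `outcome` in \{0, 1\}.
#' @export
read_trials_table <- function(path, required = c("delta_tc", "outcome")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$outcome <- decode_outcome(df$outcome)
  keep <- complete.cases(df[, required, drop = FALSE])
  if (any(!keep)) {
    message("dropped ", sum(!keep),
            " trial row(s) with missing required covariates")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  for (cn in intersect(names(df), c("delta_tc", "delta_tb",
                                    "shape_contrast", "volume_contrast")))
    df[[cn]] <- as.numeric(df[[cn]])
  if ("species" %in% names(df)) df$species <- factor(df$species)
  df
}

decode_outcome <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad))
      stop("unrecognized outcome label: ", x[bad][1L], call. = FALSE)
    return(as.integer(x))
  }
  lab <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(lab))
  out[lab %in% c("reject", "rejection", "rejected", "1")] <- 1L
  out[lab %in% c("accept", "acceptance", "accepted", "0")] <- 0L
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("unrecognized outcome label: '", as.character(x)[bad][1L], "'",
         call. = FALSE)
  out
}

#' Read a sampling-locality table
#'
#' Validates coordinate bounds (latitude within \[-90, 90\], longitude
#' within \[-180, 180\]). An optional `precision_level` column records
#' whether the locality is an exact site or a region centre.
#'
#' @param path CSV with columns `latitude_deg`, `longitude_deg` and
#'   optionally `id`, `year`, `precision_level`.
#' @return Data frame of locality records.
#' @export
read_localities_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  for (cn in c("latitude_deg", "longitude_deg"))
    if (!cn %in% names(df)) stop("missing column '", cn, "'", call. = FALSE)
  check_coords(df$latitude_deg, df$longitude_deg)
  if ("precision_level" %in% names(df)) {
    bad <- !df$precision_level %in% c("site", "region-centre")
    if (any(bad))
      stop("precision_level must be 'site' or 'region-centre'", call. = FALSE)
  }
  df
}

check_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of range: latitude must lie in [-90, 90], ",
         "longitude in [-180, 180]", call. = FALSE)
  invisible(TRUE)
}
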