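# Synthetic-data generator: egg reflectance spectra with known color-space
# coordinates, clutch populations with controllable hue structure
# (unimodal vs bimodal), parasite eggs at controlled mimicry offsets, and
# simulated rejection trials from a known logistic discrimination
# function. All randomness flows from a per-call seed; no global state.

#' Scenario configuration for synthetic populations
#'
#' @param n_clutches Number of clutches (one measured egg per clutch,
#'   matching the negligible within-clutch color variation of the study
#'   species).
#' @param hue_mixture Data frame with columns `mu` (mean hue longitude,
#'   radians), `kappa` (von Mises concentration, > 0) and `weight`
#'   (mixture weights summing to 1). One row gives a unimodal
#'   distribution, two well-separated rows a bimodal one.
#' @param phi_mean,phi_sd Hue latitude distribution (normal, radians).
#' @param sat_mean,sat_sd Saturation distribution (normal truncated to
#'   the color-space gamut).
#' @param noise_sd Additive spectral noise SD (reflectance units).
#' @param beta True discrimination coefficients `c(beta0, beta1)` of the
#'   logistic rejection law used when simulating trials.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_clutches,
                            hue_mixture,
                            phi_mean = -0.35, phi_sd = 0.12,
                            sat_mean = 0.103, sat_sd = 0.018,
                            noise_sd = 0, beta = c(-2, 60)) {
  stopifnot(is.data.frame(hue_mixture),
            all(c("mu", "kappa", "weight") %in% names(hue_mixture)),
            all(hue_mixture$kappa > 0),
            abs(sum(hue_mixture$weight) - 1) < 1e-8,
            phi_sd >= 0, sat_sd >= 0, noise_sd >= 0,
            length(beta) == 2L)
  structure(list(n_clutches = as.integer(n_clutches),
                 hue_mixture = hue_mixture,
                 phi_mean = phi_mean, phi_sd = phi_sd,
                 sat_mean = sat_mean, sat_sd = sat_sd,
                 noise_sd = noise_sd, beta = beta),
            class = "scenario_config")
}

#' Calibrated population presets
#'
#' Two ready-made scenario configurations emulating the two host species'
#' clutch-color distributions:
#' * `"brambling"` — unimodal hue (single von Mises component), mean
#'   saturation 0.103 (SD 0.018), 232 clutches;
#' * `"chaffinch"` — bimodal hue (two von Mises components), mean
#'   saturation 0.070 (SD 0.016), 157 clutches.
#' Hue concentrations are calibrated so the population mean pairwise
#' color contrast is close to 0.045; the default discrimination
#' coefficients `c(-2, 60)` put 50% rejection near contrast 0.033 so the
#' optimal egg in either population is rejected about half the time.
#'
#' @param name `"brambling"` or `"chaffinch"`.
#' @return A `scenario_config`.
#' @export
preset_scenario <- function(name = c("brambling", "chaffinch")) {
  name <- match.arg(name)
  if (name == "brambling")
    scenario_config(
      n_clutches = 232L,
      hue_mixture = data.frame(mu = 2.0, kappa = 10, weight = 1),
      phi_mean = -0.35, phi_sd = 0.10,
      sat_mean = 0.103, sat_sd = 0.018)
  else
    scenario_config(
      n_clutches = 157L,
      hue_mixture = data.frame(mu = c(1.7, 2.3), kappa = c(6, 6),
                               weight = c(0.5, 0.5)),
      phi_mean = -0.35, phi_sd = 0.10,
      sat_mean = 0.070, sat_sd = 0.016)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); returns angles
# wrapped to (-pi, pi].
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-7) {
    th <- runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    rr <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- n - got
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      k <- sum(ok)
      if (k > 0L) {
        th[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(f[ok]) + mu
        got <- got + k
      }
    }
  }
  ((th + pi) %% (2 * pi)) - pi
}

# normal rejection-sampled into [lo, hi]; errors if acceptance < 1%
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop("degenerate truncation: mean outside bounds", call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(n)
  got <- 0L
  tried <- 0L
  while (got < n) {
    m <- max(n - got, 100L)
    x <- rnorm(m, mean, sd)
    tried <- tried + m
    x <- x[x >= lo & x <= hi]
    k <- min(length(x), n - got)
    if (k > 0L) {
      out[(got + 1L):(got + k)] <- x[seq_len(k)]
      got <- got + k
    }
    if (tried > 100L * n && got < 0.01 * tried)
      stop("infeasible truncation: acceptance rate below 1%", call. = FALSE)
  }
  out
}

#' Synthesize a reflectance spectrum with a prescribed color
#'
#' Builds a smooth non-negative spectrum whose mapped color equals the
#' target `(theta, phi, r)` to well within a color contrast of 0.005.
#' The spectrum is a non-negative combination of a flat component and a
#' dictionary of smooth Gaussian bumps (sd 15 nm, centers every 10 nm),
#' with coefficients solved numerically by non-negative least squares
#' against the visual system's quantum-catch matrix — positivity of the
#' reflectance is therefore guaranteed by construction. Optional i.i.d.
#' Gaussian noise is added and clipped at zero. Targets outside the
#' spectral locus of the basis (where no non-negative spectrum attains
#' the requested cone catches) raise an explicit error.
#'
#' @param theta,phi,r Target spherical color coordinates (in gamut).
#' @param noise_sd SD of additive reflectance noise.
#' @param seed Optional RNG seed (noise only).
#' @param vs A `visual_system`.
#' @param base Mean reflectance level of the returned spectrum (the color
#'   is intensity-invariant; this only sets the overall scale).
#' @param tol Maximum accepted color contrast between the target and the
#'   reconstructed spectrum's color.
#' @return A [reflectance_spectrum] on the canonical grid.
#' @export
synth_spectrum <- function(theta, phi, r, noise_sd = 0, seed = NULL,
                           vs = bird_visual_system(), base = 0.25,
                           tol = 0.005) {
  stopifnot(r >= 0)
  if (r > 0) {
    gmax <- gamut_max_saturation(spherical_to_cartesian(theta, phi, 1))
    if (r > gmax + 1e-12)
      stop("target saturation ", signif(r, 4), " outside gamut (max ",
           signif(gmax, 4), " for this hue)", call. = FALSE)
  }
  wl <- vs$wavelengths
  D <- synth_dictionary(wl)
  w <- trap_weights(wl)
  A <- t(crossprod(D * w, vs$curves))     # 4 cones x dictionary catches
  q_target <- tetra_stimulation(spherical_to_cartesian(theta, phi, r))
  a <- pracma::lsqnonneg(A, q_target)$x
  q_hat <- drop(A %*% a)
  achieved <- tetra_cartesian(q_hat / sum(q_hat))
  err <- color_contrast(achieved, spherical_to_cartesian(theta, phi, r))
  if (err > tol)
    stop("target color unreachable with non-negative reflectance ",
         "(outside the spectral locus of the basis; nearest achievable ",
         "color is ", signif(err, 3), " away)", call. = FALSE)
  refl <- drop(D %*% a)
  refl <- refl * base / (sum(w * refl) / diff(range(wl)))
  if (noise_sd > 0)
    refl <- with_seed(seed, pmax(refl + rnorm(length(refl), 0, noise_sd), 0))
  reflectance_spectrum(wl, refl)
}

# spectral dictionary: flat component plus smooth Gaussian bumps
synth_dictionary <- function(wl) {
  centers <- seq(min(wl), max(wl), by = 10)
  cbind(flat = rep(1, length(wl)),
        vapply(centers, function(cc) exp(-(wl - cc)^2 / (2 * 15^2)),
               numeric(length(wl))))
}

#' Generate a synthetic clutch population
#'
#' Draws hue longitudes from the configured von Mises mixture, hue
#' latitudes and saturations from (truncated) normals, maps to Cartesian
#' color-space coordinates, and (optionally) reconstructs a reflectance
#' spectrum per clutch with [synth_spectrum()]. Saturations are truncated
#' to the gamut boundary along each clutch's hue direction.
#'
#' @param cfg A `scenario_config` (see [preset_scenario()]).
#' @param seed Optional RNG seed.
#' @param spectra If `TRUE`, attach a list of reflectance spectra as
#'   attribute `"spectra"`.
#' @param vs Visual system used when `spectra = TRUE`.
#' @return Data frame with one row per clutch: `clutch_id`, `theta`,
#'   `phi`, `r`, `x`, `y`, `z`, `uv`, `s`, `m`, `l`.
#' @export
synth_population <- function(cfg, seed = NULL, spectra = FALSE,
                             vs = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_clutches
  with_seed(seed, {
    comp <- sample.int(nrow(cfg$hue_mixture), n, replace = TRUE,
                       prob = cfg$hue_mixture$weight)
    theta <- numeric(n)
    for (j in unique(comp)) {
      i <- comp == j
      theta[i] <- rvonmises(sum(i), cfg$hue_mixture$mu[j],
                            cfg$hue_mixture$kappa[j])
    }
    phi <- rtruncnorm(n, cfg$phi_mean, cfg$phi_sd, -pi / 2, pi / 2)
    dirs <- spherical_to_cartesian(theta, phi, rep(1, n))
    if (is.null(dim(dirs))) dirs <- rbind(dirs)
    gmax <- vapply(seq_len(n), function(i) gamut_max_saturation(dirs[i, ]),
                   numeric(1L))
    r <- vapply(seq_len(n), function(i)
      rtruncnorm(1L, cfg$sat_mean, cfg$sat_sd, 1e-6, gmax[i]), numeric(1L))
    xyz <- dirs * r
    stim <- tetra_stimulation(xyz)
    if (is.null(dim(stim))) stim <- rbind(stim)
    pop <- data.frame(clutch_id = sprintf("clutch_%03d", seq_len(n)),
                      theta = theta, phi = phi, r = r,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      uv = stim[, 1L], s = stim[, 2L], m = stim[, 3L],
                      l = stim[, 4L])
    if (spectra) {
      if (is.null(vs)) vs <- bird_visual_system()
      sp <- lapply(seq_len(n), function(i) {
        s <- synth_spectrum(theta[i], phi[i], r[i],
                            noise_sd = cfg$noise_sd, vs = vs)
        s$egg_id <- s$clutch_id <- pop$clutch_id[i]
        s
      })
      attr(pop, "spectra") <- sp
    }
    attr(pop, "config") <- cfg
    pop
  })
}

#' Place synthetic parasite eggs at a mimicry offset
#'
#' Positions `k` parasite eggs at the population's optimal (best
#' achievable mimetic) color, displaced by a fixed color contrast
#' `offset` in a random in-gamut direction (offset 0 reproduces parasite
#' eggs sitting exactly at the optimum). Directions leaving the gamut are
#' redrawn, up to 100 times per egg.
#'
#' @param population Clutch table from [synth_population()] (or any data
#'   frame with `x`, `y`, `z`).
#' @param offset Color-contrast displacement from the optimal color.
#' @param k Number of parasite eggs.
#' @param seed Optional RNG seed.
#' @return k x 3 matrix of Cartesian colors; the optimal clutch index is
#'   attached as attribute `"optimal_index"`.
#' @export
synth_cuckoo_eggs <- function(population, offset = 0, k = 5, seed = NULL) {
  p <- as_xyz(population)
  if (nrow(p) < 2L) stop("host population too small", call. = FALSE)
  stopifnot(offset >= 0, k >= 1)
  opt <- optimal_egg(pairwise_contrasts(p))
  center <- p[opt$index, ]
  with_seed(seed, {
    out <- matrix(0, k, 3L, dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq_len(k)) {
      if (offset == 0) {
        out[i, ] <- center
        next
      }
      for (try in seq_len(100L)) {
        u <- rnorm(3L)
        u <- u / sqrt(sum(u^2))
        cand <- center + offset * u
        stim <- tetra_stimulation(cand)
        if (all(stim >= -1e-12)) {
          out[i, ] <- cand
          break
        }
        if (try == 100L)
          stop("could not place egg inside gamut after 100 draws",
               call. = FALSE)
      }
    }
    attr(out, "optimal_index") <- opt$index
    out
  })
}

#' Simulate egg-exchange rejection trials
#'
#' Pairs random host clutches with random parasite eggs and draws the
#' binary rejection outcome from the logistic law
#' `P(reject) = plogis(beta0 + beta1 * delta_tc)`. Nuisance covariates
#' (brightness contrast, shape contrast, volume contrast, host species)
#' are generated alongside; by default they have no effect on the
#' outcome, but non-null effects can be injected through `nuisance_beta`
#' (named vector on the linear-predictor scale).
#'
#' @param population Host clutch table (`x`, `y`, `z`).
#' @param cuckoo_colors Parasite egg colors (k x 3).
#' @param beta True coefficients `c(beta0, beta1)` for the color-contrast
#'   effect.
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional RNG seed.
#' @param nuisance_beta Optional named numeric vector with any of
#'   `delta_tb`, `shape_contrast`, `volume_contrast`, `species` adding
#'   true effects to the linear predictor.
#' @return Data frame of trials: `clutch`, `egg`, `delta_tc`, `delta_tb`,
#'   `shape_contrast`, `volume_contrast`, `species`, `outcome`.
#' @export
synth_trials <- function(population, cuckoo_colors, beta = c(-2, 60),
                         n_trials = 288, seed = NULL,
                         nuisance_beta = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  hp <- as_xyz(population)
  ck <- as_xyz(cuckoo_colors)
  stopifnot(length(beta) == 2L)
  with_seed(seed, {
    ci <- sample.int(nrow(hp), n_trials, replace = TRUE)
    ei <- sample.int(nrow(ck), n_trials, replace = TRUE)
    dtc <- sqrt(rowSums((hp[ci, , drop = FALSE] -
                           ck[ei, , drop = FALSE])^2))
    dtb <- abs(rnorm(n_trials, 6, 4))
    shp <- abs(rnorm(n_trials, 0.10, 0.08))
    vol <- abs(rnorm(n_trials, 300, 200))
    spc <- factor(sample(c("brambling", "chaffinch"), n_trials,
                         replace = TRUE))
    eta <- beta[1L] + beta[2L] * dtc
    if (!is.null(nuisance_beta)) {
      nb <- nuisance_beta
      if ("delta_tb" %in% names(nb)) eta <- eta + nb[["delta_tb"]] * dtb
      if ("shape_contrast" %in% names(nb))
        eta <- eta + nb[["shape_contrast"]] * shp
      if ("volume_contrast" %in% names(nb))
        eta <- eta + nb[["volume_contrast"]] * vol
      if ("species" %in% names(nb))
        eta <- eta + nb[["species"]] * (spc == "chaffinch")
    }
    data.frame(clutch = ci, egg = ei, delta_tc = dtc, delta_tb = dtb,
               shape_contrast = shp, volume_contrast = vol,
               species = spc, outcome = rbinom(n_trials, 1L, plogis(eta)))
  })
}
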