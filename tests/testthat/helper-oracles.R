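# Shared fixtures and independent oracles used across test files.

# Random points inside the color tetrahedron: uniform Dirichlet(1,1,1,1)
# cone stimulations mapped to Cartesian coordinates.
random_color_points <- function(n, seed = NULL) {
  gen <- function() {
    g <- matrix(rexp(4L * n), n, 4L)
    stim <- g / rowSums(g)
    colnames(stim) <- c("uv", "s", "m", "l")
    xyz <- tetra_cartesian(stim)
    if (is.null(dim(xyz))) xyz <- rbind(xyz)
    xyz
  }
  if (is.null(seed)) gen() else eggmimicry:::with_seed(seed, gen())
}

# Independent haversine oracle (mean Earth radius in km).
haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371.009) {
  p <- pi / 180
  2 * R * asin(sqrt(sin((lat2 - lat1) * p / 2)^2 +
                      cos(lat1 * p) * cos(lat2 * p) *
                        sin((lon2 - lon1) * p / 2)^2))
}

# Independent recursive permutation enumerator (distinct from the
# package's iterative construction).
enumerate_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in enumerate_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}

# Sarle's bimodality coefficient with sample-size correction;
# values above 5/9 indicate bimodality.
bimodality_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / s^3
  g2 <- mean((x - m)^4) / s^4 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# One discrimination model fitted on synthetic trials, cached for reuse
# across test files (slope close to the true c(-2, 60)).
cached_model <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      pop <- synth_population(preset_scenario("brambling"), seed = 11)
      ck <- synth_cuckoo_eggs(pop, offset = 0.02, k = 5, seed = 1)
      tr <- synth_trials(pop, ck, beta = c(-2, 60), n_trials = 2000,
                         seed = 5)
      env$m <- fit_logistic(tr, "delta_tc")
    }
    env$m
  }
})

# Constant-reflectance spectrum on the canonical grid.
flat_spectrum <- function(level, egg_id = NA_character_) {
  reflectance_spectrum(canonical_grid(), rep(level, 401L), egg_id = egg_id)
}

table1_terms <- function() {
  c("delta_tc", "delta_tb", "species", "shape_contrast", "volume_contrast",
    "delta_tb:species", "volume_contrast:species", "delta_tc:species",
    "delta_tb:delta_tc", "shape_contrast:species")
}

# von Mises draws for constructing test populations
rvonmises_test <- function(n, mu, kappa) eggmimicry:::rvonmises(n, mu, kappa)
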