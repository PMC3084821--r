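test_that("MRPP agrees with vegan and handles perfect separation", {
  set.seed(71)
  x <- matrix(rnorm(60), 30, 2)
  g <- rep(c("a", "b"), each = 15)
  mine <- eggmimicry::mrpp(x, g, n_perm = 499, seed = 71)
  vg <- vegan::mrpp(x, g, permutations = 499)
  expect_equal(unname(mine$statistic), vg$delta, tolerance = 1e-12)
  expect_equal(mine$A, vg$A, tolerance = 1e-12)
  expect_equal(mine$E_delta, vg$E.delta, tolerance = 1e-12)
  # zero within-group spread at disjoint locations: delta = 0, minimal p
  z <- rbind(matrix(rep(c(0, 0), 12), ncol = 2, byrow = TRUE),
             matrix(rep(c(5, 5), 12), ncol = 2, byrow = TRUE))
  gz <- rep(c("a", "b"), each = 12)
  mz <- eggmimicry::mrpp(z, gz, n_perm = 199, seed = 72)
  expect_equal(unname(mz$statistic), 0)
  expect_equal(mz$p_value, 1 / 200)
  expect_error(eggmimicry::mrpp(x[1:4, ], c("a", "a", "a", "b")),
               "singleton")
})

test_that("exhaustive MRPP matches a combination oracle and Monte-Carlo", {
  set.seed(73)
  x8 <- matrix(rnorm(16), 8, 2)
  g8 <- rep(c("a", "b"), each = 4)
  ex <- eggmimicry::mrpp(x8, g8, exhaustive = TRUE)
  # independent oracle over all label assignments (choose(8,4) splits)
  D <- as.matrix(dist(x8))
  delta_of <- function(i) {
    j <- setdiff(1:8, i)
    0.5 * sum(D[i, i]) / 12 + 0.5 * sum(D[j, j]) / 12
  }
  all_d <- apply(combn(8, 4), 2, delta_of)
  obs <- delta_of(1:4)
  expect_equal(ex$p_value, mean(all_d <= obs + 1e-12), tolerance = 1e-12)
  # Monte-Carlo agrees within 2 binomial SE
  mc <- eggmimicry::mrpp(x8, g8, n_perm = 4999, seed = 74)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 4999)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 5000)
})

test_that("Mantel statistics and p-values match vegan and exact enumeration", {
  set.seed(75)
  x <- matrix(rnorm(40), 20, 2)
  d1 <- dist(x)
  d2 <- dist(x + matrix(rnorm(40, 0, 0.8), 20, 2))
  expect_equal(unname(mantel_test(d1, d1 + 0, n_perm = 9,
                                  seed = 1)$statistic), 1)
  # affine invariance of the upper triangle
  aff <- 3 + 2 * as.matrix(d1)
  diag(aff) <- 0
  expect_equal(unname(mantel_test(d1, aff, n_perm = 9,
                                  seed = 1)$statistic), 1)
  mm <- mantel_test(d1, d2, n_perm = 999, seed = 76)
  vm <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(unname(mm$statistic), unname(vm$statistic),
               tolerance = 1e-12)
  # exhaustive mode equals an independent full enumeration (n = 7)
  x7 <- matrix(rnorm(14), 7, 2)
  e1 <- as.matrix(dist(x7))
  e2 <- as.matrix(dist(x7 + matrix(rnorm(14, 0, 1), 7, 2)))
  ex <- mantel_test(e1, e2, exhaustive = TRUE)
  ut <- upper.tri(e1)
  r_obs <- cor(e1[ut], e2[ut])
  rs <- vapply(enumerate_perms(7L), function(p) cor(e1[ut], e2[p, p][ut]),
               numeric(1))
  expect_equal(ex$p_value, mean(rs >= r_obs - 1e-12), tolerance = 1e-12)
  expect_equal(ex$n_perm, factorial(7) - 1)
  expect_error(mantel_test(matrix(0, 5, 5), e1[1:5, 1:5]), "constant")
})

test_that("partial Mantel matches the residual/partial-correlation oracle", {
  set.seed(77)
  x <- matrix(rnorm(60), 30, 2)
  d1 <- as.matrix(dist(x))
  d2 <- as.matrix(dist(x + matrix(rnorm(60, 0, 0.6), 30, 2)))
  d3 <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  pm <- partial_mantel(d1, d2, d3, n_perm = 99, seed = 78)
  ut <- upper.tri(d1)
  r12 <- cor(d1[ut], d2[ut]); r13 <- cor(d1[ut], d3[ut])
  r23 <- cor(d2[ut], d3[ut])
  expect_equal(unname(pm$statistic),
               (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2)),
               tolerance = 1e-10)
  # regression-residual oracle
  res1 <- resid(lm(d1[ut] ~ d3[ut])); res2 <- resid(lm(d2[ut] ~ d3[ut]))
  expect_equal(unname(pm$statistic), cor(res1, res2), tolerance = 1e-10)
  expect_equal(unname(pm$statistic),
               unname(vegan::mantel.partial(as.dist(d1), as.dist(d2),
                                            as.dist(d3),
                                            permutations = 9)$statistic),
               tolerance = 1e-10)
  # independent control: partial r close to the plain Mantel r
  plain <- mantel_test(d1, d2, n_perm = 99, seed = 79)
  expect_lt(abs(pm$statistic - plain$statistic), 0.05)
  # controlling for (nearly) the same structure removes the correlation
  d2b <- 1 + 2 * d3 + matrix(rnorm(900, 0, 1e-4), 30, 30)
  d2b <- (d2b + t(d2b)) / 2; diag(d2b) <- 0
  pm0 <- partial_mantel(d2b, d3, d3, n_perm = 99, seed = 80)
  expect_lt(abs(unname(pm0$statistic)), 0.1)
})

test_that("permanova pseudo-F equals classical ANOVA F for Euclidean 1-D", {
  set.seed(81)
  y <- rnorm(24)
  f <- factor(rep(1:3, each = 8))
  pa <- permanova_1factor(matrix(y, ncol = 1), f, n_perm = 99, seed = 82)
  av <- anova(lm(y ~ f))
  expect_equal(unname(pa$statistic), av$`F value`[1], tolerance = 1e-10)
  expect_equal(pa$R2, summary(lm(y ~ f))$r.squared, tolerance = 1e-10)
  # continuous covariate against vegan::adonis2
  x <- matrix(rnorm(60), 30, 2)
  cv <- rnorm(30)
  pa2 <- permanova_1factor(x, cv, n_perm = 99, seed = 83)
  ad <- vegan::adonis2(dist(x) ~ cv, permutations = 99)
  expect_equal(unname(pa2$statistic), ad$F[1], tolerance = 1e-10)
  expect_equal(pa2$R2, ad$R2[1], tolerance = 1e-10)
  # perfectly separated point clouds with zero within-spread: R2 = 1
  z <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(3, 1), 5), ncol = 2, byrow = TRUE))
  paz <- permanova_1factor(z, rep(c("a", "b"), each = 5), n_perm = 19,
                           seed = 84)
  expect_equal(paz$R2, 1, tolerance = 1e-12)
  expect_error(permanova_1factor(x, rep(1, 30)), "constant covariate")
})

test_that("group dispersion test matches centroid-distance oracles", {
  set.seed(85)
  base <- matrix(rnorm(80), 40, 2)
  # translated copies have identical dispersion: F ~ 0
  coords <- rbind(base, sweep(base, 2, c(10, -4), "+"))
  g <- rep(c("a", "b"), each = 40)
  gd <- group_dispersion_test(coords, g)
  expect_lt(gd$F, 1e-12)
  # per-observation distances match a loop oracle
  cen_a <- colMeans(coords[1:40, ]); cen_b <- colMeans(coords[41:80, ])
  oracle <- c(sqrt(rowSums(sweep(coords[1:40, ], 2, cen_a)^2)),
              sqrt(rowSums(sweep(coords[41:80, ], 2, cen_b)^2)))
  expect_equal(unname(gd$distances), oracle, tolerance = 1e-12)
  # agrees with vegan::betadisper centroid ANOVA
  x <- matrix(rnorm(135), 45, 3)
  g3 <- rep(c("a", "b", "c"), each = 15)
  gd3 <- group_dispersion_test(x, g3, tukey = TRUE)
  bd <- anova(vegan::betadisper(dist(x), g3, type = "centroid"))
  expect_equal(gd3$F, bd$`F value`[1], tolerance = 1e-10)
  expect_identical(nrow(gd3$tukey), 3L)
  expect_error(group_dispersion_test(x[1:3, ], c("a", "a", "b")),
               "singleton")
})

test_that("a threefold spread difference is detected with high power", {
  set.seed(86)
  hits <- vapply(1:100, function(s) {
    a <- matrix(rnorm(100, 0, 1), 50, 2)
    b <- matrix(rnorm(100, 0, 3), 50, 2)
    group_dispersion_test(rbind(a, b),
                          rep(c("a", "b"), each = 50))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("great-circle distances follow the haversine on the mean radius", {
  expect_equal(great_circle_distances(c(63, 63), c(12, 12))[1, 2], 0)
  expect_equal(great_circle_distances(c(0, 0), c(0, 180))[1, 2],
               pi * 6371.009, tolerance = 1e-6)
  got <- great_circle_distances(c(63, 68), c(12, 25))[1, 2]
  expect_equal(got, haversine_km(63, 12, 68, 25), tolerance = 0.1)
  locs <- data.frame(id = c("p", "q"), latitude_deg = c(63, 68),
                     longitude_deg = c(12, 25))
  m <- great_circle_distances(locs)
  expect_identical(rownames(m), c("p", "q"))
  expect_equal(m, t(m))
  expect_error(great_circle_distances(c(95, 0), c(0, 0)), "out of range")
})

test_that("permutation p-values are seeded, conventional and null-uniform", {
  set.seed(87)
  x <- matrix(rnorm(40), 20, 2)
  g <- rep(c("a", "b"), each = 10)
  p1 <- eggmimicry::mrpp(x, g, n_perm = 99, seed = 88)$p_value
  p2 <- eggmimicry::mrpp(x, g, n_perm = 99, seed = 88)$p_value
  expect_identical(p1, p2)
  # the seed is restored: global RNG state is untouched by seeded calls
  rng_before <- .Random.seed
  invisible(eggmimicry::mrpp(x, g, n_perm = 19, seed = 1))
  expect_identical(.Random.seed, rng_before)
  # null p-values approximately uniform (KS at alpha = 0.01, 200 reps)
  crit <- 1.628 / sqrt(200)
  pm <- vapply(1:200, function(s) {
    z <- eggmimicry:::with_seed(3000 + s, matrix(rnorm(30), 15, 2))
    d1 <- dist(z)
    d2 <- eggmimicry:::with_seed(6000 + s, dist(matrix(rnorm(30), 15, 2)))
    mantel_test(d1, d2, n_perm = 99, seed = 9000 + s)$p_value
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(pm, "punif")$statistic), crit)
  pr <- vapply(1:200, function(s) {
    z <- eggmimicry:::with_seed(4000 + s, matrix(rnorm(40), 20, 2))
    eggmimicry::mrpp(z, g, n_perm = 99, seed = 9500 + s)$p_value
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(pr, "punif")$statistic), crit)
})

test_that("distance-based tests are invariant to rigid motions", {
  set.seed(89)
  x <- matrix(rnorm(60), 30, 2)
  g <- rep(c("a", "b"), each = 15)
  cv <- rnorm(30)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))         # random rotation/reflection
  xr <- sweep(x %*% Q, 2, c(3, -7), "+")
  m1 <- eggmimicry::mrpp(x, g, n_perm = 99, seed = 90)
  m2 <- eggmimicry::mrpp(xr, g, n_perm = 99, seed = 90)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-12)
  expect_identical(m1$p_value, m2$p_value)
  p1 <- permanova_1factor(x, cv, n_perm = 99, seed = 91)
  p2 <- permanova_1factor(xr, cv, n_perm = 99, seed = 91)
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-9)
  expect_identical(p1$p_value, p2$p_value)
  g1 <- group_dispersion_test(x, g)
  g2 <- group_dispersion_test(xr, g)
  expect_equal(g1$F, g2$F, tolerance = 1e-9)
})
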