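test_that("brightness contrast is the absolute integrated reflectance difference", {
  s2 <- flat_spectrum(0.2); s3 <- flat_spectrum(0.3)
  expect_identical(brightness_contrast(s2, s2), 0)
  # flat difference of 0.1 over the 400-nm grid measure
  expect_equal(brightness_contrast(s2, s3), 0.1 * 400)
  expect_equal(brightness_contrast(s3, s2), brightness_contrast(s2, s3))
  # scaling both spectra scales the contrast linearly
  set.seed(10)
  a <- reflectance_spectrum(300:700, runif(401))
  b <- reflectance_spectrum(300:700, runif(401))
  k <- 2.7
  ak <- reflectance_spectrum(300:700, k * a$reflectance)
  bk <- reflectance_spectrum(300:700, k * b$reflectance)
  expect_equal(brightness_contrast(ak, bk), k * brightness_contrast(a, b))
  short <- reflectance_spectrum(seq(300, 700, 2), rep(0.1, 201))
  expect_error(brightness_contrast(a, short), "grid mismatch")
})

test_that("egg volume and shape-index formulas", {
  expect_equal(egg_volume(20, 15), 0.51 * 20 * 225)
  expect_equal(egg_shape_index(17, 17), 1)
  # toy pair: sphere-like vs elongated, contrasts by hand
  expect_equal(abs(egg_volume(20, 15) - egg_volume(24, 14)),
               abs(2295 - 0.51 * 24 * 196))
  expect_equal(abs(egg_shape_index(20, 15) - egg_shape_index(24, 14)),
               abs(20 / 15 - 24 / 14))
  expect_error(egg_volume(-1, 10), "positive")
  expect_error(egg_shape_index(10, 0), "positive")
})

test_that("logistic fit matches closed forms and an independent ML optimizer", {
  # intercept-only: 90 rejections, 60 acceptances
  tr0 <- data.frame(outcome = rep(c(1, 0), c(90, 60)))
  m0 <- fit_logistic(tr0, character(0))
  expect_equal(unname(coef(m0)), log(90 / 60), tolerance = 1e-8)
  expect_equal(plogis(unname(coef(m0))), 0.6, tolerance = 1e-8)
  # parameter recovery at n = 2000
  pop <- synth_population(preset_scenario("brambling"), seed = 21)
  ck <- synth_cuckoo_eggs(pop, offset = 0.02, k = 5, seed = 22)
  tr <- synth_trials(pop, ck, beta = c(-2, 60), n_trials = 2000, seed = 23)
  m <- fit_logistic(tr, "delta_tc")
  expect_true(all(abs(coef(m) - c(-2, 60)) <= 3 * m$se))
  # independent general-purpose optimizer on the same likelihood
  nll <- function(b) {
    eta <- b[1] + b[2] * tr$delta_tc
    -sum(tr$outcome * eta - log1p(exp(eta)))
  }
  op <- optim(c(0, 0), nll, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(m)), op$par, tolerance = 1e-5)
  expect_equal(m$deviance, 2 * op$value, tolerance = 1e-8)
  # stored deviance reproduces from stored data and coefficients
  eta <- coef(m)[1] + coef(m)[2] * m$data$delta_tc
  dev <- -2 * sum(m$data$outcome * eta - log1p(exp(eta)))
  expect_equal(m$deviance, dev, tolerance = 1e-10)
  # fitted probabilities strictly inside (0, 1)
  p <- predict_rejection(m, tr$delta_tc)
  expect_true(all(p > 0 & p < 1))
})

test_that("degenerate and separable designs raise explicit errors", {
  tr <- data.frame(delta_tc = runif(50, 0, 0.1), outcome = 1)
  expect_error(fit_logistic(tr, "delta_tc"), "degenerate outcomes")
  set.seed(24)
  sep <- data.frame(delta_tc = runif(200, 0, 0.1))
  sep$outcome <- as.integer(sep$delta_tc > 0.05)
  expect_error(suppressWarnings(fit_logistic(sep, "delta_tc")),
               "complete separation")
  dup <- data.frame(delta_tc = runif(100, 0, 0.1), outcome = rbinom(100, 1, 0.5))
  dup$twin <- dup$delta_tc
  expect_error(fit_logistic(dup, c("delta_tc", "twin")),
               "collinear term\\(s\\) twin")
})

test_that("deviance is nonincreasing as terms are added to nested models", {
  pop <- synth_population(preset_scenario("brambling"), seed = 25)
  tr <- synth_trials(pop, synth_cuckoo_eggs(pop, 0.03, 5, seed = 26),
                     n_trials = 600, seed = 27)
  terms_seq <- list(character(0), "delta_tc", c("delta_tc", "delta_tb"),
                    c("delta_tc", "delta_tb", "species"),
                    c("delta_tc", "delta_tb", "species", "delta_tb:species"))
  devs <- vapply(terms_seq, function(tm) fit_logistic(tr, tm)$deviance,
                 numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("backward elimination keeps the contrast effect and drops null terms", {
  pop <- synth_population(preset_scenario("brambling"), seed = 31)
  ck <- synth_cuckoo_eggs(pop, offset = 0.02, k = 5, seed = 32)
  tr <- synth_trials(pop, ck, beta = c(-2, 60), n_trials = 2000, seed = 33)
  be <- backward_eliminate(tr, table1_terms())
  expect_true("delta_tc" %in% be$retained)
  expect_true(all(be$selection$p >= 0 & be$selection$p <= 1))
  # interactions are dropped before their main effects become droppable
  sel <- be$selection
  for (tm in c("delta_tb", "species"))
    if (any(sel$term == tm)) {
      inter_steps <- sel$step[grepl(paste0("\\b", tm, "\\b"), sel$term) &
                                grepl(":", sel$term) & !sel$retained]
      main_step <- sel$step[sel$term == tm][1]
      if (length(inter_steps)) expect_true(all(inter_steps < main_step))
    }
  # all-null covariates give an intercept-only minimal model
  tr_null <- synth_trials(pop, ck, beta = c(0.2, 0), n_trials = 1500,
                          seed = 35)
  be_null <- backward_eliminate(tr_null,
                                c("delta_tb", "shape_contrast",
                                  "volume_contrast"))
  expect_length(be_null$retained, 0L)
  expect_length(coef(be_null$model), 1L)
  # single-deletion mode reports one test per term from the full model
  # (main effects masked by retained interactions are a known hazard of
  # single deletion, so the candidate set here is main effects only)
  mains <- c("delta_tc", "delta_tb", "species", "shape_contrast",
             "volume_contrast")
  be1 <- backward_eliminate(tr, mains, method = "single")
  expect_identical(nrow(be1$selection), length(mains))
  expect_true("delta_tc" %in% be1$retained)
})

test_that("rejection probabilities follow the inverse-logit with valid CIs", {
  m <- cached_model()
  m10 <- m; m10$coefficients <- c(0, 10)
  expect_equal(predict_rejection(m10, 0), 0.5)
  m60 <- m; m60$coefficients <- c(-2, 60)
  expect_equal(predict_rejection(m60, 1 / 30), 0.5)
  grid <- seq(0, 0.2, by = 0.005)
  expect_equal(predict_rejection(m60, grid),
               1 / (1 + exp(-(-2 + 60 * grid))), tolerance = 1e-12)
  expect_true(all(diff(predict_rejection(m, grid)) >= 0))
  expect_error(predict_rejection(m, -0.01), "negative")
  ci <- predict_rejection(m, grid, ci = TRUE)
  expect_true(all(ci$lower <= ci$p & ci$p <= ci$upper))
  expect_true(all(ci$lower > 0 & ci$upper < 1))
})

test_that("confidence intervals achieve nominal coverage across simulations", {
  pop <- synth_population(preset_scenario("brambling"), seed = 41)
  ck <- synth_cuckoo_eggs(pop, offset = 0.02, k = 5, seed = 42)
  truth <- c(-2, 60)
  hits <- matrix(FALSE, 200, 2)
  for (i in 1:200) {
    tr <- synth_trials(pop, ck, beta = truth, n_trials = 288,
                       seed = 5000 + i)
    m <- fit_logistic(tr, "delta_tc")
    hits[i, ] <- abs(coef(m) - truth) <= qnorm(0.975) * m$se
  }
  cover <- colMeans(hits)
  expect_true(all(cover >= 0.90 & cover <= 1.00))
})

test_that("pooled control rejection rate aggregates per-species counts", {
  counts <- fringilla_control_counts()
  expect_identical(sum(counts$trials), 66L)
  expect_equal(pooled_rejection_rate(counts), 61 / 66)
  expect_equal(pooled_rejection_rate(
    data.frame(rejected = c(1, 1), trials = c(2, 2))), 0.5)
})
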