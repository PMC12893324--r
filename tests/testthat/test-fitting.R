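test_that("noiseless three-state data is recovered essentially exactly", {
  st <- noiseless_study()
  fit <- noiseless_fit()
  j <- dplyr::inner_join(st$truth$ddG, tidy(fit), by = "mutation",
                         suffix = c(".true", ".fit"))
  expect_equal(nrow(j), nrow(st$truth$ddG))
  expect_lt(max(abs(j$ddGf.true - j$ddGf.fit)), 0.02)
  expect_lt(max(abs(j$ddGa.true - j$ddGa.fit)), 0.02)
  expect_equal(fit$model$wt_dGf, st$truth$wt_dGf, tolerance = 0.02)
  expect_equal(fit$model$wt_dGa, st$truth$wt_dGa, tolerance = 0.02)
})

test_that("fit is invariant to observation order", {
  st <- noiseless_study()
  set.seed(31)
  shuffled <- st$observations[sample(nrow(st$observations)), ]
  fit2 <- suppressWarnings(fit_energy_model(shuffled, n_states = 3))
  base <- tidy(noiseless_fit())
  perm <- tidy(fit2)
  expect_equal(base$mutation, perm$mutation)
  expect_lt(max(abs(base$ddGf - perm$ddGf)), 1e-6)
  expect_lt(max(abs(base$ddGa - perm$ddGa)), 1e-6)
})

test_that("data without activity-specific effects yields near-zero ddGa", {
  # all planted activity effects disabled: the three-state fit must not
  # invent them
  # moderate folding effects keep every variant inside the measurable
  # window, so the absence of activity-specific effects is fully testable
  cfg <- tiny_cfg(frac_allosteric = 0, n_activating_sites = 0,
                  allo_amplitude = 0, noise_frac = 0,
                  core_shape = 2, core_scale = 0.3)
  st <- synth_study(cfg, seed = 13, noise = FALSE)
  fit <- suppressWarnings(fit_energy_model(st$observations, n_states = 3))
  outside <- tidy(fit)
  expect_lt(max(abs(outside$ddGa)), 0.05)
})

test_that("degenerate inputs are rejected", {
  st <- noiseless_study()
  one_assay <- st$observations[st$observations$assay == "activity", ]
  expect_error(fit_energy_model(one_assay), "under-identified")
  bad <- st$observations
  bad$sigma[1] <- 0
  expect_error(fit_energy_model(bad), "sigma")
})

test_that("background exclusion removes a saturated background", {
  cfg <- tiny_cfg(saturated_background = TRUE)
  st <- synth_study(cfg, seed = 19, noise = TRUE)
  bgs <- unique(st$genotypes$background_id[st$genotypes$tile == 2])
  # the planted degenerate background is the most deleterious single
  tr2 <- st$truth$ddG[st$truth$ddG$position > 8, ]
  dead <- tr2$mutation[which.max(tr2$ddGf + tr2$ddGa)]
  expect_true(dead %in% bgs)
  fit <- suppressWarnings(
    fit_energy_model(st$observations, n_states = 3,
                     exclude_backgrounds = dead))
  expect_false(is.null(fit$excluded))
  # excluded background's observations do not constrain the fit
  expect_lt(fit$n_obs, nrow(st$observations))
})

test_that("loss trace never increases across accepted steps", {
  fit <- noiseless_fit()
  expect_true(all(diff(fit$loss_trace) <= 1e-8 * abs(fit$loss_trace[-1]) +
                    1e-12))
})

test_that("cross-validation folds partition the double mutants", {
  st <- noisy_small_study()
  cv <- suppressWarnings(crossvalidate(st$observations, n_states = 3,
                                       k_folds = 5, seed = 3))
  expect_equal(sort(unique(cv$folds$fold)), 1:5)
  expect_true(all(c("activity", "abundance", "all") %in% cv$folds$assay))
  expect_true(is.finite(cv$median_r2))
  expect_error(crossvalidate(st$observations[genotype_order(
    st$observations$genotype) < 2, ], k_folds = 10), "double")
})

test_that("noiseless cross-validation is near perfect", {
  st <- noiseless_study()
  cv <- suppressWarnings(crossvalidate(st$observations, n_states = 3,
                                       k_folds = 5, seed = 5))
  expect_gte(cv$median_r2, 0.999)
})

test_that("explainable variance follows its definition", {
  # homogeneous errors: Var = 1, mean sigma^2 = 0.2
  set.seed(8)
  y <- stats::rnorm(5000)
  y <- (y - mean(y)) / stats::sd(y)
  ev <- explainable_variance(y, rep(sqrt(0.2), 5000))
  expect_equal(ev$MEV, 0.8, tolerance = 1e-6)
  expect_equal(ev$FEV, 0.8, tolerance = 1e-6)
  # zero errors: everything is explainable
  ev0 <- explainable_variance(y, rep(1e-12, 5000))
  expect_equal(ev0$FEV, 1, tolerance = 1e-6)
  # technical variance exceeding total: clipped with a warning
  expect_warning(ev_bad <- explainable_variance(y, rep(2, 5000)), "clipped")
  expect_equal(ev_bad$MEV, 0)
  expect_equal(ev_bad$FEV, 0)
  # the top error quantile is discarded before estimation
  sig <- c(rep(0.1, 90), rep(10, 10))
  ev_f <- explainable_variance(stats::rnorm(100), sig)
  expect_equal(ev_f$n_retained, 90)
})

test_that("ensemble uncertainty behaves in the no-noise limit and grows with noise", {
  st0 <- noiseless_study()
  un0 <- suppressWarnings(estimate_uncertainty(st0$observations,
                                               n_replicates = 4, seed = 2))
  expect_true(all(un0$ddGf_sd <= 0.02))
  expect_true(all(un0$ddGa_sd <= 0.02))
  # determinism
  un0b <- suppressWarnings(estimate_uncertainty(st0$observations,
                                                n_replicates = 4, seed = 2))
  expect_identical(un0, un0b)
  # doubling the noise increases the median parameter sd
  cfg_lo <- tiny_cfg(noise_frac = 0.05)
  cfg_hi <- tiny_cfg(noise_frac = 0.1)
  st_lo <- synth_study(cfg_lo, seed = 23, noise = TRUE)
  st_hi <- synth_study(cfg_hi, seed = 23, noise = TRUE)
  un_lo <- suppressWarnings(estimate_uncertainty(st_lo$observations,
                                                 n_replicates = 4, seed = 2))
  un_hi <- suppressWarnings(estimate_uncertainty(st_hi$observations,
                                                 n_replicates = 4, seed = 2))
  expect_gt(stats::median(un_hi$ddGf_sd), stats::median(un_lo$ddGf_sd))
})

test_that("energy tables round-trip through the TSV interface", {
  fit <- noiseless_fit()
  e <- tidy(fit)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_tsv(e, path)
  back <- read_energy_tsv(path)
  expect_equal(back$ddGf_mean, e$ddGf, tolerance = 1e-9)
  expect_equal(back$mutation, e$mutation)
})

test_that("tidiers expose the fit in broom style", {
  fit <- noiseless_fit()
  td <- tidy(fit)
  expect_true(all(c("mutation", "ddGf", "ddGa") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_states, 3L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
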