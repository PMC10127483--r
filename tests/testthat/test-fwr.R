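test_that("noiseless 2x2 fixture is recovered to closed-form values", {
  fit <- fit_fw_ols(two_by_two_fixture(), "normal kernel number")
  expect_equal(fit$mu, 10, tolerance = 1e-10)
  expect_equal(unname(fit$g), c(1, -1), tolerance = 1e-10)
  expect_equal(unname(fit$b), c(0.5, -0.5), tolerance = 1e-10)
  expect_equal(unname(fit$h), c(2, -2), tolerance = 1e-10)
  expect_lt(fit$sse, 1e-18)
  expect_true(fit$converged)
})

test_that("identifiability constraints hold after any fit", {
  d <- population_design(30, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(), seed = 8)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  expect_lt(abs(sum(fit$h)), 1e-8)
  expect_lt(abs(mean(fit$b)), 1e-8)
  expect_lt(abs(mean(fit$g)), 1e-8)
})

test_that("least-squares objective is non-increasing across sweeps", {
  d <- population_design(40, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(sigma = 30), seed = 10)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  expect_true(all(diff(fit$sse_path) <= 1e-8 * max(1, fit$sse_path[1])))
})

test_that("parallel profiles give zero slopes and zero residual variance", {
  g <- c(L1 = 3, L2 = -1, L3 = 0.5, WT = 0)
  b <- c(L1 = 0, L2 = 0, L3 = 0, WT = 0)
  rec <- records_from_params(g, b, h = c(-3, 1, 2))
  fit <- fit_fw_ols(rec, "normal kernel number")
  expect_lt(max(abs(fit$b)), 1e-9)
  expect_lt(max(nonlinear_plasticity(fit)), 1e-16)
})

test_that("a constant line has slope zero (b = -1) and a tracking line slope one (b = 0)", {
  # L_flat is identical in every environment; L_track follows the
  # environment means exactly. The construction has mean(b) = 0, so the
  # identified scale coincides with the construction scale.
  h <- c(-4, 0, 4)
  rec <- rbind(
    records_from_params(c(A = 2, B = -2, WT = 0), c(A = 0.5, B = 0.5, WT = 0), h),
    records_from_params(c(L_flat = 1), c(L_flat = -1), h),
    records_from_params(c(L_track = 0), c(L_track = 0), h)
  )
  fit <- fit_fw_ols(rec, "normal kernel number")
  expect_equal(unname(1 + fit$b["L_flat"]), 0, tolerance = 1e-6)
  expect_equal(unname(1 + fit$b["L_track"]), 1, tolerance = 1e-6)
  expect_lt(unname(1 + fit$b["L_flat"]), unname(1 + fit$b["L_track"]))
})

test_that("lines seen in fewer than 2 environments are excluded with a warning", {
  rec <- two_by_two_fixture()
  singleton <- rec[1, ]
  singleton$line_id <- "L3"
  singleton$site <- "S1"
  expect_warning(fit <- fit_fw_ols(rbind(rec, singleton),
                                   "normal kernel number"),
                 "fewer than 2 environments")
  expect_false("L3" %in% names(fit$g))
})

test_that("single-environment data are refused", {
  rec <- two_by_two_fixture()
  expect_error(fit_fw_ols(rec[rec$site == "S1", ], "normal kernel number"),
               "unidentifiable")
})

test_that("moderate-noise simulation recovers g and b", {
  d <- population_design(67, 3, years = 2018, sites_per_year = 3,
                         blocks_per_site = 2)
  sim <- simulate_dataset(d, truth_config(sigma = 0.5 * 45), seed = 77)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  tr <- sim$truth$lines
  i <- match(names(fit$g), tr$line_id)
  expect_gte(stats::cor(tr$g[i], fit$g), 0.95)
  expect_gte(stats::cor(tr$b[i], fit$b), 0.75)
})

test_that("a quadratic responder shows elevated nonlinear plasticity", {
  set.seed(3)
  h <- seq(-6, 6, length.out = 7)
  h <- h - mean(h)
  g <- stats::setNames(stats::rnorm(20, 0, 2), paste0("L", 1:20))
  b <- stats::setNames(stats::rnorm(20, 0, 0.2), paste0("L", 1:20))
  b <- b - mean(b)
  rec <- records_from_params(c(g, WT = 0), c(b, WT = 0), h)
  quad <- rec$line_id == "L1"
  env_h <- h[match(rec$site, paste0("S", seq_along(h)))]
  rec$value[quad] <- 10 + 0.3 * env_h[quad]^2
  fit <- fit_fw_ols(rec, "normal kernel number")
  nl <- nonlinear_plasticity(fit)
  expect_true(all(nl >= 0))
  expect_gt(nl["L1"], stats::median(nl))
})

test_that("Gibbs sampler concentrates on the noiseless construction", {
  fit <- fit_fw_bayes(two_by_two_fixture(), "normal kernel number",
                      n_iter = 6000, burn_in = 2000, thin = 2, seed = 1)
  expect_equal(fit$mu, 10, tolerance = 0.05)
  expect_equal(unname(fit$g), c(1, -1), tolerance = 0.25)
  expect_equal(unname(fit$h), c(2, -2), tolerance = 0.25)
  expect_lt(abs(sum(fit$h)), 1e-8)
  expect_lt(abs(mean(fit$b)), 1e-8)
})

test_that("Gibbs chains are reproducible under a fixed seed", {
  d <- population_design(10, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(sigma = 20), seed = 2)
  f1 <- fit_fw_bayes(sim$records, "normal kernel number", n_iter = 500,
                     burn_in = 100, thin = 2, seed = 99)
  f2 <- fit_fw_bayes(sim$records, "normal kernel number", n_iter = 500,
                     burn_in = 100, thin = 2, seed = 99)
  expect_identical(f1$chain$g, f2$chain$g)
  expect_identical(f1$g, f2$g)
})

test_that("posterior means agree with least squares on moderate-noise data", {
  d <- population_design(50, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(sigma = 0.5 * 45), seed = 31)
  ols <- fit_fw_ols(sim$records, "normal kernel number")
  bay <- fit_fw_bayes(sim$records, "normal kernel number", n_iter = 4000,
                      burn_in = 1000, thin = 2, seed = 31)
  expect_gt(stats::cor(ols$g, bay$g[names(ols$g)]), 0.98)
  expect_gt(stats::cor(ols$b, bay$b[names(ols$b)]), 0.9)
})

test_that("posterior means are Monte-Carlo stable across seeds", {
  d <- population_design(25, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(sigma = 20), seed = 4)
  f1 <- fit_fw_bayes(sim$records, "normal kernel number", n_iter = 8000,
                     burn_in = 2000, thin = 2, seed = 1)
  f2 <- fit_fw_bayes(sim$records, "normal kernel number", n_iter = 8000,
                     burn_in = 2000, thin = 2, seed = 2)
  expect_lt(max(abs(f1$g - f2$g)) / stats::sd(f1$g), 0.1)
})

test_that("replicated observations are averaged before fitting", {
  rec <- two_by_two_fixture()
  jitter <- rbind(rec, rec)
  jitter$value <- jitter$value + rep(c(-1, 1), each = nrow(rec))
  fit <- fit_fw_ols(jitter, "normal kernel number")
  base <- fit_fw_ols(rec, "normal kernel number")
  expect_equal(fit$g, base$g, tolerance = 1e-8)
  expect_equal(fit$h, base$h, tolerance = 1e-8)
})
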