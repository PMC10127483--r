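test_that("zero-noise simulation reproduces the generative model exactly", {
  d <- population_design(1, 1, years = 2018, sites_per_year = 2,
                         blocks_per_site = 2)
  cfg <- truth_config(sigma = 0)
  sim <- simulate_dataset(d, cfg, seed = 3)
  tr <- sim$truth
  env_id <- paste(sim$records$year, sim$records$site, sim$records$block,
                  sep = ":")
  i <- match(sim$records$line_id, tr$lines$line_id)
  j <- match(env_id, tr$envs$env_id)
  expected <- tr$mu + tr$lines$g[i] + (1 + tr$lines$b[i]) * tr$envs$h[j]
  expect_equal(sim$records$value, expected, tolerance = 1e-12)
})

test_that("with b = 0 every line's profile is a constant offset from the environment means", {
  d <- population_design(4, 2, years = 2018)
  cfg <- truth_config(sd_b = 0, sigma = 0)
  sim <- simulate_dataset(d, cfg, seed = 5)
  wide <- stats::reshape(
    cbind(sim$records[c("line_id", "value")],
          env = paste(sim$records$site, sim$records$block)),
    idvar = "line_id", timevar = "env", direction = "wide"
  )
  m <- as.matrix(wide[, -1])
  centred <- m - rowMeans(m)
  # all rows identical after centring: profiles are parallel
  expect_lt(max(abs(sweep(centred, 2, centred[1, ]))), 1e-10)
})

test_that("identical seeds give identical datasets and truths", {
  d <- population_design(50, 3, years = 2018)
  s1 <- simulate_dataset(d, truth_config(), seed = 1)
  s2 <- simulate_dataset(d, truth_config(), seed = 1)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$lines, s2$truth$lines)
  s3 <- simulate_dataset(d, truth_config(), seed = 2)
  expect_false(identical(s1$records$value, s3$records$value))
})

test_that("truth satisfies its constraints and the design its environment count", {
  d <- population_design(10, c(1:10), years = c(2018, 2019),
                         sites_per_year = 3, blocks_per_site = 2)
  sim <- simulate_dataset(d, truth_config(), seed = 9)
  expect_equal(sum(sim$truth$envs$h), 0, tolerance = 1e-9)
  expect_equal(mean(sim$truth$lines$b), 0, tolerance = 1e-12)
  expect_true(all(sim$truth$lines$sigma >= 0))
  expect_equal(nrow(sim$truth$envs), 2 * 3 * 2)
  expect_equal(length(unique(paste(sim$records$year, sim$records$site,
                                   sim$records$block))), 12)
  # exactly one wild-type line
  expect_equal(sum(sim$truth$lines$material_class == "WT"), 1)
  expect_equal(sim$truth$lines$g[sim$truth$lines$line_id == "WT"], 0)
})

test_that("degenerate designs are refused", {
  expect_error(population_design(0), "n_genes")
  expect_error(population_design(3, events_per_gene = 11), "1..10")
  expect_error(population_design(3, years = 2018, sites_per_year = 1,
                                 blocks_per_site = 1), "2 environments")
})

test_that("outlier injection contaminates exactly the requested fraction", {
  d <- population_design(50, 2, years = 2018, sites_per_year = 5,
                         blocks_per_site = 2)
  sim <- simulate_dataset(d, truth_config(), seed = 11)
  n <- nrow(sim$records)
  out <- inject_outliers(sim$records, fraction = 0.05, magnitude = 3,
                         seed = 2)
  expect_equal(length(out$outlier_idx), round(0.05 * n))
  changed <- which(out$records$value != sim$records$value)
  expect_equal(sort(changed), out$outlier_idx)

  none <- inject_outliers(sim$records, fraction = 0, seed = 2)
  expect_identical(none$records, sim$records)
  expect_error(inject_outliers(sim$records, fraction = 0.5, seed = 2),
               "fraction")
})

test_that("injected outliers at magnitude 3 are caught by the 1.5 IQR filter", {
  d <- population_design(50, 2, years = 2018, sites_per_year = 5,
                         blocks_per_site = 2)
  sim <- simulate_dataset(d, truth_config(), seed = 13)
  out <- inject_outliers(sim$records, fraction = 0.05, magnitude = 3,
                         seed = 4)
  res <- filter_outliers_iqr(out$records$value)
  flagged <- res$removed_idx
  expect_gte(mean(out$outlier_idx %in% flagged), 0.95)
})

test_that("skewed trait generator produces a right-skewed, clipped trait", {
  d <- population_design(100, 3, years = 2018, sites_per_year = 3,
                         blocks_per_site = 3)
  rec <- simulate_skewed_trait(d, zero_inflation = 0.7, seed = 1)
  v <- rec$value
  expect_gt(length(v), 2000)
  skew <- mean((v - mean(v))^3) / stats::sd(v)^3
  expect_gt(skew, 0)
  expect_gte(mean(v == 0), 0.5) # point mass near zero

  all_zero <- simulate_skewed_trait(d, zero_inflation = 1, seed = 1)
  expect_true(all(all_zero$value == 0))

  prop <- simulate_skewed_trait(population_design(5), zero_inflation = 0.3,
                                seed = 2,
                                trait_name = "proportion of bald tip area",
                                scale = 0.5)
  expect_gte(min(prop$value), 0)
  expect_lte(max(prop$value), 1)
})

test_that("zero-noise simulation is recovered exactly by the least-squares fit", {
  d <- population_design(10, 2, years = 2018)
  sim <- simulate_dataset(d, truth_config(sigma = 0), seed = 21)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  tr <- sim$truth
  i <- match(names(fit$g), tr$lines$line_id)
  j <- match(names(fit$h), tr$envs$env_id)
  # compare on the identified scale: the fit centres g into mu
  g_true <- tr$lines$g[i] - mean(tr$lines$g[i])
  mu_true <- tr$mu + mean(tr$lines$g[i])
  expect_lt(max(abs(fit$g - g_true)), 1e-8)
  expect_lt(max(abs(fit$b - tr$lines$b[i])), 1e-8)
  expect_lt(max(abs(fit$h - tr$envs$h[j])), 1e-8)
  expect_lt(abs(fit$mu - mu_true), 1e-8)
})
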