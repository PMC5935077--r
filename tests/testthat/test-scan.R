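sites <- marsh_sites()

test_that("environmental deltas are ln-ratios, antisymmetric and zero at home", {
  expect_equal(env_delta("WB", "AB", "air_temp", sites), log(24.2) - log(17.1))
  expect_equal(env_delta("WB", "AB", "air_temp", sites), 0.3473, tolerance = 1e-4)
  expect_equal(env_delta("AB", "WB", "air_temp", sites),
               -env_delta("WB", "AB", "air_temp", sites))
  expect_equal(env_delta("WB", "WB", "salinity", sites), 0)
  for (v in c("air_temp", "pct_nitrogen", "salinity")) {
    expect_equal(env_delta("PI", "RC", v, sites), -env_delta("RC", "PI", v, sites))
  }

  # geographic distance: symmetric, zero at home, ln(1 + km) by default
  g <- geographic_distance_matrix(sites)
  expect_equal(env_delta("WB", "PI", "geographic_distance", sites),
               log1p(g["WB", "PI"]))
  expect_equal(env_delta("PI", "WB", "geographic_distance", sites),
               env_delta("WB", "PI", "geographic_distance", sites))
  expect_equal(env_delta("WB", "WB", "geographic_distance", sites), 0)
  expect_equal(
    env_delta("WB", "PI", "geographic_distance", sites, geodist_convention = "raw_symmetric"),
    g["WB", "PI"]
  )
  expect_error(env_delta("WB", "XX", "air_temp", sites), "XX")
})

test_that("regression datasets pair per-sample shares with deltas", {
  meta <- sample_metadata(tibble::tibble(
    sample_id = c("t1", "r1", "p1"),
    origin_site = c("WB", "AB", "AB"),
    destination_site = c("AB", "AB", "AB"),
    sample_class = c("transplant", "replant_control", "pristine_control"),
    replicate = 1
  ))
  tbl <- otu_table(tibble::tibble(otu_id = "v", t1 = 100, r1 = 850, p1 = 50))
  ds <- assemble_regression_dataset(tbl, meta, sites, "v", "air_temp")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$x[ds$sample_id == "t1"], 0.3473, tolerance = 1e-4)
  expect_equal(ds$y[ds$sample_id == "t1"], 0.10)
  expect_equal(ds$x[ds$sample_id %in% c("r1", "p1")], c(0, 0)) # controls at x = 0

  # the full 88-sample design yields exactly 88 points
  cfg <- simulation_config(n_otus = 40, depth = 800, seed = 4)
  sim <- simulate_dataset(cfg)
  full <- assemble_regression_dataset(sim$otu_table, sim$metadata, sites,
                                      sim$otu_table$otu_id[1], "pct_nitrogen")
  expect_equal(nrow(full), 88)
})

test_that("the least-squares slope test matches an lm oracle", {
  exact <- linear_regression_test(data.frame(x = 1:6, y = 2 * (1:6) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  expect_true(exact$degenerate)
  expect_equal(exact$p_value, 0)

  flat <- linear_regression_test(data.frame(x = 1:5, y = rep(3, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  withr::local_seed(9)
  for (i in 1:5) {
    pts <- data.frame(x = stats::rnorm(10), y = stats::rnorm(10))
    got <- linear_regression_test(pts)
    ref <- summary(stats::lm(y ~ x, pts))
    expect_equal(got$slope, unname(ref$coefficients["x", "Estimate"]), tolerance = 1e-10)
    expect_equal(got$intercept, unname(ref$coefficients["(Intercept)", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(got$r_squared, ref$r.squared, tolerance = 1e-10)
    expect_equal(got$p_value, unname(ref$coefficients["x", "Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_error(linear_regression_test(data.frame(x = rep(1, 5), y = 1:5)), "zero variance")
})

test_that("Bonferroni correction divides the family alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.001, 253348), 4), 3.947e-9)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.001, 4), 0.00025)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("the scan ranks a strongly planted indicator first and flags it", {
  ind <- indicator_spec(1, "air_temp", -1.4)
  cfg <- simulation_config(indicators = ind, depth = 5000, seed = 42)
  sim <- simulate_dataset(cfg)
  scan <- quiet_scan(sim$otu_table, sim$metadata, sim$sites)
  top <- scan$results[1, ]
  expect_equal(top$otu_id, sim$ground_truth$otu_id)
  expect_equal(top$variable, "air_temp")
  expect_true(top$passes)
  expect_lt(top$slope, 0)
  expect_equal(glance(scan)$n_tests, scan$summary$n_otus_tested * 4)
  expect_equal(scan$summary$corrected_alpha,
               0.001 / (scan$summary$n_otus_tested * 4))
})

test_that("reversing every transplant negates directional slopes exactly", {
  cfg <- simulation_config(n_otus = 60, depth = 1500, seed = 11)
  sim <- simulate_dataset(cfg)
  rev_meta <- sim$metadata
  tr <- rev_meta$sample_class == "transplant"
  tmp <- rev_meta$origin_site[tr]
  rev_meta$origin_site[tr] <- rev_meta$destination_site[tr]
  rev_meta$destination_site[tr] <- tmp

  fwd <- quiet_scan(sim$otu_table, sim$metadata, sim$sites,
                    variables = c("air_temp", "pct_nitrogen", "salinity"))
  bwd <- quiet_scan(sim$otu_table, rev_meta, sim$sites,
                    variables = c("air_temp", "pct_nitrogen", "salinity"))
  key <- function(x) paste(x$otu_id, x$variable)
  b <- bwd$results[match(key(fwd$results), key(bwd$results)), ]
  expect_equal(b$slope, -fwd$results$slope, tolerance = 1e-12)
  expect_equal(b$r_squared, fwd$results$r_squared, tolerance = 1e-12)
  expect_equal(b$p_value, fwd$results$p_value, tolerance = 1e-12)
})

test_that("pass sets nest as the family alpha grows", {
  cfg <- simulation_config(n_otus = 80, depth = 2000, seed = 3)
  sim <- simulate_dataset(cfg)
  strict <- quiet_scan(sim$otu_table, sim$metadata, sim$sites, alpha = 1e-4)
  loose <- quiet_scan(sim$otu_table, sim$metadata, sim$sites, alpha = 0.01)
  expect_lt(strict$summary$corrected_alpha, loose$summary$corrected_alpha)
  key <- function(s) with(s$results[s$results$passes, ], paste(otu_id, variable))
  expect_true(all(key(strict) %in% key(loose)))
})
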