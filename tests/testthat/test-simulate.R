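test_that("the factorial design enumerates cells, controls and drops", {
  sites <- marsh_sites()
  expect_equal(nrow(build_design(sites)), 90) # 5*5*3 + 5*3
  expect_equal(nrow(build_design(sites, dropped_cells = c("PI_to_JR_2", "WB_to_AB_3"))), 88)

  two <- build_design(c("A", "B"), replicates_per_cell = 1, n_pristine_per_site = 0)
  expect_equal(nrow(two), 4)
  expect_equal(sum(two$sample_class == "transplant"), 2)
  expect_equal(sum(two$sample_class == "replant_control"), 2)

  expect_error(build_design(sites, dropped_cells = "ZZ_to_WB_1"), "not in the design")
  expect_error(build_design("A"), "2 sites")
})

test_that("site profiles are simplexes, deterministic, and structured by region", {
  cfg0 <- simulation_config(region_effect_sigma = 0, site_effect_sigma = 0,
                            indicators = dplyr::tibble(), seed = 1)
  prof0 <- simulate_site_profiles(cfg0)
  wide0 <- tidyr::pivot_wider(prof0, names_from = site, values_from = theta)
  expect_true(all(abs(as.matrix(wide0[, -1]) - wide0$WB) < 1e-12)) # identical sites
  sums <- dplyr::summarise(dplyr::group_by(prof0, site), s = sum(theta))
  expect_equal(sums$s, rep(1, 5), tolerance = 1e-12)

  cfg1 <- simulation_config(seed = 5)
  expect_identical(simulate_site_profiles(cfg1), simulate_site_profiles(cfg1))

  # stronger region effect: expected profiles are closer within region
  cfg2 <- simulation_config(region_effect_sigma = 0.6, site_effect_sigma = 0.1,
                            indicators = dplyr::tibble(), seed = 2)
  m <- t(marshtransplant:::profiles_to_matrix(simulate_site_profiles(cfg2)))
  bc <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
  reg <- marsh_regions()[rownames(m)]
  within <- c(); between <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    v <- bc(m[i, ], m[j, ])
    if (reg[i] == reg[j]) within <- c(within, v) else between <- c(between, v)
  }
  expect_lt(mean(within), mean(between))
})

test_that("simulated counts sum to depth and converge to the expected mixture", {
  cfg <- simulation_config(n_otus = 60, depth = 2000, seed = 9)
  sim <- simulate_dataset(cfg)
  expect_true(all(colSums(otu_counts(sim$otu_table)) == cfg$depth))
  expect_equal(nrow(sim$metadata), 88)

  # pi = 0, no indicators, noise switched off: transplants match theta_origin
  # within the multinomial standard-error bound
  cfg0 <- simulation_config(n_otus = 50, depth = 4000, overdispersion = 1e9,
                            invasion_fraction = 0, indicators = dplyr::tibble(),
                            seed = 21)
  sim0 <- simulate_dataset(cfg0)
  theta <- marshtransplant:::profiles_to_matrix(sim0$profiles)
  counts <- otu_counts(sim0$otu_table)
  tr <- sim0$metadata[sim0$metadata$sample_class == "transplant", ]
  for (s in tr$sample_id[1:10]) {
    th <- theta[, tr$origin_site[tr$sample_id == s]]
    dev <- abs(counts[, s] / cfg0$depth - th)
    # 4-sigma multinomial bound plus a small-count floor, jointly over OTUs
    bound <- 4 * sqrt(th * (1 - th) / cfg0$depth) + 5 / cfg0$depth
    expect_true(all(dev <= bound))
  }

  # pi = 1: the expected transplant profile is theta_destination
  cfg1 <- simulation_config(n_otus = 50, depth = 4000, overdispersion = 1e9,
                            invasion_fraction = 1, indicators = dplyr::tibble(),
                            seed = 22)
  sim1 <- simulate_dataset(cfg1)
  theta1 <- marshtransplant:::profiles_to_matrix(sim1$profiles)
  counts1 <- otu_counts(sim1$otu_table)
  tr1 <- sim1$metadata[sim1$metadata$sample_class == "transplant", ]
  s <- tr1$sample_id[1]
  th <- theta1[, tr1$destination_site[1]]
  expect_true(all(abs(counts1[, s] / cfg1$depth - th) <=
                    4 * sqrt(th * (1 - th) / cfg1$depth) + 5 / cfg1$depth))
})

test_that("a planted indicator multiplies its OTU by exp(beta * delta) before renormalisation", {
  cfg <- simulation_config(n_otus = 30, depth = 20000, overdispersion = 1e9,
                           invasion_fraction = 0,
                           indicators = indicator_spec(1, "air_temp", 2),
                           seed = 33)
  sim <- simulate_dataset(cfg)
  theta <- marshtransplant:::profiles_to_matrix(sim$profiles)[, "WB"]
  fold <- exp(2 * (log(24.2) - log(17.1))) # WB -> AB with beta = 2
  expected <- theta
  expected[1] <- expected[1] * fold
  expected <- expected / sum(expected)
  counts <- otu_counts(sim$otu_table)[, "WB_to_AB_1"]
  expect_equal(unname(counts[1] / cfg$depth), unname(expected[1]),
               tolerance = 4 * sqrt(expected[1] / cfg$depth) / expected[1])

  # swapping origin and destination inverts the multiplier (antisymmetry)
  d_fwd <- env_delta("WB", "AB", "air_temp", marsh_sites())
  d_bwd <- env_delta("AB", "WB", "air_temp", marsh_sites())
  expect_equal(exp(2 * d_fwd) * exp(2 * d_bwd), 1, tolerance = 1e-12)
})

test_that("simulation is bit-reproducible and validates its inputs", {
  cfg <- simulation_config(n_otus = 25, depth = 500, seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(otu_counts(s1$otu_table), otu_counts(s2$otu_table))

  bad_design <- sample_metadata(tibble::tibble(
    sample_id = "x", origin_site = "QQ", destination_site = "QQ",
    sample_class = "replant_control", replicate = 1
  ))
  expect_error(simulate_dataset(cfg, design = bad_design), "QQ")
  expect_error(simulation_config(invasion_fraction = 1.2), "invasion_fraction")
  expect_error(simulation_config(overdispersion = 0), "overdispersion")
  expect_error(simulation_config(indicators = indicator_spec(500, "salinity", 1)),
               "otu_index")
})
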