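# A hand-built dissimilarity geometry over two sites (A, B) with three
# pristine controls each lets every classifier branch be reached exactly.
outcome_fixture <- function(d_o, d_d, base_a = 0.10, base_b = 0.10, sep = 0.60) {
  ids <- c("t1", paste0("A_p", 1:3), paste0("B_p", 1:3))
  m <- matrix(0, 7, 7, dimnames = list(ids, ids))
  a <- ids[2:4]; b <- ids[5:7]
  m[a, a] <- base_a; m[b, b] <- base_b
  m[a, b] <- sep; m[b, a] <- sep
  m["t1", a] <- d_o; m[a, "t1"] <- d_o
  m["t1", b] <- d_d; m[b, "t1"] <- d_d
  diag(m) <- 0
  meta <- sample_metadata(tibble::tibble(
    sample_id = ids,
    origin_site = c("A", rep("A", 3), rep("B", 3)),
    destination_site = c("B", rep("A", 3), rep("B", 3)),
    sample_class = c("transplant", rep("pristine_control", 6)),
    replicate = c(1, 1:3, 1:3)
  ))
  list(bc = dist_matrix(m), meta = meta)
}

test_that("control statistics average within- and between-cloud dissimilarities", {
  f <- outcome_fixture(0.1, 0.6)
  stats <- control_statistics(f$bc, f$meta)
  expect_equal(stats$baselines$baseline, c(0.10, 0.10))
  expect_equal(stats$separations["A", "B"], 0.60)

  # hand-computed mean of three distinct pairwise values
  m <- unclass(f$bc)
  m["A_p1", "A_p2"] <- m["A_p2", "A_p1"] <- 0.2
  m["A_p1", "A_p3"] <- m["A_p3", "A_p1"] <- 0.3
  m["A_p2", "A_p3"] <- m["A_p3", "A_p2"] <- 0.7
  stats2 <- control_statistics(dist_matrix(m), f$meta)
  expect_equal(stats2$baselines$baseline[stats2$baselines$site == "A"], mean(c(0.2, 0.3, 0.7)))

  short <- f$meta[!f$meta$sample_id %in% c("A_p1", "A_p2"), ]
  expect_error(control_statistics(f$bc, short), "'A'")
})

test_that("the four outcome calls partition the distance geometry", {
  call_of <- function(d_o, d_d, ...) {
    f <- outcome_fixture(d_o, d_d, ...)
    classify_outcomes(f$bc, f$meta)$call
  }
  expect_equal(call_of(0.05, 0.60), "no_change")       # near origin cloud
  expect_equal(call_of(0.60, 0.05), "total_adoption")  # near destination cloud
  expect_equal(call_of(0.40, 0.35), "host_shift")      # between, outside both bands
  expect_equal(call_of(0.80, 0.75), "random_shift")    # beyond the separation
  # ties favour no change; the call set is always a single valid level
  expect_equal(call_of(0.12, 0.12), "no_change")
  withr::local_seed(4)
  for (i in 1:20) {
    cl <- call_of(stats::runif(1, 0, 0.9), stats::runif(1, 0, 0.9))
    expect_length(cl, 1)
    expect_true(cl %in% c("no_change", "total_adoption", "host_shift", "random_shift"))
  }
})

test_that("calls are re-derivable from the stored distances and tau", {
  f <- outcome_fixture(0.35, 0.4)
  calls <- classify_outcomes(f$bc, f$meta, tau = 1.5)
  row <- calls[1, ]
  rederive <- function(r, tau) {
    if (r$d_origin <= tau * r$baseline_origin && r$d_origin <= r$d_destination) "no_change"
    else if (r$d_destination <= tau * r$baseline_destination &&
             r$d_destination < r$d_origin) "total_adoption"
    else if (max(r$d_origin, r$d_destination) <= r$separation) "host_shift"
    else "random_shift"
  }
  expect_equal(row$call, rederive(row, 1.5))
  # tau widens the no-change band
  expect_equal(classify_outcomes(f$bc, f$meta, tau = 6)$call, "no_change")
})

test_that("half-mixed communities are called host shifts when noise is off", {
  n_host <- vapply(1:5, function(sd) {
    # noise off and sites well separated: the mixture sits clearly outside
    # both tolerance bands but inside the between-cloud separation
    cfg <- simulation_config(n_otus = 100, depth = 10000, overdispersion = 1e9,
                             site_effect_sigma = 1.2, region_effect_sigma = 0.2,
                             invasion_fraction = 0.5, indicators = dplyr::tibble(),
                             seed = sd)
    sim <- simulate_dataset(cfg)
    calls <- classify_outcomes(bray_curtis(sim$otu_table), sim$metadata)
    mean(calls$call == "host_shift")
  }, numeric(1))
  expect_gt(mean(n_host), 0.5)
})

test_that("total adoption is monotone in the invasion fraction", {
  frac_ta <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    mean(vapply(1:6, function(sd) {
      cfg <- simulation_config(n_otus = 80, depth = 2000, overdispersion = 5000,
                               invasion_fraction = p, indicators = dplyr::tibble(),
                               seed = sd)
      sim <- simulate_dataset(cfg)
      calls <- classify_outcomes(bray_curtis(sim$otu_table), sim$metadata)
      mean(calls$call == "total_adoption")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac_ta) >= -0.02))
  expect_lt(frac_ta[1], 0.1)
  expect_gt(frac_ta[5], 0.9)
})

test_that("outcome summaries report modal calls and ties per design cell", {
  calls <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    origin_site = c("A", "A", "A", "B", "B", "B"),
    destination_site = c("B", "B", "B", "A", "A", "A"),
    call = c("no_change", "no_change", "host_shift",
             "total_adoption", "host_shift", "no_change")
  )
  s <- outcome_summary(calls)
  ab <- s[s$origin_site == "A", ]
  expect_equal(ab$modal_call, "no_change")
  expect_equal(ab$n_no_change, 2)
  expect_equal(ab$n_host_shift, 1)
  ba <- s[s$origin_site == "B", ]
  expect_equal(ba$modal_call, "tie")

  uniform <- dplyr::mutate(calls, call = "no_change")
  expect_true(all(outcome_summary(uniform)$modal_call == "no_change"))
})

test_that("the classifier is invariant to sample order and OTU relabelling", {
  cfg <- simulation_config(n_otus = 40, depth = 1000, seed = 13)
  sim <- simulate_dataset(cfg)
  calls <- classify_outcomes(sim$otu_table, sim$metadata)

  perm <- sample(nrow(sim$metadata))
  shuffled_meta <- sim$metadata[perm, ]
  tbl2 <- sim$otu_table[sample(nrow(sim$otu_table)), ]
  tbl2$otu_id <- paste0("renamed_", tbl2$otu_id)
  calls2 <- classify_outcomes(tbl2, shuffled_meta)
  calls2 <- calls2[match(calls$sample_id, calls2$sample_id), ]
  expect_equal(calls2$call, calls$call)
  expect_equal(calls2$d_origin, calls$d_origin, tolerance = 1e-12)
})
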