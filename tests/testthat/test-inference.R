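# Binomial machinery, resampling inference, and sensitivity arithmetic.

test_that("binomial path test equals a brute-force tail sum", {
  for (n in c(1, 5, 12, 25)) {
    for (ti in c(0, 1, floor(n / 2), n)) {
      tv <- n - ti
      for (r0 in c(0.5, 1, 0.42)) {
        ns <- null_spec(r0)
        oracle <- sum(stats::dbinom(ti:n, n, ns$p))
        expect_equal(binomial_path_test(ti, tv, ns)$p_value, oracle,
                     tolerance = 1e-12,
                     label = sprintf("ti=%d tv=%d r0=%g", ti, tv, r0))
      }
    }
  }
  # zero transitions: the upper tail is everything
  expect_equal(binomial_path_test(0, 10)$p_value, 1)
})

test_that("path test and expectation reproduce the published numbers", {
  expect_equal(signif(binomial_path_test(28, 27)$p_value, 2), 5.3e-3)
  expect_equal(signif(binomial_path_test(16, 16)$p_value, 3), 3.77e-2)
  expect_equal(round(expected_ti_paths(55), 1), 18.3)
  expect_equal(expected_ti_paths(63), 21)
  expect_equal(expected_ti_paths(0), 0)
})

test_that("Clopper-Pearson ratio intervals behave and match printed endpoints", {
  ci <- binomial_ratio_ci(43, 20)
  expect_equal(ci$ratio, 43 / 20)
  # printed endpoints 1.3 and 3.8; method ambiguity allows +/-0.1 at rounding
  expect_lte(abs(round(ci$ci_low, 1) - 1.3), 0.1 + 1e-9)
  expect_lte(abs(round(ci$ci_high, 1) - 3.8), 0.1 + 1e-9)
  ci2 <- binomial_ratio_ci(28, 27)
  expect_lte(abs(round(ci2$ci_low, 2) - 0.62), 0.1 + 1e-9)
  expect_lte(abs(round(ci2$ci_high, 1) - 1.8), 0.1 + 1e-9)
  # no transversions: upper endpoint is infinite
  expect_identical(binomial_ratio_ci(7, 0)$ci_high, Inf)
  # endpoints monotone in level
  wide <- binomial_ratio_ci(28, 27, level = 0.99)
  expect_lt(wide$ci_low, ci2$ci_low)
  expect_gt(wide$ci_high, ci2$ci_high)
})

test_that("bootstrap CIs are reproducible and invariant to path order", {
  d <- load_fixture("natural")
  a <- bootstrap_event_ratio(d, n_boot = 2000, seed = 7)
  b <- bootstrap_event_ratio(d, n_boot = 2000, seed = 7)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  shuffled <- parallelism_dataset(as.data.frame(d)[rev(seq_len(nrow(d))), ],
                                  name = "natural")
  s <- bootstrap_event_ratio(shuffled, n_boot = 2000, seed = 7)
  expect_identical(a$ci_low, s$ci_low)
  expect_identical(a$ci_high, s$ci_high)
  # the observed ratio lies inside the percentile interval
  expect_lte(a$ci_low, a$ratio)
  expect_gte(a$ci_high, a$ratio)
})

test_that("bootstrap on a single path is degenerate at that path's ratio", {
  one <- make_dataset(c(3), integer(0))
  ci <- bootstrap_event_ratio(one, n_boot = 100, seed = 1)
  expect_identical(ci$ci_low, Inf)
  expect_identical(ci$ci_high, Inf)
})

test_that("randomization p-value matches the exhaustive-enumeration oracle", {
  set.seed(20)
  for (rep in 1:3) {
    n_ti <- sample(1:6, 1)
    n_tv <- sample(1:6, 1)
    d <- make_dataset(sample(2:12, n_ti, replace = TRUE),
                      sample(2:12, n_tv, replace = TRUE))
    fr <- aggregate_paths(d)
    obs <- fr$event_ratio
    exact <- oracle_randomization_tail(d$n_events, obs, 1 / 3)
    mc <- randomization_event_test(d, n_reps = 2e5, seed = 100 + rep)
    se <- sqrt(exact * (1 - exact) / 2e5)
    expect_lt(abs(mc$p_value - exact), 4 * se + 1e-5,
              label = sprintf("replicate %d (exact %.4g)", rep, exact))
    # add-one convention lower-bounds the p-value
    expect_gte(mc$p_value, 1 / (2e5 + 1))
  }
})

test_that("an all-transversion dataset cannot show transition enrichment", {
  d <- make_dataset(integer(0), c(4, 3, 2))
  expect_equal(randomization_event_test(d, n_reps = 1000, seed = 1)$p_value, 1)
})

test_that("cutoff scan reproduces published count and ratio cells and handles exhaustion", {
  for (name in c("experimental", "natural")) {
    pub <- if (name == "experimental") published_experimental_cutoffs()
           else published_natural_cutoffs()
    scan <- cutoff_scan(load_fixture(name), k_max = 8, n_reps = 100, seed = 1)
    expect_equal(scan$ti_paths, pub$ti_paths)
    expect_equal(scan$tv_paths, pub$tv_paths)
    expect_equal(scan$ti_events, pub$ti_events)
    expect_equal(scan$tv_events, pub$tv_events)
    # ratio cells at printed (1-decimal) rounding
    expect_true(all(abs(scan$path_ratio - pub$path_ratio) <= 0.05 + 1e-9))
    expect_true(all(abs(scan$event_ratio - pub$event_ratio) <= 0.05 + 1e-9))
  }
  # a cutoff beyond the largest event count empties the table
  scan <- cutoff_scan(make_dataset(c(2, 3), c(2)), k_max = 5, n_reps = 100)
  expect_equal(scan$ti_paths[scan$cutoff == 5], 0)
  expect_true(is.na(scan$path_ratio[scan$cutoff == 5]))
  expect_true(is.na(scan$event_p[scan$cutoff == 5]))
})

test_that("published event-level p-values are recovered to Monte-Carlo tolerance", {
  published_event_p <- list(
    experimental = c(1e-5, 1e-5, 1e-5, 1.7e-5, 1.41e-4, 2.32e-4, 4.38e-4),
    natural = c(3.05e-3, 9.28e-3, 8.5e-3, 1.63e-2, 3.58e-2, 3.49e-2, 6.18e-2))
  upper_bound_only <- list(
    experimental = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    natural = rep(FALSE, 7))
  n_reps <- 2e5
  for (name in c("experimental", "natural")) {
    scan <- cutoff_scan(load_fixture(name), k_max = 8, n_reps = n_reps,
                        seed = 11)
    pub <- published_event_p[[name]]
    for (i in seq_along(pub)) {
      if (upper_bound_only[[name]][i]) {
        # printed as "< 1e-5": only an upper bound is asserted
        expect_lte(scan$event_p[i], 1e-4)
      } else {
        band <- 4 * sqrt(pub[i] * (1 - pub[i]) / n_reps) + 0.05 * pub[i]
        expect_lt(abs(scan$event_p[i] - pub[i]), band,
                  label = sprintf("%s cutoff %d", name, i + 1))
      }
    }
  }
})

test_that("contamination arithmetic floors at zero and recovers published thresholds", {
  r <- contamination_threshold(43, 20)
  expect_equal(r$n_contaminants, 33)
  expect_equal(c(r$genuine_ti, r$genuine_tv), c(10, 20))
  r2 <- contamination_threshold(28, 27)
  expect_equal(r2$n_contaminants, 14.5)
  expect_equal(c(r2$genuine_ti, r2$genuine_tv), c(13.5, 27))
  expect_equal(round(100 * r2$contaminant_fraction, 1), 26.4)
  expect_equal(contamination_threshold(10, 20)$n_contaminants, 0)
})

test_that("rule-of-three bound", {
  expect_equal(round(100 * zero_count_upper_bound(241), 1), 1.2)
  expect_equal(zero_count_upper_bound(3), 1)
  expect_equal(zero_count_upper_bound(300), 0.01)
  expect_error(zero_count_upper_bound(0))
})
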