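test_that("centre-of-mass CF weights channels by response", {
  resp <- matrix(0, 10, 8)
  resp[3, ] <- 1
  expect_equal(center_of_mass_cf(resp), 3)
  resp2 <- matrix(0, 10, 8); resp2[2, ] <- 1; resp2[4, ] <- 1
  expect_equal(center_of_mass_cf(resp2), 3)
  resp3 <- matrix(0, 10, 8); resp3[2, 1] <- 1; resp3[4, 1] <- 3
  expect_equal(center_of_mass_cf(resp3), 3.5)
  expect_equal(center_of_mass_cf(10 * resp3), 3.5)  # scale invariance
  expect_error(center_of_mass_cf(matrix(0, 10, 8)), "undefined")
})

test_that("circular-safe CF agrees off-boundary and handles ring wrap", {
  resp <- matrix(0, 10, 8); resp[4, ] <- 2; resp[5, ] <- 1
  expect_equal(fra_cf(resp), center_of_mass_cf(resp))
  # response wrapping the seam: mass at channels 10 and 1
  wrapped <- matrix(0, 10, 8); wrapped[10, ] <- 1; wrapped[1, ] <- 1
  expect_equal(fra_cf(wrapped), 10.5)
})

test_that("CF differences convert to octaves on the shorter circular arc", {
  p <- model_params()
  expect_equal(cf_difference_octaves(4, 4, p), 0)
  expect_equal(cf_difference_octaves(6, 4, p), 1.0)   # 2 channels = 1 octave
  expect_equal(cf_difference_octaves(1, 9, p), -1.0)  # wrapped arc of 2
  expect_equal(cf_difference_octaves(9, 1, p), 1.0)   # antisymmetric
  expect_equal(cf_difference_octaves(1, 6, p), 2.5)   # half-ring tie positive
  expect_equal(cf_difference_octaves(6, 1, p), 2.5)
})

test_that("model FRAs are monotone in intensity and localised at the RF", {
  p <- model_params()
  n <- p$n_channels
  zero <- synaptic_weights(rep(0.01, n), rep(0.01, n), rep(0, n), rep(0, n))
  fra0 <- measure_model_fra(zero, p)
  expect_equal(max(fra0$on_resp), 0)                 # subthreshold everywhere
  w <- synaptic_weights(c(0, 0, 2, rep(0, 7)), c(0, 2, rep(0, 8)),
                        rep(0, n), rep(0, n))
  fra <- measure_model_fra(w, p)
  expect_true(all(apply(fra$on_resp, 1, diff) >= -1e-12))
  expect_equal(which.max(fra$on_resp[, 8]), 3)       # ON RF at channel 3
  expect_equal(which.max(fra$off_resp[, 8]), 2)
  expect_equal(fra$intensity_axis, seq(19.5, 65, length.out = 8))
})

test_that("sweep selectivity is antisymmetric under channel reflection", {
  p <- model_params()
  n <- p$n_channels
  set.seed(5)
  for (k in 1:5) {
    w_on <- runif(n)^3; w_on <- 2 * w_on / sum(w_on)
    w_off <- runif(n)^3; w_off <- 2 * w_off / sum(w_off)
    w <- synaptic_weights(w_on, w_off, rep(0, n), rep(0, n))
    wr <- synaptic_weights(rev(w_on), rev(w_off), rep(0, n), rep(0, n))
    a <- measure_sweep_selectivity(w, p)
    b <- measure_sweep_selectivity(wr, p)
    expect_equal(a$rate_up, b$rate_down, tolerance = 1e-9)
    expect_equal(a$selectivity, -b$selectivity, tolerance = 1e-9)
    expect_true(abs(a$selectivity) <= 1)
  }
  silent <- synaptic_weights(rep(0.001, n), rep(0.001, n),
                             rep(0, n), rep(0, n))
  s <- measure_sweep_selectivity(silent, p)
  expect_true(s$undefined)
  expect_equal(s$selectivity, 0)
})

test_that("adjacent ON/OFF arrangement sets sweep direction preference", {
  p <- model_params()
  n <- p$n_channels
  delta <- function(c) { v <- rep(0, n); v[c] <- 2; v }
  on_higher <- synaptic_weights(delta(6), delta(5), rep(0, n), rep(0, n))
  off_higher <- synaptic_weights(delta(5), delta(6), rep(0, n), rep(0, n))
  expect_gt(measure_sweep_selectivity(on_higher, p)$selectivity, 0.1)
  expect_lt(measure_sweep_selectivity(off_higher, p)$selectivity, -0.1)
})

test_that("population statistics match brute-force references", {
  set.seed(9)
  for (k in 1:50) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = 0.3)
    ks <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(unname(ks$statistic), reference_ks(a, b),
                 tolerance = 1e-12)
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(cor(x, y), reference_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("divergence statistics and correlations behave on constructed populations", {
  p <- tiny_params()
  pop <- run_population(6, p, "single_channel", master_seed = 10,
                        snapshot_steps = c(0, 2000))
  same <- population_divergence_stats(pop, 0, 0)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$mean_a, same$mean_b)
  st <- population_divergence_stats(pop, 0, 2000)
  expect_true(st$ks_statistic >= 0 && st$ks_statistic <= 1)
  expect_true(st$p_value >= 0 && st$p_value <= 1)
})

test_that("a perfectly linear CF-selectivity relation gives |r| = 1", {
  # construct records-free check through the public correlation math:
  # the function is exercised end-to-end elsewhere; here validate the
  # Pearson fallback against a planted linear relation
  x <- seq(-0.5, 0.5, length.out = 20)
  y <- -0.8 * x
  expect_equal(reference_pearson(x, y), -1, tolerance = 1e-12)
})
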