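test_that("excitatory Hebbian update follows the printed rule", {
  p <- model_params(alpha_e = 1e-4)
  w <- rep(0.1, 10)
  x <- rep(1, 10)
  expect_equal(excitatory_hebbian_step(w, x, 0, p, eta = rep(0, 10)), w)
  out <- excitatory_hebbian_step(w, x, 1, p, eta = rep(0, 10))
  expect_equal(out - w, rep(1e-4, 10))
  # multiplicative noise cannot revive a silent synapse
  w0 <- rep(0, 10)
  out0 <- excitatory_hebbian_step(w0, x, 0, p, eta = rep(0.0025, 10))
  expect_equal(out0, w0)
})

test_that("inhibitory magnitudes track the rate relative to the target rho", {
  p <- model_params(alpha_i = 1e-5, rho = 0.01)
  m <- rep(0.2, 10)
  x <- rep(1, 10)
  expect_equal(inhibitory_step(m, x, p$rho, p), m)      # at target: no drive
  out <- inhibitory_step(m, x, 0.02, p)
  expect_equal(out - m, rep(1e-7, 10))
  # magnitudes decay toward zero but never below
  m2 <- rep(1e-8, 10)
  for (k in 1:50) m2 <- inhibitory_step(m2, x, 0, p)
  expect_true(all(m2 >= 0))
  expect_true(all(m2 < 1e-8 + 1e-15))
})

test_that("weight constraints clip, normalise per class, and skip zero inhibition", {
  p <- model_params(excit_l1 = 1)
  w <- synaptic_weights(rep(0.2, 10), rep(0.05, 10), rep(0, 10), rep(0, 10))
  out <- apply_weight_constraints(w, p)
  expect_equal(out$w_on_e, rep(0.1, 10))
  expect_equal(sum(out$w_off_e), 1, tolerance = 1e-12)
  expect_equal(out$w_on_i, rep(0, 10))                  # zero class skipped
  # defaults: each excitatory class normalised to L1 = 2
  p2 <- model_params()
  out2 <- apply_weight_constraints(
    synaptic_weights(runif(10), runif(10), -runif(10), -runif(10)), p2)
  expect_equal(sum(out2$w_on_e), p2$excit_l1, tolerance = 1e-12)
  expect_equal(sum(out2$w_off_e), p2$excit_l1, tolerance = 1e-12)
  expect_true(all(out2$w_on_e >= 0 & out2$w_on_e <= 1))
  expect_equal(-sum(out2$w_on_i), p2$inhib_l1, tolerance = 1e-12)
  expect_error(apply_weight_constraints(
    synaptic_weights(rep(0, 10), rep(0.1, 10), rep(0, 10), rep(0, 10)), p),
    "all zero")
})

test_that("inhibitory cap normalisation only rescales above the target", {
  p <- model_params(inhib_l1 = 1, inhib_norm = "cap")
  small <- synaptic_weights(rep(0.2, 10), rep(0.2, 10),
                            rep(-0.05, 10), rep(0, 10))
  out <- apply_weight_constraints(small, p)
  expect_equal(out$w_on_i, rep(-0.05, 10))              # below cap: untouched
  big <- synaptic_weights(rep(0.2, 10), rep(0.2, 10),
                          rep(-0.3, 10), rep(0, 10))
  out2 <- apply_weight_constraints(big, p)
  expect_equal(-sum(out2$w_on_i), 1, tolerance = 1e-12)
  p3 <- model_params(inhib_l1 = 1, inhib_norm = "exact")
  out3 <- apply_weight_constraints(small, p3)
  expect_equal(-sum(out3$w_on_i), 1, tolerance = 1e-12) # exact: rescaled up
})

test_that("synaptic scaling is multiplicative, symmetric, and ratio-preserving", {
  p <- model_params(scaling_factor = 1e-5)
  w <- list(w_on_e = c(0.5, rep(0.1, 9)), w_off_e = rep(0.2, 10))
  st <- scaling_state(0.5, 10L)
  same <- synaptic_scaling_step(w, 0.5, st, p)
  expect_equal(same$w_on_e, w$w_on_e)                   # neither branch
  up <- synaptic_scaling_step(w, 1, st, p)
  expect_equal(up$w_on_e, w$w_on_e * (1 - 1e-5))
  # a high/low pair around the mean returns weights to O(eps^2)
  st0 <- scaling_state(0.5, 1000000L)
  a <- synaptic_scaling_step(w, 0.6, st0, p)
  b <- synaptic_scaling_step(a[c("w_on_e", "w_off_e")], 0.4, a$state, p)
  expect_equal(b$w_on_e, w$w_on_e, tolerance = 1e-9)
  # uniform factor preserves weight ratios exactly
  expect_equal(up$w_on_e[1] / up$w_on_e[2], 5, tolerance = 1e-12)
  # running mean accumulates the observed rates
  expect_equal(up$state$running_mean_y, (0.5 * 10 + 1) / 11)
})

test_that("excitatory updates are bitwise reproducible under a fixed seed", {
  p <- model_params()
  w <- rep(0.1, 10); x <- runif(10)
  set.seed(77); a <- excitatory_hebbian_step(w, x, 0.5, p)
  set.seed(77); b <- excitatory_hebbian_step(w, x, 0.5, p)
  expect_identical(a, b)
})

test_that("constraint invariants hold under random plasticity sequences", {
  p <- model_params()
  set.seed(123)
  w <- initial_weights(p)
  m_on <- rep(0, 10); m_off <- rep(0, 10)
  for (step in 1:200) {
    x_on <- runif(10, 0, 10); x_off <- runif(10, 0, 10)
    y <- firing_rate(sum(w$w_on_e * x_on) + sum(w$w_off_e * x_off) -
                       sum(m_on * x_on) - sum(m_off * x_off), p$theta)
    w_on <- excitatory_hebbian_step(w$w_on_e, x_on, y, p)
    w_off <- excitatory_hebbian_step(w$w_off_e, x_off, y, p)
    m_on <- inhibitory_step(m_on, x_on, y, p)
    m_off <- inhibitory_step(m_off, x_off, y, p)
    w <- apply_weight_constraints(
      synaptic_weights(w_on, w_off, -m_on, -m_off), p)
    m_on <- -w$w_on_i; m_off <- -w$w_off_i
    expect_true(all(w$w_on_e >= 0 & w$w_on_e <= 1))
    expect_true(all(w$w_off_e >= 0 & w$w_off_e <= 1))
    expect_equal(sum(w$w_on_e), p$excit_l1, tolerance = 1e-9)
    expect_equal(sum(w$w_off_e), p$excit_l1, tolerance = 1e-9)
    expect_true(all(w$w_on_i <= 0) && all(w$w_off_i <= 0))
    expect_lte(-sum(w$w_on_i), p$inhib_l1 + 1e-9)
  }
})
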