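test_that("pyramidal smoothing preserves constants and renormalises edges", {
  const <- matrix(3, 25, 8)
  expect_equal(smooth_fra(const), const)
  mid <- matrix(0, 25, 8); mid[13, 4] <- 1
  sm <- smooth_fra(mid)
  expect_equal(sm[13, 4], 0.25)                 # centre tap 4/16
  expect_equal(sm[12, 3], 1 / 16)
  corner <- matrix(0, 25, 8); corner[1, 1] <- 1
  expect_equal(smooth_fra(corner)[1, 1], 4 / 9) # renormalised over 4 taps
  # interior-supported mass is conserved
  interior <- matrix(0, 25, 8); interior[10:15, 3:6] <- runif(24)
  expect_equal(sum(smooth_fra(interior)), sum(interior), tolerance = 1e-12)
  expect_error(smooth_fra(matrix(1, 1, 8)), "at least 2")
})

test_that("iso-response boundary applies the 30 percent rule inclusively", {
  sm <- matrix(c(12.9, 13.0, 13.1, 20), 2, 2)
  mask <- fra_boundary(sm, baseline = 10)
  expect_equal(as.vector(mask), c(FALSE, TRUE, TRUE, TRUE))
  # zero baseline falls back to 30% of the surface maximum
  mask0 <- fra_boundary(sm, baseline = 0)
  expect_equal(as.vector(mask0), as.vector(sm >= 6))
  expect_equal(sum(fra_boundary(matrix(0, 4, 4), 0)), 0)
})

test_that("core component extraction drops isolated islands", {
  sm <- matrix(0, 10, 6)
  sm[3:5, 2:4] <- 5
  sm[9, 6] <- 2                                  # isolated noise island
  mask <- sm > 1
  core <- fra_core(mask, sm)
  expect_true(all(core[3:5, 2:4]))
  expect_false(core[9, 6])
})

test_that("CF is the weighted centre at the lowest defined level", {
  grid <- tone_grid()
  mask <- matrix(FALSE, 25, 8)
  sm <- matrix(0, 25, 8)
  mask[9, 2] <- TRUE; sm[9, 2] <- 4              # single cell at 20 dB
  cf <- characteristic_frequency(mask, sm, grid$freq_khz, grid$level_db)
  expect_equal(cf$cf_khz, grid$freq_khz[9])
  expect_equal(cf$threshold_db, 20)
  # two equal cells one step apart: geometric midpoint
  mask2 <- matrix(FALSE, 25, 8); sm2 <- matrix(0, 25, 8)
  mask2[c(10, 11), 1] <- TRUE; sm2[c(10, 11), 1] <- 2
  cf2 <- characteristic_frequency(mask2, sm2, grid$freq_khz, grid$level_db)
  expect_equal(cf2$cf_khz, sqrt(grid$freq_khz[10] * grid$freq_khz[11]))
  expect_error(characteristic_frequency(matrix(FALSE, 25, 8), sm,
                                        grid$freq_khz, grid$level_db),
               "empty")
})

test_that("best frequency breaks ties toward low level then low frequency", {
  grid <- tone_grid()
  sm <- matrix(0, 25, 8); sm[7, 5] <- 9
  bf <- best_frequency(sm, grid$freq_khz, grid$level_db)
  expect_equal(bf$bf_khz, grid$freq_khz[7])
  expect_equal(bf$bf_level_db, 50)
  sm2 <- matrix(0, 25, 8); sm2[7, 5] <- 9; sm2[7, 3] <- 9
  expect_equal(best_frequency(sm2, grid$freq_khz, grid$level_db)$bf_level_db,
               30)
  const <- matrix(1, 25, 8)
  bf3 <- best_frequency(const, grid$freq_khz, grid$level_db)
  expect_equal(bf3$bf_khz, grid$freq_khz[1])
  expect_equal(bf3$bf_level_db, 10)
})

test_that("bandwidth spans the defined region 30 dB above threshold", {
  grid <- tone_grid()
  mask <- matrix(FALSE, 25, 8)
  mask[9, 2] <- TRUE                             # threshold at 20 dB
  mask[9, 5] <- TRUE                             # single cell at 50 dB
  expect_equal(bandwidth_30db(mask, grid$freq_khz, grid$level_db), 0)
  mask[5:13, 5] <- TRUE                          # 9 contiguous cells
  expect_equal(bandwidth_30db(mask, grid$freq_khz, grid$level_db), 1.0)
  # threshold 60 dB puts the target row off the grid
  mask2 <- matrix(FALSE, 25, 8); mask2[4, 6] <- TRUE
  expect_true(is.na(bandwidth_30db(mask2, grid$freq_khz, grid$level_db)))
})

test_that("FRA overlap uses intersection over mean mask size", {
  a <- matrix(FALSE, 5, 4); a[1:2, 1:4] <- TRUE   # 8 cells
  expect_equal(fra_overlap_percent(a, a), 100)
  b <- matrix(FALSE, 5, 4); b[4:5, 1:4] <- TRUE
  expect_equal(fra_overlap_percent(a, b), 0)
  cmask <- matrix(FALSE, 5, 4); cmask[1:4, 1:4] <- TRUE  # 16, overlap 8
  expect_equal(fra_overlap_percent(a, cmask), 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(fra_overlap_percent(a, cmask, method = "jaccard"), 50)
  expect_true(is.na(fra_overlap_percent(a & FALSE, b & FALSE)))
})

test_that("DSI follows its printed definition and antisymmetry", {
  mk <- function(up, down, v = 2.2)
    sweep_spikes(data.frame(velocity = v,
                            direction = rep(c("UP", "DOWN"),
                                            c(length(up), length(down))),
                            rep = c(seq_along(up), seq_along(down)),
                            count = c(up, down)))
  expect_equal(dsi(mk(c(10, 20), c(10, 20)), 2.2), 0)
  expect_equal(dsi(mk(rep(15, 4), rep(5, 4)), 2.2), 0.5)
  expect_equal(dsi(mk(rep(5, 4), rep(15, 4)), 2.2), -0.5)
  expect_equal(dsi(mk(rep(0, 3), rep(0, 3)), 2.2), 0)  # silent: flagged 0
  expect_error(dsi(mk(1, 1), 4.4), "not present")
})

test_that("direction-selectivity classification averages the two lowest speeds", {
  mk2 <- function(d22, d44) {
    rows <- do.call(rbind, lapply(c(2.2, 4.4), function(v) {
      d <- if (v == 2.2) d22 else d44
      data.frame(velocity = v, direction = rep(c("UP", "DOWN"), each = 10),
                 rep = rep(1:10, 2),
                 count = c(rep(round(100 * (1 + d)), 10),
                           rep(round(100 * (1 - d)), 10)))
    }))
    sweep_spikes(rows)
  }
  expect_true(is_direction_selective(mk2(0.2, 0.2)))
  expect_false(is_direction_selective(mk2(0.06, -0.06)))  # mean is zero
  expect_false(is_direction_selective(mk2(0.05, 0.05)))   # strictly above
})

test_that("DSI regression recovers coefficients, PRE, and flags collinearity", {
  set.seed(14)
  n <- 40
  units <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  units$dsi_low <- 0.5 * scale(units$a)[, 1] + rnorm(n, sd = 0.05)
  fit <- fit_dsi_regression(units)
  expect_equal(names(which.max(abs(fit$coefficients))), "a")
  expect_gt(fit$adjusted_r2, 0.9)
  expect_gt(fit$pre[["a"]], 10 * max(fit$pre[c("b", "c")]))
  # predictor with zero coefficient contributes zero PRE
  units2 <- units
  units2$d <- 0.5 * units2$b + 0.5 * units2$c +
    rnorm(n, sd = 0.3)                          # correlated but full rank
  fit2 <- fit_dsi_regression(units2)
  expect_true(all(is.finite(fit2$pre)))
  # PRE arithmetic: doubling SSE means PRE = 1 by definition
  expect_equal((2 - 1) / 1, 1)
  units3 <- units
  units3$dup <- units3$a                         # exact collinearity
  expect_error(fit_dsi_regression(units3), "collinear|rank")
  units4 <- units; units4$k <- 1
  expect_error(fit_dsi_regression(units4), "zero-variance")
  # refit variant gives PRE at least as large as the full-coefficient form
  fit3 <- fit_dsi_regression(units, pre_method = "refit")
  expect_true(all(fit3$pre <= fit$pre + 1e-9))
})

test_that("normalised change averages post/baseline ratios with exclusions", {
  expect_equal(normalized_change(c(2, 4), c(2, 4)), 1)
  expect_equal(normalized_change(c(2, 4), c(4, 8)), 2)
  expect_equal(normalized_change(c(0, 4), c(9, 8)), 2)   # zero baseline dropped
  expect_equal(normalized_change(c(0.5, 4), c(9, 8), baseline_floor = 1), 2)
  expect_error(normalized_change(c(0, 0), c(1, 1)), "excluded")
})

test_that("LFP amplitude is the window minimum and CF shifts are log2 ratios", {
  times <- seq(-50, 500, by = 1)
  flat <- rep(0, length(times))
  expect_equal(lfp_on_amplitude(flat, times), 0)
  dip <- flat; dip[times == 50] <- -40
  expect_equal(lfp_on_amplitude(dip, times), -40)
  late <- flat; late[times == 350] <- -40
  expect_equal(lfp_on_amplitude(late, times), 0)         # outside 0-300 ms
  expect_error(lfp_on_amplitude(flat, times, window = c(600, 700)), "window")
  expect_equal(cf_shift_octaves(16, 16), 0)
  expect_equal(cf_shift_octaves(8, 16), 1)
  expect_equal(cf_shift_octaves(16, 13.45), log2(13.45 / 16))
  expect_lt(abs(cf_shift_octaves(16, 13.45) + 0.25), 0.002)
  expect_error(cf_shift_octaves(0, 5), "positive")
})
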