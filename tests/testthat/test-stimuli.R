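test_that("spontaneous traces are rectified filtered noise with unit mean", {
  p <- tiny_params()
  tr <- generate_spontaneous_traces(p, seed = 11, n_steps = 20000)
  expect_s3_class(tr, "stimulus_traces")
  expect_equal(colMeans(tr$on_drive), rep(1, 10), tolerance = 1e-9)
  expect_identical(tr$on_drive, tr$off_drive)    # shared ON/OFF trace
  expect_true(min(tr$on_drive) >= 0)
  # channels are mutually independent noise sources
  cc <- cor(tr$on_drive)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("impossible rectification threshold raises after regeneration attempts", {
  p <- tiny_params(theta_x = 1.0)   # above the filtered noise ceiling
  expect_error(
    suppressMessages(generate_spontaneous_traces(p, seed = 1,
                                                 n_steps = 500)),
    "all zero")
})

test_that("single-channel switching keeps at most one channel active", {
  p <- model_params()
  ev <- generate_switching_sequence(p, "single_channel", seed = 5,
                                    n_steps = 100000)
  n_steps <- ev$n_steps
  active <- matrix(FALSE, n_steps, 10)
  for (j in 1:10) {
    on <- ev$onsets[[j]]; off <- ev$offsets[[j]]
    if (length(on) > length(off)) off <- c(off, n_steps + 1L)
    for (k in seq_along(on))
      active[on[k]:min(off[k] - 1L, n_steps), j] <- TRUE
  }
  expect_lte(max(rowSums(active)), 1)
  # geometric dwell times: mean ON duration ~ 1/p_on = 50
  dwell <- unlist(lapply(1:10, function(j) {
    off <- ev$offsets[[j]]
    ev$onsets[[j]][seq_along(off)] * -1 + off
  }))
  expect_gt(length(dwell), 300)
  se <- sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 50), 3 * se + 1)
})

test_that("overlapping switching matches the two-state stationary occupancy", {
  p <- model_params()   # p_off resolves to 1/500 in overlapping mode
  ev <- generate_switching_sequence(p, "overlapping", seed = 6,
                                    n_steps = 100000)
  frac <- vapply(1:10, function(j) {
    on <- ev$onsets[[j]]; off <- ev$offsets[[j]]
    if (length(on) > length(off)) off <- c(off, ev$n_steps + 1L)
    sum(pmin(off, ev$n_steps + 1L) - on) / ev$n_steps
  }, numeric(1))
  # stationary ON fraction (1/500)/((1/500)+(1/50)) = 1/11
  expect_equal(mean(frac), 1 / 11, tolerance = 0.15)
})

test_that("event trains alternate onsets and offsets within channels", {
  p <- model_params()
  for (seed in 1:5) {
    ev <- generate_switching_sequence(p, "single_channel", seed = seed,
                                      n_steps = 20000)
    for (j in 1:10) {
      d <- length(ev$onsets[[j]]) - length(ev$offsets[[j]])
      expect_true(d %in% c(0L, 1L))
    }
  }
  expect_error(event_train(list(c(5L, 10L)), list(3L), 100, 1),
               "alternate")
})

test_that("independent ON/OFF sequences are distinct but statistically alike", {
  p <- model_params()
  tr <- generate_independent_sequences(p, seed = 9, n_steps = 100000)
  n_on <- sum(lengths(tr$on_train$onsets))
  n_off <- sum(lengths(tr$off_train$onsets))
  expect_false(identical(tr$on_train$onsets, tr$off_train$onsets))
  expect_lt(abs(n_on - n_off) / mean(c(n_on, n_off)), 0.2)
})

test_that("pulse traces decay exponentially and respect the rescale ceiling", {
  p <- model_params()
  ev <- event_train(c(list(50L), rep(list(integer(0)), 9)),
                    rep(list(integer(0)), 10), 200, 10)
  tr <- events_to_traces(ev, p, rescale_max = NULL)
  ch1 <- tr$on_drive[, 1]
  expect_equal(ch1[51] / ch1[50], exp(-1 / 10), tolerance = 1e-12)
  expect_equal(ch1[49], 0)
  expect_equal(max(tr$off_drive), 0)

  ev2 <- generate_switching_sequence(p, "single_channel", seed = 2,
                                     n_steps = 5000)
  tr2 <- events_to_traces(ev2, p, rescale_max = 40)
  expect_equal(max(max(tr2$on_drive), max(tr2$off_drive)), 40,
               tolerance = 1e-9)
  tr3 <- events_to_traces(ev2, p, rescale_max = 40,
                          rescale_mode = "total")
  expect_equal(max(max(rowSums(tr3$on_drive)), max(rowSums(tr3$off_drive))),
               40, tolerance = 1e-9)
  empty <- event_train(rep(list(integer(0)), 10),
                       rep(list(integer(0)), 10), 100, 10)
  expect_warning(tr0 <- events_to_traces(empty, p), "empty")
  expect_equal(max(tr0$on_drive), 0)
})

test_that("pulse trace construction commutes with time shifts", {
  p <- model_params()
  mk <- function(shift) {
    on <- rep(list(integer(0)), 10); off <- rep(list(integer(0)), 10)
    on[[3]] <- c(10L, 60L) + shift
    off[[3]] <- c(30L, 90L) + shift
    events_to_traces(event_train(on, off, 200L + shift, 10), p,
                     rescale_max = NULL)
  }
  a <- mk(0L); b <- mk(40L)
  expect_equal(a$on_drive[10:160, ], b$on_drive[50:200, ],
               tolerance = 1e-12)
})

test_that("FM sweeps step one channel per interval with circular wrap", {
  p <- model_params()
  up <- fm_sweep_events("UP", p)
  expect_equal(sum(lengths(up$onsets)), 60)       # 3000 / 50 presentations
  # presentation k lands on channel (k mod 10) + 1 from channel 1
  ts <- sort(unlist(up$onsets))
  ch_at <- function(ev, t) which(vapply(ev$onsets, function(o) t %in% o,
                                        logical(1)))
  expect_equal(vapply(ts[1:12], ch_at, numeric(1), ev = up),
               c(1:10, 1, 2))
  # offset of each band coincides with the onset in the next band
  expect_equal(sort(unlist(up$offsets)), ts + 50L)
  down <- fm_sweep_events("DOWN", p)
  expect_equal(vapply(ts[1:3], ch_at, numeric(1), ev = down), c(10, 9, 8))
})

test_that("tone probes scale linearly with intensity and carry both pulses", {
  p <- model_params()
  a <- tone_probe_traces(4, 10, p)
  b <- tone_probe_traces(4, 20, p)
  expect_equal(2 * a$on_drive, b$on_drive, tolerance = 1e-12)
  expect_equal(2 * a$off_drive, b$off_drive, tolerance = 1e-12)
  expect_equal(max(a$off_drive[seq_len(p$probe_tone_steps), ]), 0)
  expect_error(tone_probe_traces(4, 0, p), "positive")
  ladder <- probe_intensities(p)
  expect_equal(ladder[1], 19.5)
  expect_equal(ladder[length(ladder)], 65)
})
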