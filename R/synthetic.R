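#' Ground truth for one synthetic unit
#'
#' Planted parameters of a synthetic in-vivo-like unit: V-shaped ON and
#' OFF response fields centred on the planted CFs, Poisson spiking, and a
#' direction-selectivity coupling in which the unit's low-speed DSI equals
#' \code{dsi_slope * (off_cf - on_cf)} in octaves (clamped to
#' \eqn{[-1, 1]}). With a negative slope, units whose OFF CF sits above
#' their ON CF prefer DOWN sweeps, as observed in adult cortex.
#'
#' @param on_cf_khz,off_cf_khz planted ON and OFF characteristic
#'   frequencies (within 7-56 kHz).
#' @param bw_on_oct,bw_off_oct planted bandwidths 30 dB above threshold.
#' @param threshold_db minimum responsive level (dB SPL).
#' @param peak_rate maximal evoked rate (spikes/s).
#' @param spont_rate spontaneous rate (spikes/s).
#' @param dsi_slope DSI per octave of (OFF - ON) CF offset.
#' @param sweep_rate mean evoked rate during a sweep (spikes/s).
#' @return an object of class \code{unit_ground_truth}.
#' @export
unit_ground_truth <- function(on_cf_khz, off_cf_khz,
                              bw_on_oct = 1, bw_off_oct = 1,
                              threshold_db = 30, peak_rate = 100,
                              spont_rate = 8, dsi_slope = -1,
                              sweep_rate = 30) {
  stopifnot(on_cf_khz >= 7, on_cf_khz <= 56,
            off_cf_khz >= 7, off_cf_khz <= 56,
            bw_on_oct > 0, bw_off_oct > 0,
            peak_rate >= 0, spont_rate >= 0, sweep_rate >= 0)
  structure(list(on_cf_khz = on_cf_khz, off_cf_khz = off_cf_khz,
                 bw_on_oct = bw_on_oct, bw_off_oct = bw_off_oct,
                 threshold_db = threshold_db, peak_rate = peak_rate,
                 spont_rate = spont_rate, dsi_slope = dsi_slope,
                 sweep_rate = sweep_rate),
            class = "unit_ground_truth")
}

# V-shaped mean rate surface (spikes/s): responsive where
# level >= threshold + slope * |octaves from CF|, slope set so the field is
# bw octaves wide 30 dB above threshold; rate grows with level above the
# local threshold up to peak_rate at (CF, 80 dB).
v_shape_rates <- function(cf_khz, bw_oct, threshold_db, peak_rate,
                          freq_axis, level_axis) {
  slope <- 60 / bw_oct                      # dB per octave
  doct <- abs(log2(freq_axis / cf_khz))
  local_thr <- threshold_db + outer(doct, rep(1, length(level_axis))) * slope
  lev <- outer(rep(1, length(freq_axis)), level_axis)
  span <- max(level_axis) - threshold_db
  pmax(lev - local_thr, 0) / span * peak_rate
}

#' Synthesise spike-count FRAs and sweep responses for one unit
#'
#' Generates Poisson spike counts on the in vivo tone grid (100-ms ON and
#' OFF windows, V-shaped mean-rate fields around the planted CFs, plus
#' spontaneous activity) and per-trial sweep counts whose expected DSI is
#' the planted coupling at slow speeds, decaying linearly to zero between
#' 17.5 and 35 octaves/second (direction selectivity at slow speeds only).
#'
#' @param truth a [unit_ground_truth()].
#' @param repeats tone repeats per grid cell (default 10).
#' @param sweep_repeats sweep repeats per velocity and direction
#'   (default 30).
#' @param velocities sweep velocity magnitudes in octaves/second.
#' @param sweep_octaves sweep extent in octaves (default 3).
#' @param seed optional integer seed.
#' @return list with \code{fra} ([spike_fra()]) and \code{sweeps}
#'   ([sweep_spikes()]).
#' @export
synth_unit <- function(truth, repeats = 10, sweep_repeats = 30,
                       velocities = c(2.2, 4.4, 8.8, 17.5, 35, 70),
                       sweep_octaves = 3, seed = NULL) {
  stopifnot(inherits(truth, "unit_ground_truth"), repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- tone_grid()
  nf <- length(grid$freq_khz); nl <- length(grid$level_db)
  window_s <- 0.1
  draw <- function(cf, bw) {
    mu <- (v_shape_rates(cf, bw, truth$threshold_db, truth$peak_rate,
                         grid$freq_khz, grid$level_db) +
             truth$spont_rate) * window_s
    array(stats::rpois(nf * nl * repeats, rep(mu, repeats)),
          dim = c(nf, nl, repeats))
  }
  fra <- spike_fra(
    on_counts = draw(truth$on_cf_khz, truth$bw_on_oct),
    off_counts = draw(truth$off_cf_khz, truth$bw_off_oct),
    freq_axis = grid$freq_khz, level_axis = grid$level_db,
    baseline_counts = stats::rpois(nf * nl * repeats,
                                   truth$spont_rate * window_s))

  d0 <- max(-1, min(1, truth$dsi_slope *
                      log2(truth$off_cf_khz / truth$on_cf_khz)))
  profile <- function(v) ifelse(v <= 17.5, 1,
                                pmax(0, 1 - (v - 17.5) / 17.5))
  rows <- do.call(rbind, lapply(velocities, function(v) {
    dur <- sweep_octaves / v + 0.1          # onset to 100 ms after offset
    base <- (truth$sweep_rate + truth$spont_rate) * dur
    d <- d0 * profile(v)
    data.frame(
      velocity = v,
      direction = rep(c("UP", "DOWN"), each = sweep_repeats),
      rep = c(seq_len(sweep_repeats), seq_len(sweep_repeats)),
      count = c(stats::rpois(sweep_repeats, base * (1 + d)),
                stats::rpois(sweep_repeats, base * (1 - d))))
  }))
  list(fra = fra, sweeps = sweep_spikes(rows))
}

# Triangular sampler on [lo, hi] with the given mode.
rtriangle <- function(n, lo, hi, mode) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Synthesise a population of in-vivo-like units
#'
#' Draws unit ground truths from population-level distributions and
#' generates each unit with [synth_unit()]. The \code{"adult"} profile
#' plants ON/OFF CF offsets up to 0.5 octave with mode 0.25 (random sign)
#' and a nonzero DSI coupling; the \code{"young"} profile plants offsets
#' near zero and no coupling, so CF difference carries no information
#' about DSI.
#'
#' @param n number of units.
#' @param type \code{"adult"} or \code{"young"}.
#' @param master_seed integer master seed.
#' @param dsi_slope DSI per octave of (OFF - ON) offset; defaults to -1
#'   for adult and 0 for young populations.
#' @param repeats,sweep_repeats passed to [synth_unit()].
#' @return list of per-unit lists with elements \code{truth}, \code{fra},
#'   \code{sweeps}.
#' @export
synth_population <- function(n, type = c("adult", "young"),
                             master_seed = 1, dsi_slope = NULL,
                             repeats = 10, sweep_repeats = 30) {
  type <- match.arg(type)
  stopifnot(n >= 1)
  if (is.null(dsi_slope)) dsi_slope <- if (type == "adult") -1 else 0
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  cf_on <- exp(stats::runif(n, log(9.9), log(39.6)))
  offset <- if (type == "adult") {
    sample(c(-1, 1), n, replace = TRUE) * rtriangle(n, 0, 0.5, 0.25)
  } else {
    sample(c(-1, 1), n, replace = TRUE) * rtriangle(n, 0, 0.125, 0)
  }
  bw_on <- stats::runif(n, 0.75, 1.25)
  bw_off <- stats::runif(n, 0.75, 1.25)
  thr <- sample(c(20, 30, 40), n, replace = TRUE)
  peak <- stats::runif(n, 80, 150)
  spont <- stats::runif(n, 6, 15)
  lapply(seq_len(n), function(k) {
    truth <- unit_ground_truth(
      on_cf_khz = cf_on[k], off_cf_khz = cf_on[k] * 2^offset[k],
      bw_on_oct = bw_on[k], bw_off_oct = bw_off[k],
      threshold_db = thr[k], peak_rate = peak[k], spont_rate = spont[k],
      dsi_slope = dsi_slope)
    c(list(truth = truth),
      synth_unit(truth, repeats = repeats, sweep_repeats = sweep_repeats,
                 seed = seeds[k]))
  })
}

#' Unit-properties table for a synthetic (or real) population
#'
#' Applies [unit_properties()] to every unit; units without defined ON and
#' OFF responses are dropped (with a count attribute), mirroring the in
#' vivo rejection of units lacking clear FRA structure.
#'
#' @param units list of lists with \code{fra} and \code{sweeps} elements.
#' @return data.frame of unit properties with attribute
#'   \code{n_rejected}.
#' @export
population_properties <- function(units) {
  rows <- lapply(units, function(u) unit_properties(u$fra, u$sweeps))
  rejected <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "n_rejected") <- rejected
  out
}
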