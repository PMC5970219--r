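#' Spike-count frequency response area
#'
#' Spike counts on the tone grid used in vivo: 25 frequencies (7-56 kHz at
#' 0.125-octave spacing) by 8 sound levels (10-80 dB SPL), with R repeats,
#' counted in 100-ms windows after tone onset (ON) and offset (OFF), plus
#' pre-stimulus baseline window counts.
#'
#' @param on_counts,off_counts integer arrays of dimension
#'   \code{n_freq x n_level x repeats}.
#' @param freq_axis strictly increasing tone frequencies in kHz.
#' @param level_axis strictly increasing sound levels in dB SPL.
#' @param baseline_counts integer vector of pre-stimulus window spike
#'   counts (one per trial).
#' @return an object of class \code{spike_fra}.
#' @export
spike_fra <- function(on_counts, off_counts, freq_axis, level_axis,
                      baseline_counts) {
  d <- dim(on_counts)
  stopifnot(length(d) == 3, all(dim(off_counts) == d),
            d[1] == length(freq_axis), d[2] == length(level_axis),
            all(diff(freq_axis) > 0), all(diff(level_axis) > 0),
            d[3] >= 1, length(baseline_counts) >= 1)
  if (min(on_counts) < 0 || min(off_counts) < 0 || min(baseline_counts) < 0)
    stop("spike counts must be non-negative")
  structure(list(on_counts = on_counts, off_counts = off_counts,
                 freq_axis = freq_axis, level_axis = level_axis,
                 baseline_counts = baseline_counts,
                 baseline_rate = mean(baseline_counts)),
            class = "spike_fra")
}

#' Default in vivo tone grid
#'
#' 25 frequencies from 7 kHz at 0.125-octave spacing (up to 56 kHz) and
#' levels 10-80 dB SPL in 10-dB steps.
#'
#' @return list with \code{freq_khz} and \code{level_db}.
#' @export
tone_grid <- function() {
  list(freq_khz = 7 * 2^(0.125 * (0:24)), level_db = seq(10, 80, by = 10))
}

#' Spike counts to FM sweeps
#'
#' Per-trial spike counts in the window from sweep onset to 100 ms after
#' offset, for each velocity magnitude and direction.
#'
#' @param counts data.frame with columns \code{velocity} (octaves/second,
#'   positive magnitude), \code{direction} (\code{"UP"}/\code{"DOWN"}),
#'   \code{rep}, \code{count}.
#' @return an object of class \code{sweep_spikes}.
#' @export
sweep_spikes <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("velocity", "direction", "count") %in% names(counts)))
  if (min(counts$count) < 0) stop("spike counts must be non-negative")
  counts$direction <- toupper(counts$direction)
  if (!all(counts$direction %in% c("UP", "DOWN")))
    stop("direction must be UP or DOWN")
  for (v in unique(counts$velocity))
    if (length(unique(counts$direction[counts$velocity == v])) < 2)
      stop("both directions must be present at velocity ", v)
  structure(list(counts = counts,
                 velocity_axis = sort(unique(counts$velocity))),
            class = "sweep_spikes")
}

# 3x3 pyramidal smoothing kernel.
pyramid_kernel <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)

#' Smooth an FRA surface with a 3x3 pyramidal window
#'
#' Convolution with the kernel \code{[[1,2,1],[2,4,2],[1,2,1]]/16}. At
#' edges the kernel is renormalised over the in-bounds taps, so a constant
#' surface is unchanged everywhere.
#'
#' @param raw numeric matrix (frequencies x levels).
#' @return smoothed matrix of the same dimension.
#' @export
smooth_fra <- function(raw) {
  if (!is.matrix(raw) || nrow(raw) < 2 || ncol(raw) < 2)
    stop("raw FRA must be a matrix with at least 2 rows and columns")
  nr <- nrow(raw); nc <- ncol(raw)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (di in -1:1) {
    ri <- seq_len(nr) + di
    ok_i <- ri >= 1 & ri <= nr
    for (dj in -1:1) {
      cj <- seq_len(nc) + dj
      ok_j <- cj >= 1 & cj <= nc
      k <- pyramid_kernel[di + 2, dj + 2]
      num[ok_i, ok_j] <- num[ok_i, ok_j] + k * raw[ri[ok_i], cj[ok_j]]
      den[ok_i, ok_j] <- den[ok_i, ok_j] + k
    }
  }
  num / den
}

#' Iso-response FRA boundary mask
#'
#' Marks grid cells whose smoothed response is at least a 30\% increase
#' over the baseline firing rate (inclusive). With a zero baseline the
#' threshold falls back to 30\% of the surface maximum; an all-zero
#' surface yields an empty mask.
#'
#' @param smoothed smoothed response surface from [smooth_fra()].
#' @param baseline baseline rate, in the same units (counts per window).
#' @return logical mask of the same dimension.
#' @export
fra_boundary <- function(smoothed, baseline) {
  stopifnot(baseline >= 0)
  thr <- if (baseline > 0) 1.3 * baseline else 0.3 * max(smoothed)
  if (thr <= 0) return(smoothed > 0)   # all-zero surface: empty mask
  smoothed >= thr
}

#' Core connected component of an FRA mask
#'
#' Keeps only the 4-connected component of the mask that contains the peak
#' of the smoothed surface (or, if the peak is unmasked, the largest
#' component). This automates the manual curation step of discarding
#' isolated supra-threshold islands produced by noise.
#'
#' @param mask logical mask from [fra_boundary()].
#' @param smoothed matching smoothed response surface.
#' @return logical mask containing a single connected component (or all
#'   \code{FALSE} for an empty input mask).
#' @export
fra_core <- function(mask, smoothed) {
  stopifnot(all(dim(mask) == dim(smoothed)))
  if (!any(mask)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                      c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          idx <- (nb[2] - 1L) * nr + nb[1]
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- cur
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  peak <- which.max(ifelse(mask, smoothed, -Inf))
  keep <- lab[peak]
  if (keep == 0L) {
    sizes <- tabulate(lab, nbins = cur)
    keep <- which.max(sizes)
  }
  lab == keep
}

#' Characteristic frequency from an FRA mask
#'
#' The CF is measured at the lowest sound level at which the mask contains
#' any defined response: the response-weighted centre frequency (geometric,
#' i.e. weighted mean in log2 frequency) of the defined cells at that
#' level.
#'
#' @param mask logical mask (frequencies x levels).
#' @param smoothed matching smoothed response surface (weights).
#' @param freq_axis frequencies in kHz.
#' @param level_axis levels in dB SPL.
#' @return list with \code{cf_khz} and \code{threshold_db} (the lowest
#'   defined level).
#' @export
characteristic_frequency <- function(mask, smoothed, freq_axis, level_axis) {
  if (!any(mask))
    stop("empty FRA mask: unit has no defined response, CF undefined")
  lev <- which(colSums(mask) > 0)[1]
  rows <- which(mask[, lev])
  w <- smoothed[rows, lev]
  if (sum(w) <= 0) w <- rep(1, length(rows))
  list(cf_khz = 2^(sum(w * log2(freq_axis[rows])) / sum(w)),
       threshold_db = level_axis[lev])
}

#' Best frequency of a smoothed FRA
#'
#' The frequency/level cell with the highest (smoothed) spike count. Ties
#' are resolved towards the lowest level, then the lowest frequency.
#'
#' @inheritParams characteristic_frequency
#' @return list with \code{bf_khz} and \code{bf_level_db}.
#' @export
best_frequency <- function(smoothed, freq_axis, level_axis) {
  hits <- which(smoothed == max(smoothed), arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  list(bf_khz = freq_axis[hits[1, 1]], bf_level_db = level_axis[hits[1, 2]])
}

#' RF bandwidth 30 dB above threshold
#'
#' The octave span of the defined region in the level row 30 dB above the
#' response threshold (the lowest defined level). If that row lies outside
#' the level grid the bandwidth is undefined and \code{NA} is returned.
#'
#' @inheritParams characteristic_frequency
#' @param threshold_db response threshold; defaults to the lowest level
#'   with any defined cell.
#' @return bandwidth in octaves (0 for a single defined cell), or
#'   \code{NA} if the target row is off the grid.
#' @export
bandwidth_30db <- function(mask, freq_axis, level_axis,
                           threshold_db = NULL) {
  if (!any(mask)) stop("empty FRA mask: bandwidth undefined")
  if (is.null(threshold_db))
    threshold_db <- level_axis[which(colSums(mask) > 0)[1]]
  target <- threshold_db + 30
  col <- which(abs(level_axis - target) < 1e-9)
  if (length(col) != 1) return(NA_real_)
  rows <- which(mask[, col])
  if (!length(rows)) return(0)
  log2(freq_axis[max(rows)] / freq_axis[min(rows)])
}

#' Percentage overlap of ON and OFF FRA masks
#'
#' Overlap is the intersection size divided by the mean of the two mask
#' sizes, as a percentage: identical masks give 100, disjoint masks 0.
#' The \code{"jaccard"} variant divides by the union size instead.
#'
#' @param mask_on,mask_off logical masks of equal dimension.
#' @param method \code{"mean"} (default) or \code{"jaccard"}.
#' @return overlap percentage, or \code{NA} if both masks are empty.
#' @export
fra_overlap_percent <- function(mask_on, mask_off,
                                method = c("mean", "jaccard")) {
  method <- match.arg(method)
  stopifnot(all(dim(mask_on) == dim(mask_off)))
  a <- sum(mask_on); b <- sum(mask_off)
  if (a + b == 0) return(NA_real_)
  inter <- sum(mask_on & mask_off)
  denom <- if (method == "mean") (a + b) / 2 else sum(mask_on | mask_off)
  100 * inter / denom
}

#' Direction selectivity index at one sweep velocity
#'
#' \eqn{DSI = (r_1 - r_2) / (r_1 + r_2)} where \eqn{r_1} is the mean spike
#' count for UP sweeps and \eqn{r_2} for DOWN sweeps at the given velocity.
#' Positive values indicate UP preference. If both means are zero the DSI
#' is 0.
#'
#' @param spikes a [sweep_spikes()] object.
#' @param velocity sweep velocity magnitude (octaves/second).
#' @return DSI in \eqn{[-1, 1]}.
#' @export
dsi <- function(spikes, velocity) {
  cc <- spikes$counts[abs(spikes$counts$velocity - velocity) < 1e-9, ]
  if (!nrow(cc)) stop("velocity ", velocity, " not present")
  r1 <- mean(cc$count[cc$direction == "UP"])
  r2 <- mean(cc$count[cc$direction == "DOWN"])
  if (r1 + r2 <= 0) return(0)
  (r1 - r2) / (r1 + r2)
}

#' Direction-selectivity classification
#'
#' A unit is direction selective if the absolute value of the mean of its
#' DSIs at the two lowest sweep speeds (2.2 and 4.4 octaves/second) is
#' strictly above 0.05.
#'
#' @param spikes a [sweep_spikes()] object.
#' @param velocities the two lowest speeds (defaults 2.2 and 4.4).
#' @param threshold classification threshold (default 0.05).
#' @return logical.
#' @export
is_direction_selective <- function(spikes, velocities = c(2.2, 4.4),
                                   threshold = 0.05) {
  vals <- vapply(velocities, function(v) dsi(spikes, v), numeric(1))
  abs(mean(vals)) > threshold
}

#' Linear DSI regression with z-scored predictors and PRE
#'
#' Fits DSI on z-scored functional unit properties by least squares and
#' reports, per predictor, the normalised coefficient and the proportional
#' reduction of error, \eqn{PRE_j = (SSE_{truncated} - SSE_{full}) /
#' SSE_{full}}, where the truncated prediction drops predictor j's term
#' while keeping the full-model coefficients (default); a refit variant
#' re-estimates the truncated model instead. Model performance is the
#' adjusted R-squared.
#'
#' @param units data.frame with a \code{dsi_low} column and the predictor
#'   columns.
#' @param predictors character vector of predictor column names; defaults
#'   to every column except \code{dsi_low}.
#' @param pre_method \code{"full_coef"} (as defined above) or
#'   \code{"refit"}.
#' @return list with \code{coefficients} (z-scored, named),
#'   \code{p_values}, \code{adjusted_r2}, \code{pre} (named), \code{n},
#'   and the underlying \code{fit}.
#' @export
fit_dsi_regression <- function(units, predictors = NULL,
                               pre_method = c("full_coef", "refit")) {
  pre_method <- match.arg(pre_method)
  stopifnot("dsi_low" %in% names(units))
  if (is.null(predictors)) predictors <- setdiff(names(units), "dsi_low")
  stopifnot(all(predictors %in% names(units)))
  units <- units[stats::complete.cases(units[c("dsi_low", predictors)]), ]
  n <- nrow(units)
  if (n <= length(predictors) + 1)
    stop("need more units (", n, ") than predictors (+1) to fit")
  z <- as.data.frame(scale(units[predictors]))
  bad <- names(z)[!vapply(z, function(v) all(is.finite(v)), logical(1))]
  if (length(bad))
    stop("constant (zero-variance) predictors: ", paste(bad, collapse = ", "))
  dat <- cbind(dsi_low = units$dsi_low, z)
  fit <- stats::lm(dsi_low ~ ., data = dat)
  coefs <- stats::coef(fit)
  if (anyNA(coefs))
    stop("rank-deficient fit; collinear predictors: ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  yhat <- stats::fitted(fit)
  sse_full <- sum(stats::residuals(fit)^2)
  pre <- vapply(predictors, function(p) {
    if (pre_method == "full_coef") {
      yhat_trunc <- yhat - coefs[p] * z[[p]]
      sse_trunc <- sum((units$dsi_low - yhat_trunc)^2)
    } else {
      f2 <- stats::lm(dsi_low ~ ., data = dat[setdiff(names(dat), p)])
      sse_trunc <- sum(stats::residuals(f2)^2)
    }
    (sse_trunc - sse_full) / sse_full
  }, numeric(1))
  sm <- summary(fit)
  list(coefficients = coefs[predictors],
       p_values = sm$coefficients[predictors, "Pr(>|t|)"],
       adjusted_r2 = sm$adj.r.squared,
       pre = pre, n = n, fit = fit)
}

#' Normalised response change (post / baseline)
#'
#' The mean element-wise ratio of post-manipulation responses to baseline
#' responses over stimuli inside the baseline FRA edges; a value above 1
#' denotes an activity increase. Elements whose baseline response is at or
#' below \code{baseline_floor} are excluded (for spike counts, recordings
#' averaging under 1 baseline spike are excluded upstream).
#'
#' @param r_baseline,r_post equal-length response vectors.
#' @param baseline_floor exclusion floor for baseline responses
#'   (default 0).
#' @return mean ratio.
#' @export
normalized_change <- function(r_baseline, r_post, baseline_floor = 0) {
  stopifnot(length(r_baseline) == length(r_post))
  keep <- r_baseline > baseline_floor
  if (!any(keep))
    stop("all elements excluded by the baseline floor; change undefined")
  mean(r_post[keep] / r_baseline[keep])
}

#' Evoked LFP ON amplitude
#'
#' The ON response of a local field potential trace is quantified as the
#' global minimum over the response window (LFP deflections are
#' negative-going).
#'
#' @param trace sampled LFP values.
#' @param times sample times in ms (same length as \code{trace}).
#' @param window response window in ms, default 0-300 after sound onset.
#' @return the minimum value within the window.
#' @export
lfp_on_amplitude <- function(trace, times, window = c(0, 300)) {
  stopifnot(length(trace) == length(times), length(window) == 2)
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel)) stop("no samples inside the response window")
  min(trace[sel])
}

#' CF shift in octaves
#'
#' \eqn{\log_2(CF_2 / CF_1)}: the octave difference between two
#' characteristic frequencies.
#'
#' @param cf1,cf2 frequencies in matching units (> 0).
#' @return signed shift in octaves.
#' @export
cf_shift_octaves <- function(cf1, cf2) {
  if (any(c(cf1, cf2) <= 0)) stop("frequencies must be positive")
  log2(cf2 / cf1)
}

# Fano factor of repeat counts; 0 for an all-zero condition.
fano_factor <- function(counts) {
  m <- mean(counts)
  if (m <= 0) return(0)
  stats::var(counts) / m
}

#' Functional properties of one unit
#'
#' Computes the ten regression predictors used to model DSI, from a unit's
#' spike-count FRAs and sweep responses: ON/OFF evoked rate increases at
#' CF and 60 dB, their Fano factors, spontaneous rate and Fano factor, ON
#' and OFF bandwidths 30 dB above threshold, ON/OFF FRA overlap
#' percentage, and the octave difference between ON and OFF CF
#' (\code{log2(cf_on / cf_off)}); plus the response variable
#' \code{dsi_low}, the DSI at the lowest sweep speed.
#'
#' @param fra a [spike_fra()] object.
#' @param sweeps a [sweep_spikes()] object.
#' @param evoked_level_db level at which evoked responses are read
#'   (default 60).
#' @return one-row data.frame of unit properties, or \code{NULL} if the
#'   unit has no defined ON or OFF response (mirroring in vivo rejection).
#' @export
unit_properties <- function(fra, sweeps, evoked_level_db = 60) {
  sm_on <- smooth_fra(apply(fra$on_counts, c(1, 2), mean))
  sm_off <- smooth_fra(apply(fra$off_counts, c(1, 2), mean))
  baseline <- fra$baseline_rate
  mask_on <- fra_core(fra_boundary(sm_on, baseline), sm_on)
  mask_off <- fra_core(fra_boundary(sm_off, baseline), sm_off)
  if (!any(mask_on) || !any(mask_off)) return(NULL)
  cf_on <- characteristic_frequency(mask_on, sm_on, fra$freq_axis,
                                    fra$level_axis)
  cf_off <- characteristic_frequency(mask_off, sm_off, fra$freq_axis,
                                     fra$level_axis)
  lev <- which.min(abs(fra$level_axis - evoked_level_db))
  evoked <- function(counts, cf_khz) {
    fi <- which.min(abs(log2(fra$freq_axis) - log2(cf_khz)))
    reps <- counts[fi, lev, ]
    c(increase = mean(reps) - baseline, fano = fano_factor(reps))
  }
  ev_on <- evoked(fra$on_counts, cf_on$cf_khz)
  ev_off <- evoked(fra$off_counts, cf_off$cf_khz)
  data.frame(
    on_rate_increase = ev_on[["increase"]],
    off_rate_increase = ev_off[["increase"]],
    fano_on = ev_on[["fano"]],
    fano_off = ev_off[["fano"]],
    spont_rate = baseline,
    fano_spont = fano_factor(fra$baseline_counts),
    bw_on = bandwidth_30db(mask_on, fra$freq_axis, fra$level_axis),
    bw_off = bandwidth_30db(mask_off, fra$freq_axis, fra$level_axis),
    overlap_pct = fra_overlap_percent(mask_on, mask_off),
    cf_diff_oct = log2(cf_on$cf_khz / cf_off$cf_khz),
    dsi_low = dsi(sweeps, min(sweeps$velocity_axis)))
}
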