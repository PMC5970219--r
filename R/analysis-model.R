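#' Rate response of a frozen model cell to stimulus traces
#'
#' Computes the threshold-linear output at every step with plasticity
#' frozen: \eqn{u(t) = x_{on}(t) \cdot (w^{ON,e} + w^{ON,i}) +
#' x_{off}(t) \cdot (w^{OFF,e} + w^{OFF,i})}, \eqn{y = \max(u - \theta, 0)}.
#'
#' @param w a [synaptic_weights()] object.
#' @param traces a [stimulus_traces()] object with tuned drive.
#' @param params a [model_params()] object.
#' @return numeric vector of rates, one per step.
#' @export
frozen_response <- function(w, traces, params) {
  u <- drop(traces$on_drive %*% (w$w_on_e + w$w_on_i) +
              traces$off_drive %*% (w$w_off_e + w$w_off_i))
  firing_rate(u, params$theta)
}

#' Model frequency response areas
#'
#' Probes a frozen cell with sustained tones on the channel x intensity
#' grid (intensities from \code{probe_min} to \code{probe_max}). The ON
#' response of a probe is the mean rate over \code{probe_window} steps from
#' the onset pulse; the OFF response is the mean rate over the same-length
#' window from the offset pulse.
#'
#' @param w a [synaptic_weights()] object.
#' @param params a [model_params()] object.
#' @return an object of class \code{model_fra}: list with \code{on_resp}
#'   and \code{off_resp} (\code{n_channels x probe_levels} matrices) and
#'   \code{intensity_axis}.
#' @export
measure_model_fra <- function(w, params) {
  n <- params$n_channels
  levels <- probe_intensities(params)
  on_resp <- matrix(0, n, length(levels))
  off_resp <- matrix(0, n, length(levels))
  win_on <- seq_len(params$probe_window)
  win_off <- params$probe_tone_steps + win_on
  for (j in seq_len(n)) {
    base <- tone_probe_traces(j, 1, params)   # drive is linear in intensity
    u1 <- drop(base$on_drive %*% (w$w_on_e + w$w_on_i) +
                 base$off_drive %*% (w$w_off_e + w$w_off_i))
    for (k in seq_along(levels)) {
      y <- firing_rate(levels[k] * u1, params$theta)
      on_resp[j, k] <- mean(y[win_on])
      off_resp[j, k] <- mean(y[win_off])
    }
  }
  structure(list(on_resp = on_resp, off_resp = off_resp,
                 intensity_axis = levels),
            class = "model_fra")
}

#' Centre-of-mass characteristic frequency of a model FRA surface
#'
#' The response-weighted mean channel index over the full channel x
#' intensity surface, in the 1..N channel convention. Invariant to uniform
#' scaling of the surface.
#'
#' @param resp \code{n_channels x n_levels} non-negative response surface.
#' @return real channel index.
#' @export
center_of_mass_cf <- function(resp) {
  wts <- rowSums(resp)
  tot <- sum(wts)
  if (!is.finite(tot) || tot <= 0)
    stop("all-zero response surface: centre-of-mass CF undefined")
  sum(seq_along(wts) * wts) / tot
}

#' Centre-of-mass CF of a model FRA on the circular channel axis
#'
#' Channels form a ring (channel 1 neighbours channel N), so a response
#' surface whose mass wraps around the boundary would get a meaningless
#' plain centre of mass. The surface is therefore rotated so its peak
#' channel sits at the middle of the axis, the plain response-weighted
#' mean index ([center_of_mass_cf()]) is taken there, and the result is
#' rotated back. For surfaces away from the boundary this equals the
#' plain centre of mass.
#'
#' @param resp \code{n_channels x n_levels} non-negative response surface.
#' @return real channel index in \code{[0.5, n + 0.5)}.
#' @export
fra_cf <- function(resp) {
  n <- nrow(resp)
  peak <- which.max(rowSums(resp))
  mid <- n %/% 2 + 1
  rot <- (seq_len(n) - 1 + (peak - mid)) %% n + 1
  com <- center_of_mass_cf(resp[rot, , drop = FALSE])
  (com + (peak - mid) - 1) %% n + 1
}

#' Is a model FRA well formed (V-shaped, single-peaked)?
#'
#' The in vivo direction-selectivity analysis includes only units with
#' clear V-shaped ON and OFF receptive fields; the model analogue accepts
#' an FRA whose response mass is concentrated around a single peak: at
#' least \code{min_fraction} of the total response must fall within
#' \code{half_width} channels (one octave by default) of the peak
#' channel, circularly. Multi-peaked surfaces, whose centre of mass is
#' not a meaningful CF, fail this screen.
#'
#' @param resp \code{n_channels x n_levels} response surface.
#' @param min_fraction minimal mass fraction near the peak (default 0.6).
#' @param half_width half-width of the peak window in channels.
#' @return logical.
#' @export
fra_well_formed <- function(resp, min_fraction = 0.6, half_width = 2L) {
  m <- rowSums(resp)
  tot <- sum(m)
  if (tot <= 0) return(FALSE)
  n <- length(m)
  pk <- which.max(m)
  idx <- ((pk - 1L + seq(-half_width, half_width)) %% n) + 1L
  sum(m[idx]) / tot >= min_fraction
}

#' Signed ON/OFF CF difference in octaves
#'
#' Channel indices are converted to octaves with
#' \code{octaves_per_index} (an index difference of 2 corresponds to 1
#' octave for 10 channels spanning 5 octaves). The difference keeps the
#' sign of \code{on_cf - off_cf} with its magnitude wrapped to the shorter
#' circular arc; an exact half-ring tie is resolved positive.
#'
#' @param on_cf,off_cf centre-of-mass channel indices.
#' @param params a [model_params()] object.
#' @return signed difference in octaves.
#' @export
cf_difference_octaves <- function(on_cf, off_cf, params) {
  n <- params$n_channels
  d <- on_cf - off_cf
  mag <- pmin(abs(d), n - abs(d))
  sgn <- ifelse(abs(d) == n / 2, 1, sign(d))
  sgn * mag * params$octaves_per_index
}

#' FM sweep responses and direction selectivity of a frozen cell
#'
#' Presents the UP and the DOWN sweep (one-step tones advancing one channel
#' every \code{sweep_interval} steps, inputs jointly rescaled to
#' \code{sweep_input_max}) to the frozen cell and returns the mean rates
#' over the \code{sweep_steps}-step sweeps together with the selectivity
#' index \eqn{(r_{up} - r_{down}) / (r_{up} + r_{down})}; positive values
#' indicate UP preference. If both rates are zero the selectivity is
#' reported as 0 with \code{undefined = TRUE}.
#'
#' @param w a [synaptic_weights()] object.
#' @param params a [model_params()] object.
#' @return an object of class \code{sweep_result}: list with
#'   \code{rate_up}, \code{rate_down}, \code{selectivity},
#'   \code{undefined}.
#' @export
measure_sweep_selectivity <- function(w, params) {
  rate_for <- function(direction) {
    ev <- fm_sweep_events(direction, params)
    tr <- events_to_traces(ev, params,
                           rescale_max = params$sweep_input_max,
                           kind = "sweep")
    mean(frozen_response(w, tr, params))
  }
  up <- rate_for("UP")
  down <- rate_for("DOWN")
  denom <- up + down
  undefined <- denom <= 0
  structure(list(rate_up = up, rate_down = down,
                 selectivity = if (undefined) 0 else (up - down) / denom,
                 undefined = undefined),
            class = "sweep_result")
}

#' Per-cell receptive-field table at one snapshot
#'
#' Probes every cell's ON and OFF FRAs at snapshot time \code{t} and
#' returns centre-of-mass CFs and their signed octave difference. Cells
#' with an all-zero FRA surface get \code{NA} and are counted in the
#' \code{n_undefined} attribute.
#'
#' @param records list of \code{sim_record}s from [run_population()].
#' @param t snapshot step.
#' @param sweep also measure sweep selectivity (default \code{FALSE}).
#' @return data.frame with columns \code{cell}, \code{on_cf},
#'   \code{off_cf}, \code{cf_diff_oct} and, if requested, \code{rate_up},
#'   \code{rate_down}, \code{selectivity}.
#' @export
population_fra_table <- function(records, t, sweep = FALSE) {
  params <- records[[1]]$params
  rows <- lapply(seq_along(records), function(k) {
    w <- snapshot_weights(records[[k]], t)
    fra <- measure_model_fra(w, params)
    on_cf <- tryCatch(fra_cf(fra$on_resp), error = function(e) NA_real_)
    off_cf <- tryCatch(fra_cf(fra$off_resp), error = function(e) NA_real_)
    row <- data.frame(
      cell = if (is.null(records[[k]]$cell)) k else records[[k]]$cell,
      on_cf = on_cf, off_cf = off_cf,
      cf_diff_oct = if (is.na(on_cf) || is.na(off_cf)) NA_real_ else
        cf_difference_octaves(on_cf, off_cf, params),
      well_formed = fra_well_formed(fra$on_resp) &&
        fra_well_formed(fra$off_resp))
    if (sweep) {
      sw <- measure_sweep_selectivity(w, params)
      row$rate_up <- sw$rate_up
      row$rate_down <- sw$rate_down
      row$selectivity <- sw$selectivity
      row$sweep_undefined <- sw$undefined
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "n_undefined") <- sum(is.na(out$cf_diff_oct))
  out
}

#' Divergence statistics between two population time points
#'
#' Compares the absolute ON/OFF CF differences (octaves) of a simulated
#' population at two snapshot times: mean |CF difference| at each time and
#' a two-sample Kolmogorov-Smirnov test between the two samples. Cells
#' with undefined CFs are excluded and counted.
#'
#' @param records list of \code{sim_record}s.
#' @param t_a,t_b the two snapshot steps (e.g. young and adult).
#' @return list with \code{mean_a}, \code{mean_b}, \code{ks_statistic},
#'   \code{p_value}, \code{n_a}, \code{n_b}, \code{n_excluded}.
#' @export
population_divergence_stats <- function(records, t_a, t_b) {
  tab_a <- population_fra_table(records, t_a)
  tab_b <- population_fra_table(records, t_b)
  a <- abs(tab_a$cf_diff_oct[!is.na(tab_a$cf_diff_oct)])
  b <- abs(tab_b$cf_diff_oct[!is.na(tab_b$cf_diff_oct)])
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 cells with defined CFs at both time points")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(mean_a = mean(a), mean_b = mean(b),
       ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       n_a = length(a), n_b = length(b),
       n_excluded = attr(tab_a, "n_undefined") + attr(tab_b, "n_undefined"))
}

#' Correlation between ON/OFF CF arrangement and sweep selectivity
#'
#' Pearson correlation across cells between the signed CF difference in
#' octaves and the FM sweep selectivity index, at one snapshot (normally
#' the adult time point). Following the published axis convention the CF
#' difference is reported as OFF minus ON by default, so positive values
#' mean the OFF CF sits above the ON CF; cells whose ON CF is the higher
#' one then prefer UP sweeps, giving a negative correlation. Mirroring
#' the in vivo analysis, which included only units with clear V-shaped ON
#' and OFF receptive fields, cells enter the correlation only if both
#' FRAs pass [fra_well_formed()], their CFs are defined, and their sweep
#' response is measurable; \code{n} reports how many cells remain.
#'
#' @param records list of \code{sim_record}s.
#' @param t snapshot step (defaults to the records' final step).
#' @param cf_sign \code{"off_minus_on"} (default, the published figure
#'   axis) or \code{"on_minus_off"}.
#' @return list with \code{pearson_r}, \code{p_value}, \code{n}, and the
#'   per-cell \code{table}.
#' @export
cfdiff_selectivity_correlation <- function(records,
                                           t = max(records[[1]]$snapshot_steps),
                                           cf_sign = c("off_minus_on",
                                                       "on_minus_off")) {
  cf_sign <- match.arg(cf_sign)
  tab <- population_fra_table(records, t, sweep = TRUE)
  # mirror the in vivo inclusion criterion: V-shaped ON and OFF RFs with
  # defined CFs and a measurable sweep response
  tab <- tab[!is.na(tab$cf_diff_oct) & !tab$sweep_undefined &
               tab$well_formed, ]
  if (nrow(tab) < 3)
    stop("need at least 3 well-formed cells with sweep responses")
  x <- if (cf_sign == "off_minus_on") -tab$cf_diff_oct else tab$cf_diff_oct
  if (stats::sd(x) == 0 || stats::sd(tab$selectivity) == 0)
    stop("zero variance in CF differences or selectivity; ",
         "correlation undefined")
  ct <- stats::cor.test(x, tab$selectivity, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(tab), table = tab)
}
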