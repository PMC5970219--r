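#' Onset/offset event train
#'
#' Per-channel sorted onset and offset step indices (1-based, within
#' \code{1..n_steps}). Within a channel, onsets and offsets strictly
#' alternate, starting with an onset; a channel that is still ON when the
#' train ends has one more onset than offset.
#'
#' @param onsets,offsets lists of length \code{n_channels} of sorted integer
#'   step vectors.
#' @param n_steps total duration in steps.
#' @param n_channels number of channels.
#' @return an object of class \code{event_train}.
#' @export
event_train <- function(onsets, offsets, n_steps, n_channels) {
  stopifnot(length(onsets) == n_channels, length(offsets) == n_channels)
  for (j in seq_len(n_channels)) {
    on <- onsets[[j]]; off <- offsets[[j]]
    if (length(on) - length(off) < 0 || length(on) - length(off) > 1)
      stop("channel ", j, ": onset/offset counts must differ by 0 or 1")
    if (length(off) > 0) {
      ok <- all(off > on[seq_along(off)]) &&
        (length(on) < 2 ||
           all(on[-1] > off[seq_len(length(on) - 1)]))
      if (!ok)
        stop("channel ", j, ": onsets and offsets must strictly alternate")
    }
    if (length(on) && (min(on) < 1 || max(c(on, off)) > n_steps))
      stop("channel ", j, ": event times outside 1..n_steps")
  }
  structure(list(onsets = onsets, offsets = offsets,
                 n_steps = as.integer(n_steps),
                 n_channels = as.integer(n_channels)),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat("<event_train>", x$n_channels, "channels,", x$n_steps, "steps,",
      sum(lengths(x$onsets)), "onsets /", sum(lengths(x$offsets)),
      "offsets\n")
  invisible(x)
}

#' Time x channel stimulus drive
#'
#' Container for the drive delivered to the ON and OFF input populations.
#' For sound and sweep traces the arrays are already tuned (via the Gaussian
#' tuning matrix) and jointly rescaled; for spontaneous traces the arrays
#' hold the per-channel stimulus activity itself (temporal mean 1), and
#' tuning is applied by the simulation.
#'
#' @param on_drive,off_drive \code{n_steps x n_channels} non-negative
#'   matrices.
#' @param kind one of \code{"spontaneous"}, \code{"sound"}, \code{"sweep"},
#'   \code{"probe"}.
#' @return an object of class \code{stimulus_traces}.
#' @export
stimulus_traces <- function(on_drive, off_drive,
                            kind = c("sound", "spontaneous", "sweep",
                                     "probe")) {
  kind <- match.arg(kind)
  stopifnot(all(dim(on_drive) == dim(off_drive)))
  if (min(on_drive) < 0 || min(off_drive) < 0)
    stop("stimulus traces must be non-negative")
  structure(list(on_drive = on_drive, off_drive = off_drive, kind = kind),
            class = "stimulus_traces")
}

# First-order exponential low-pass: x[t] = a x[t-1] + (1 - a) raw[t].
ar1_filter <- function(raw, tc) {
  a <- exp(-1 / tc)
  as.numeric(stats::filter((1 - a) * raw, a, method = "recursive"))
}

# Impulse response accumulator: trace[t] = a trace[t-1] + impulse[t], i.e.
# the trace jumps by the impulse height at an event and decays by exp(-1/tau)
# per step otherwise.
decay_accumulate <- function(impulses, tau) {
  as.numeric(stats::filter(impulses, exp(-1 / tau), method = "recursive"))
}

#' Spontaneous (pre-hearing) input traces
#'
#' Each frequency channel carries independent uniform noise on
#' \eqn{[-0.5, 0.5]} passed through a first-order exponential filter with
#' time constant \code{spont_tc}, reduced by the constant \code{theta_x},
#' rectified at zero, and rescaled so its temporal mean is exactly 1. ON and
#' OFF populations (and excitation and inhibition) share the same trace per
#' channel, emulating synchronised spontaneous activity before hearing
#' onset.
#'
#' @param params a [model_params()] object.
#' @param seed optional integer seed.
#' @param n_steps duration; defaults to \code{params$n_steps_pre}.
#' @return a [stimulus_traces()] object of kind \code{"spontaneous"} whose
#'   \code{on_drive} and \code{off_drive} are identical.
#' @export
generate_spontaneous_traces <- function(params, seed = NULL,
                                        n_steps = params$n_steps_pre) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_channels
  for (attempt in 1:5) {
    raw <- matrix(stats::runif(n_steps * n, -0.5, 0.5), n_steps, n)
    s <- apply(raw, 2, ar1_filter, tc = params$spont_tc)
    s <- pmax(s - params$theta_x, 0)
    mu <- colMeans(s)
    if (all(mu > 0)) {
      s <- sweep(s, 2, mu, "/")
      return(stimulus_traces(s, s, kind = "spontaneous"))
    }
    message("spontaneous trace degenerate (all-zero channel); ",
            "regenerating with perturbed seed")
    if (!is.null(seed)) set.seed(seed + attempt)
  }
  stop("spontaneous traces are all zero after rectification; ",
       "theta_x = ", params$theta_x, " exceeds the filtered noise range")
}

# Alternating geometric dwells for one two-state on/off chain.
# Returns matrix with columns onset, offset (offset NA if truncated).
chain_periods <- function(n_steps, p_switch_on, p_switch_off) {
  onsets <- integer(0); offsets <- integer(0)
  t <- 1L
  state_on <- FALSE
  while (t <= n_steps) {
    if (!state_on) {
      t <- t + stats::rgeom(1, p_switch_on)       # first eligible step counts
      if (t > n_steps) break
      onsets <- c(onsets, t)
      state_on <- TRUE
      t <- t + 1L                                  # cannot switch same step
    } else {
      t <- t + stats::rgeom(1, p_switch_off)
      if (t > n_steps) break
      offsets <- c(offsets, t)
      state_on <- FALSE
      t <- t + 1L
    }
  }
  list(onsets = onsets, offsets = offsets)
}

#' Stochastic sound on/off switching sequence
#'
#' In the \code{single_channel} condition a single global sound alternates
#' between silence and one active channel: from silence, each step switches
#' the sound ON with probability \code{p_off} (the active channel drawn
#' uniformly at random); while ON, each step switches it OFF with
#' probability \code{p_on}, so at most one channel is ON at any step. In the
#' \code{overlapping} condition every channel runs its own independent
#' two-state chain (default switch-on probability 1/500), so multiple
#' frequencies can sound at once.
#'
#' @param params a [model_params()] object.
#' @param mode \code{"single_channel"} or \code{"overlapping"}.
#' @param seed optional integer seed.
#' @param n_steps duration; defaults to \code{params$n_steps_sound}.
#' @return an [event_train()].
#' @export
generate_switching_sequence <- function(params,
                                        mode = c("single_channel",
                                                 "overlapping"),
                                        seed = NULL,
                                        n_steps = params$n_steps_sound) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_channels
  p_off <- resolve_p_off(params, mode)
  onsets <- rep(list(integer(0)), n)
  offsets <- rep(list(integer(0)), n)
  if (mode == "single_channel") {
    per <- chain_periods(n_steps, p_off, params$p_on)
    ch <- sample.int(n, length(per$onsets), replace = TRUE)
    for (j in seq_len(n)) {
      k <- which(ch == j)
      onsets[[j]] <- per$onsets[k]
      offsets[[j]] <- per$offsets[k[k <= length(per$offsets)]]
    }
  } else {
    for (j in seq_len(n)) {
      per <- chain_periods(n_steps, p_off, params$p_on)
      onsets[[j]] <- per$onsets
      offsets[[j]] <- per$offsets
    }
  }
  event_train(onsets, offsets, n_steps, n)
}

#' Independent ON and OFF switching sequences
#'
#' Generates two statistically independent single-channel switching
#' sequences. In the independent-channels stimulation scheme the ON inputs
#' are pulsed by the onset events of the first train and the OFF inputs by
#' the offset events of the second, so onsets and offsets need not
#' alternate.
#'
#' @inheritParams generate_switching_sequence
#' @return a list with elements \code{on_train} and \code{off_train}.
#' @export
generate_independent_sequences <- function(params, seed = NULL,
                                           n_steps = params$n_steps_sound) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2)
  list(on_train = generate_switching_sequence(params, "single_channel",
                                              seed = sub[1],
                                              n_steps = n_steps),
       off_train = generate_switching_sequence(params, "single_channel",
                                               seed = sub[2],
                                               n_steps = n_steps))
}

# Tuned, optionally rescaled drive from explicit per-channel impulse lists.
# rescale_mode "peak": the ceiling applies to the largest single-input
# value; "total": it applies to the largest momentary population input of
# either class (the sum of the tuned ON inputs, or of the OFF inputs),
# which sets single-input pulse peaks a factor of ~3 (the tuning-curve
# mass) below the ceiling.
impulse_traces <- function(on_events, off_events, n_steps, params,
                           rescale_max = NULL, heights = 1,
                           rescale_mode = c("peak", "total", "total_joint"),
                           kind = "sound") {
  rescale_mode <- match.arg(rescale_mode)
  n <- params$n_channels
  T <- tuning_matrix(params)
  pulse <- function(ev_list) {
    m <- matrix(0, n_steps, n)
    for (j in seq_len(n)) {
      tt <- ev_list[[j]]
      if (length(tt)) {
        for (t in tt) m[t, j] <- m[t, j] + heights
      }
    }
    apply(m, 2, decay_accumulate, tau = params$tau_decay) %*% T
  }
  x_on <- pulse(on_events)
  x_off <- pulse(off_events)
  if (!is.null(rescale_max)) {
    peak <- switch(rescale_mode,
                   peak = max(max(x_on), max(x_off)),
                   total = max(max(rowSums(x_on)), max(rowSums(x_off))),
                   total_joint = max(rowSums(x_on) + rowSums(x_off)))
    if (peak <= 0) {
      warning("empty event train: traces are all zero, skipping rescale")
    } else {
      sc <- rescale_max / peak
      x_on <- x_on * sc
      x_off <- x_off * sc
    }
  }
  stimulus_traces(x_on, x_off, kind = kind)
}

#' Convert an event train to tuned input traces
#'
#' Each onset event increments the channel's ON pulse trace by 1 and each
#' offset event its OFF pulse trace by 1; between events the traces decay by
#' \eqn{\exp(-1/\tau)} per step. Both pulse arrays are then passed through
#' the Gaussian tuning matrix and jointly rescaled so their global maximum
#' equals \code{rescale_max} (40 for sound exposure, 2 for FM sweeps).
#'
#' @param events an [event_train()].
#' @param params a [model_params()] object.
#' @param rescale_max joint ceiling, or \code{NULL} to skip rescaling.
#' @param kind trace label, see [stimulus_traces()].
#' @return a [stimulus_traces()] object.
#' @export
events_to_traces <- function(events, params, rescale_max = params$input_max,
                             kind = "sound",
                             rescale_mode = c("peak", "total",
                                              "total_joint")) {
  stopifnot(inherits(events, "event_train"))
  rescale_mode <- match.arg(rescale_mode)
  impulse_traces(events$onsets, events$offsets, events$n_steps, params,
                 rescale_max = rescale_max, rescale_mode = rescale_mode,
                 kind = kind)
}

# Independent condition: ON pulses from onsets of train A, OFF pulses from
# offsets of train B, jointly rescaled.
independent_traces <- function(on_train, off_train, params,
                               rescale_max = params$input_max,
                               rescale_mode = c("peak", "total",
                                                "total_joint")) {
  stopifnot(on_train$n_steps == off_train$n_steps)
  rescale_mode <- match.arg(rescale_mode)
  impulse_traces(on_train$onsets, off_train$offsets, on_train$n_steps,
                 params, rescale_max = rescale_max,
                 rescale_mode = rescale_mode, kind = "sound")
}

#' Frequency-modulated sweep event train
#'
#' The sweep tone is presented in one frequency channel, then
#' \code{sweep_interval} steps later in the next channel up (UP sweep) or
#' down (DOWN sweep), with circular wrap-around, for \code{sweep_steps}
#' steps in total. Each band change produces an onset event in the new
#' channel at the same step as the offset event of the channel it leaves,
#' so offset- and onset-evoked activity of adjacent channels coincide and
#' can summate -- the temporal structure that underlies direction
#' selectivity of the model.
#'
#' @param direction \code{"UP"} or \code{"DOWN"}.
#' @param params a [model_params()] object.
#' @param start_channel first channel; defaults to 1 for UP and
#'   \code{n_channels} for DOWN (so DOWN is the channel-reflected mirror of
#'   UP).
#' @return an [event_train()].
#' @export
fm_sweep_events <- function(direction = c("UP", "DOWN"), params,
                            start_channel = NULL) {
  direction <- match.arg(direction)
  n <- params$n_channels
  if (is.null(start_channel)) start_channel <- if (direction == "UP") 1L else n
  k <- seq_len(params$sweep_steps %/% params$sweep_interval) - 1L
  t_on <- 1L + k * params$sweep_interval
  step <- if (direction == "UP") 1L else -1L
  ch <- ((start_channel - 1L + step * k) %% n) + 1L
  onsets <- rep(list(integer(0)), n)
  offsets <- rep(list(integer(0)), n)
  t_off <- t_on + params$sweep_interval   # tone leaves the band
  for (j in seq_len(n)) {
    onsets[[j]] <- t_on[ch == j]
    offsets[[j]] <- t_off[ch == j]
  }
  event_train(onsets, offsets, params$sweep_steps + params$sweep_interval, n)
}

#' Tuned tone-probe traces for one channel and intensity
#'
#' A sustained probe tone in one channel: an onset pulse of height
#' \code{intensity} drives the ON inputs at step 1 and, after the tone
#' duration, an offset pulse of the same height drives the OFF inputs. Both
#' pulse traces decay with \code{tau_decay} and are tuned; no global
#' rescaling is applied, so the intensity carries the level information.
#'
#' @param channel probed channel index.
#' @param intensity tone intensity (> 0); the probe ladder spans
#'   \code{probe_min} to \code{probe_max}.
#' @param params a [model_params()] object.
#' @return a [stimulus_traces()] object of kind \code{"probe"} covering the
#'   tone plus the OFF response window.
#' @export
tone_probe_traces <- function(channel, intensity, params) {
  if (!is.numeric(intensity) || intensity <= 0)
    stop("intensity must be positive")
  if (channel < 1 || channel > params$n_channels)
    stop("channel out of range")
  n_steps <- params$probe_tone_steps + params$probe_window
  on_ev <- rep(list(integer(0)), params$n_channels)
  off_ev <- rep(list(integer(0)), params$n_channels)
  on_ev[[channel]] <- 1L
  off_ev[[channel]] <- 1L + params$probe_tone_steps
  impulse_traces(on_ev, off_ev, n_steps, params, rescale_max = NULL,
                 heights = intensity, kind = "probe")
}

#' Default probe intensity ladder
#'
#' Evenly spaced intensities from \code{probe_min} (19.5) to
#' \code{probe_max} (65).
#'
#' @param params a [model_params()] object.
#' @return numeric vector of length \code{probe_levels}.
#' @export
probe_intensities <- function(params) {
  seq(params$probe_min, params$probe_max, length.out = params$probe_levels)
}
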