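#' Run the plasticity simulation over precomputed input traces
#'
#' Low-level driver around the compiled simulation loop. Each step computes
#' the membrane voltage from the current weights and the step's tuned ON and
#' OFF drive (shared by excitation and inhibition), the threshold-linear
#' rate, the excitatory update (Hebbian with synaptic noise, or homeostatic
#' synaptic scaling), the inhibitory magnitude update, and the weight
#' constraints. Synaptic noise is drawn from R's RNG stream, so results are
#' reproducible under \code{set.seed()}.
#'
#' @param x_on,x_off \code{n_steps x n_channels} tuned drive matrices.
#' @param start a [synaptic_weights()] object (inhibitory entries are
#'   magnitudes \code{-w}).
#' @param params a [model_params()] object.
#' @param use_inhib include inhibitory inputs in the voltage.
#' @param plastic_inhib apply the inhibitory plasticity rule and its
#'   normalisation (ignored when \code{use_inhib} is \code{FALSE}).
#' @param rule \code{"hebbian"} (default) or \code{"scaling"} (homeostatic
#'   synaptic scaling replaces the Hebbian term and the excitatory L1
#'   normalisation).
#' @param snapshot_steps sorted non-negative step counts at which to record
#'   weights (0 = initial state).
#' @return list with \code{weights} (final [synaptic_weights()]),
#'   \code{snapshots} (named list keyed \code{"t<step>"}), and
#'   \code{mean_rate}.
#' @export
simulate_weights <- function(x_on, x_off, start, params,
                             use_inhib = TRUE, plastic_inhib = TRUE,
                             rule = c("hebbian", "scaling"),
                             snapshot_steps = integer(0)) {
  rule <- match.arg(rule)
  stopifnot(inherits(start, "synaptic_weights"),
            ncol(x_on) == params$n_channels)
  snapshot_steps <- sort(unique(as.integer(snapshot_steps)))
  if (length(snapshot_steps) &&
      (min(snapshot_steps) < 0 || max(snapshot_steps) > nrow(x_on)))
    stop("snapshot steps must lie in [0, n_steps]")
  out <- .sim_core(x_on, x_off,
                   start$w_on_e, start$w_off_e,
                   -start$w_on_i, -start$w_off_i,
                   params$theta, params$alpha_e, params$alpha_i, params$rho,
                   params$eta_bound, params$excit_l1, params$inhib_l1,
                   params$w_min, params$w_max, params$scaling_factor,
                   use_inhib, plastic_inhib,
                   if (rule == "hebbian") 0L else 1L,
                   if (params$inhib_norm == "cap") 1L else 0L,
                   if (params$inhib_rule == "magnitude") 0L else 1L,
                   snapshot_steps)
  snaps <- if (length(snapshot_steps) == 0) list() else stats::setNames(
    lapply(seq_along(snapshot_steps), function(k)
      synaptic_weights(out$snap_on_e[k, ], out$snap_off_e[k, ],
                       out$snap_on_i[k, ], out$snap_off_i[k, ])),
    paste0("t", snapshot_steps))
  list(weights = synaptic_weights(out$w_on_e, out$w_off_e,
                                  out$w_on_i, out$w_off_i),
       snapshots = snaps, mean_rate = out$mean_rate)
}

#' Pre-hearing developmental phase
#'
#' Starting from uniform excitatory weights \eqn{1/(2N)} and zero
#' inhibition, the neuron is driven for \code{n_steps_pre} steps by
#' synchronised spontaneous activity (shared per channel by ON/OFF and
#' excitation/inhibition) with full plasticity. Because ON and OFF inputs
#' receive identical drive, the returned hearing-onset weights have matched
#' ON and OFF receptive fields up to synaptic noise.
#'
#' @param params a [model_params()] object.
#' @param seed integer seed for the phase (traces and synaptic noise).
#' @return the hearing-onset [synaptic_weights()].
#' @export
run_pre_hearing <- function(params, seed = NULL) {
  traces <- generate_spontaneous_traces(params, seed = seed)
  T <- tuning_matrix(params)
  x <- traces$on_drive %*% T
  simulate_weights(x, x, initial_weights(params), params,
                   use_inhib = TRUE, rule = "hebbian")$weights
}

#' Default snapshot schedule for the sound-exposure phase
#'
#' Covers the early divergence time course plus the Young (\code{t_young})
#' and Adult (\code{t_adult}) time points; always includes 0 (hearing
#' onset) and the final step.
#'
#' @param params a [model_params()] object.
#' @return sorted integer vector of snapshot steps.
#' @export
default_snapshots <- function(params) {
  s <- c(0L, 500L, 1000L, params$t_young, 5000L, 20000L, params$t_adult,
         params$n_steps_sound)
  sort(unique(s[s >= 0 & s <= params$n_steps_sound]))
}

sound_conditions <- c("single_channel", "overlapping", "independent_on_off",
                      "excitation_only", "scaling_only")

# Stimulus traces for one sound-exposure condition.
condition_traces <- function(params, condition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- switch(params$input_rescale, per_input = "peak",
                 params$input_rescale)
  switch(condition,
    overlapping = events_to_traces(
      generate_switching_sequence(params, "overlapping"),
      params, rescale_max = params$input_max, rescale_mode = mode),
    independent_on_off = {
      tr <- generate_independent_sequences(params)
      independent_traces(tr$on_train, tr$off_train, params,
                         rescale_mode = mode)
    },
    # single_channel, excitation_only and scaling_only share the
    # single-channel alternating sound stimulus
    events_to_traces(
      generate_switching_sequence(params, "single_channel"),
      params, rescale_max = params$input_max, rescale_mode = mode))
}

#' Sound-exposure developmental phase
#'
#' Runs \code{n_steps_sound} steps of plasticity from the given starting
#' weights under one of five conditions: \code{"single_channel"}
#' (alternating onset/offset sound in one channel at a time, the reference
#' condition), \code{"overlapping"} (channels switch independently with
#' switch-on probability 1/500), \code{"independent_on_off"} (ON inputs
#' pulsed by onsets of one sequence, OFF inputs by offsets of an
#' independent one), \code{"excitation_only"} (inhibitory inputs and their
#' rule removed; inhibitory weights are zeroed), or \code{"scaling_only"}
#' (homeostatic synaptic scaling replaces the entire Hebbian framework --
#' excitatory rule, weight bounds and normalisation, and the inhibitory
#' rule -- acting on the excitatory circuit alone, so weight ratios are
#' preserved exactly).
#'
#' @param start hearing-onset [synaptic_weights()].
#' @param params a [model_params()] object.
#' @param condition one of the five condition names.
#' @param seed integer seed for the phase (stimulus and synaptic noise).
#' @param snapshot_steps steps at which weights are recorded; defaults to
#'   [default_snapshots()].
#' @return an object of class \code{sim_record}: list with
#'   \code{condition}, \code{seed}, \code{params}, \code{snapshots} (named
#'   list of [synaptic_weights()]), \code{snapshot_steps},
#'   \code{weights} (final), and \code{mean_rate}.
#' @export
run_sound_phase <- function(start, params, condition = "single_channel",
                            seed = NULL,
                            snapshot_steps = default_snapshots(params)) {
  condition <- match.arg(condition, sound_conditions)
  if (!is.null(seed)) set.seed(seed)
  traces <- condition_traces(params, condition)
  # excitation_only removes inhibition to probe its role in divergence;
  # scaling_only removes the whole Hebbian framework (excitatory rule,
  # bounds/normalisation, and the likewise-Hebbian inhibitory rule) so
  # that the homeostatic rule acts on the excitatory circuit alone
  no_inhib <- condition %in% c("excitation_only", "scaling_only")
  if (no_inhib) {
    n <- params$n_channels
    start <- synaptic_weights(start$w_on_e, start$w_off_e,
                              rep(0, n), rep(0, n))
  }
  sim <- simulate_weights(
    traces$on_drive, traces$off_drive, start, params,
    use_inhib = !no_inhib,
    rule = if (condition == "scaling_only") "scaling" else "hebbian",
    snapshot_steps = snapshot_steps)
  structure(list(condition = condition, seed = seed, params = params,
                 snapshot_steps = sort(unique(as.integer(snapshot_steps))),
                 snapshots = sim$snapshots, weights = sim$weights,
                 mean_rate = sim$mean_rate),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record>", x$condition, "condition, seed", x$seed, "\n")
  cat("  snapshots at:", paste(x$snapshot_steps, collapse = ", "), "\n")
  cat("  mean output rate:", format(x$mean_rate, digits = 4), "\n")
  invisible(x)
}

#' Weights stored at a snapshot time
#'
#' @param record a \code{sim_record} from [run_sound_phase()].
#' @param t snapshot step.
#' @return a [synaptic_weights()] object.
#' @export
snapshot_weights <- function(record, t) {
  key <- paste0("t", as.integer(t))
  if (is.null(record$snapshots[[key]]))
    stop("no snapshot at t = ", t, "; available: ",
         paste(record$snapshot_steps, collapse = ", "))
  record$snapshots[[key]]
}

#' Simulate a population of independent model cells
#'
#' Runs \code{n_cells} end-to-end developmental simulations (pre-hearing
#' phase followed by the sound-exposure phase of the given condition).
#' Per-cell seeds for the two phases are split deterministically from
#' \code{master_seed}, so cells are mutually independent, results are
#' identical regardless of execution order, and the same master seed always
#' reproduces the same population.
#'
#' @param n_cells number of cells (the published population uses 100).
#' @param params a [model_params()] object.
#' @param condition sound-exposure condition, see [run_sound_phase()].
#' @param master_seed integer master seed.
#' @param snapshot_steps snapshot schedule passed to [run_sound_phase()].
#' @return list of \code{sim_record} objects (one per cell), each carrying
#'   a \code{cell} index.
#' @export
run_population <- function(n_cells, params, condition = "single_channel",
                           master_seed = 1,
                           snapshot_steps = default_snapshots(params)) {
  stopifnot(n_cells >= 1)
  seeds <- split_seeds(master_seed, n_cells)
  lapply(seq_len(n_cells), function(k) {
    w0 <- run_pre_hearing(params, seed = seeds$pre[k])
    rec <- run_sound_phase(w0, params, condition, seed = seeds$sound[k],
                           snapshot_steps = snapshot_steps)
    rec$cell <- k
    rec
  })
}

#' Split a master seed into per-cell phase seeds
#'
#' Deterministic splitting scheme: the master seed seeds R's RNG once, from
#' which \code{2 * n_cells} sub-seeds are drawn; cell k uses the k-th seed
#' for its pre-hearing phase and the (n_cells + k)-th for its sound phase.
#'
#' @param master_seed integer master seed.
#' @param n_cells number of cells.
#' @return list with integer vectors \code{pre} and \code{sound}.
#' @export
split_seeds <- function(master_seed, n_cells) {
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, 2L * n_cells)
  list(pre = s[seq_len(n_cells)], sound = s[n_cells + seq_len(n_cells)])
}
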