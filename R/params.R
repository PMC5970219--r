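#' Model parameters for the ON/OFF receptive-field development model
#'
#' Collects every constant of the rate-based feedforward model in one
#' validated record. Defaults are the published values of the model:
#' a threshold-linear neuron with \code{n_channels = 10} frequency channels,
#' Gaussian input tuning of width \code{sigma = 1.5}, firing threshold
#' \code{theta = 2.5}, Hebbian excitatory learning rate \code{alpha_e = 1e-4}
#' with multiplicative synaptic noise drawn uniformly from
#' \code{[-eta_bound, eta_bound]}, a rate-based inhibitory rule with learning
#' rate \code{alpha_i = 1e-5} and target rate \code{rho = 0.01}, and
#' exponentially decaying onset/offset input pulses with time constant
#' \code{tau_decay = 10} steps. One simulation step is interpreted as 1 ms.
#'
#' @param n_channels number of tonotopic frequency channels (N).
#' @param theta firing threshold of the threshold-linear unit.
#' @param sigma Gaussian tuning width, in channel indices.
#' @param alpha_e excitatory Hebbian learning rate.
#' @param alpha_i inhibitory learning rate.
#' @param rho inhibitory target rate.
#' @param eta_bound half-width of the uniform multiplicative synaptic noise.
#' @param tau_decay decay time constant of input pulses, in steps.
#' @param p_on per-step probability that a sound that is ON switches OFF.
#' @param p_off per-step probability that a silent channel switches ON.
#'   \code{NULL} (default) resolves by stimulus mode: 1/50 in the
#'   single-channel condition, 1/500 in the overlapping condition.
#' @param n_steps_pre duration of the pre-hearing (spontaneous) phase.
#' @param n_steps_sound duration of the sound-exposure phase.
#' @param input_max rescale ceiling for sound-evoked input traces.
#' @param input_rescale how the sound-exposure ceiling is applied:
#'   \code{"total_joint"} (default) caps the maximal momentary population
#'   input (the sum over all ON and OFF input channels together), so
#'   individual evoked pulses peak a little above the firing threshold
#'   and tone-evoked firing stays frequency selective; \code{"total"}
#'   caps the larger of the two per-class sums; \code{"per_input"} caps
#'   the largest single input value.
#' @param sweep_input_max rescale ceiling for FM-sweep input traces
#'   (applied to the largest single input value, so coincident onset and
#'   offset pulses summate to just above threshold).
#' @param spont_tc time constant of the spontaneous-noise filter.
#' @param theta_x constant subtracted from filtered spontaneous noise.
#' @param excit_l1 L1 target of each excitatory weight class: the ON and
#'   the OFF excitatory weights are each kept at an L1 norm of 2.
#' @param inhib_l1 L1 magnitude target of each inhibitory weight class:
#'   the ON and OFF inhibitory synapses jointly undergo an L1
#'   normalisation of 1, i.e. 0.5 per class, so evoked excitation
#'   dominates co-tuned inhibition.
#' @param inhib_rule \code{"magnitude"} (default): the inhibitory update
#'   strengthens inhibition when the rate exceeds \eqn{\rho}, developing
#'   excitatory/inhibitory co-tuning; \code{"literal"}: the update is
#'   applied to the negative weights as written, so inhibition withdraws
#'   from strongly driving channels and accumulates in sidebands.
#' @param inhib_norm \code{"cap"} (default): the inhibitory L1 value acts
#'   as a ceiling, so inhibition grows gradually from its zero
#'   initialisation under the rate-based rule and is rescaled only once a
#'   class exceeds the target; \code{"exact"}: any nonzero class is
#'   rescaled to the target every step.
#' @param w_min,w_max bounds on individual excitatory weights.
#' @param octaves_per_index octaves per unit channel-index difference
#'   (10 channels span 5 octaves, so an index difference of 2 is 1 octave).
#' @param t_young,t_adult simulation steps defining the "Young" and "Adult"
#'   snapshots of the sound-exposure phase.
#' @param scaling_factor multiplicative step of the synaptic-scaling
#'   alternative rule.
#' @param tuning_denominator \code{"2sigma"} (default, the model as printed:
#'   \eqn{T_{ij} = \exp(-d^2 / (2\sigma))}) or \code{"2sigma2"}
#'   (\eqn{\exp(-d^2 / (2\sigma^2))}).
#' @param sweep_interval steps between successive sweep tone presentations.
#' @param sweep_steps total duration of one FM sweep probe.
#' @param probe_min,probe_max,probe_levels intensity ladder used to probe
#'   model frequency response areas.
#' @param probe_tone_steps duration of a probe tone, in steps.
#' @param probe_window length of the ON/OFF response window used when
#'   probing, in steps.
#'
#' @return an object of class \code{model_params} (a validated named list).
#' @export
#' @examples
#' p <- model_params()
#' p$theta
model_params <- function(n_channels = 10L,
                         theta = 2.5,
                         sigma = 1.5,
                         alpha_e = 1e-4,
                         alpha_i = 1e-5,
                         rho = 0.01,
                         eta_bound = 0.0025,
                         tau_decay = 10,
                         p_on = 1 / 50,
                         p_off = NULL,
                         n_steps_pre = 100000L,
                         n_steps_sound = 100000L,
                         input_max = 40,
                         input_rescale = c("total_joint", "total",
                                           "per_input"),
                         sweep_input_max = 2,
                         spont_tc = 5,
                         theta_x = 0.1,
                         excit_l1 = 2.0,
                         inhib_l1 = 0.5,
                         inhib_rule = c("magnitude", "literal"),
                         inhib_norm = c("cap", "exact"),
                         w_min = 0,
                         w_max = 1,
                         octaves_per_index = 0.5,
                         t_young = 1500L,
                         t_adult = 100000L,
                         scaling_factor = 1e-5,
                         tuning_denominator = c("2sigma", "2sigma2"),
                         sweep_interval = 50L,
                         sweep_steps = 3000L,
                         probe_min = 19.5,
                         probe_max = 65,
                         probe_levels = 8L,
                         probe_tone_steps = 100L,
                         probe_window = 30L) {
  tuning_denominator <- match.arg(tuning_denominator)
  inhib_rule <- match.arg(inhib_rule)
  inhib_norm <- match.arg(inhib_norm)
  input_rescale <- match.arg(input_rescale)
  p <- list(
    n_channels = as.integer(n_channels), theta = theta, sigma = sigma,
    alpha_e = alpha_e, alpha_i = alpha_i, rho = rho, eta_bound = eta_bound,
    tau_decay = tau_decay, p_on = p_on, p_off = p_off,
    n_steps_pre = as.integer(n_steps_pre),
    n_steps_sound = as.integer(n_steps_sound),
    input_max = input_max, input_rescale = input_rescale,
    sweep_input_max = sweep_input_max,
    spont_tc = spont_tc, theta_x = theta_x,
    excit_l1 = excit_l1, inhib_l1 = inhib_l1, inhib_rule = inhib_rule,
    inhib_norm = inhib_norm,
    w_min = w_min, w_max = w_max,
    octaves_per_index = octaves_per_index,
    t_young = as.integer(t_young), t_adult = as.integer(t_adult),
    scaling_factor = scaling_factor,
    tuning_denominator = tuning_denominator,
    sweep_interval = as.integer(sweep_interval),
    sweep_steps = as.integer(sweep_steps),
    probe_min = probe_min, probe_max = probe_max,
    probe_levels = as.integer(probe_levels),
    probe_tone_steps = as.integer(probe_tone_steps),
    probe_window = as.integer(probe_window)
  )
  class(p) <- "model_params"
  validate_model_params(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$n_channels, "channels, theta =", x$theta,
      ", sigma =", x$sigma, paste0("(", x$tuning_denominator, ")"), "\n")
  cat("  alpha_e =", x$alpha_e, ", alpha_i =", x$alpha_i,
      ", rho =", x$rho, ", eta_bound =", x$eta_bound, "\n")
  cat("  phases:", x$n_steps_pre, "pre-hearing +", x$n_steps_sound,
      "sound steps\n")
  invisible(x)
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("model_params: ", msg,
                                                 call. = FALSE)
  chk(p$n_channels >= 2, "n_channels must be >= 2")
  chk(p$sigma > 0, "sigma must be > 0")
  chk(p$theta >= 0, "theta must be >= 0")
  chk(p$tau_decay >= 1, "tau_decay must be >= 1")
  chk(p$p_on > 0 && p$p_on <= 1, "p_on must be in (0, 1]")
  if (!is.null(p$p_off))
    chk(p$p_off > 0 && p$p_off <= 1, "p_off must be in (0, 1]")
  chk(p$n_steps_pre > 0, "n_steps_pre must be positive")
  chk(p$n_steps_sound > 0, "n_steps_sound must be positive")
  chk(p$eta_bound >= 0, "eta_bound must be >= 0")
  chk(p$excit_l1 > 0, "excit_l1 must be > 0")
  chk(p$inhib_l1 >= 0, "inhib_l1 must be >= 0")
  chk(p$w_min < p$w_max, "w_min must be below w_max")
  chk(p$spont_tc > 0, "spont_tc must be > 0")
  chk(p$octaves_per_index > 0, "octaves_per_index must be > 0")
  chk(p$scaling_factor >= 0 && p$scaling_factor < 1,
      "scaling_factor must be in [0, 1)")
  chk(p$probe_levels >= 1, "probe_levels must be >= 1")
  chk(p$probe_window >= 1, "probe_window must be >= 1")
  chk(p$sweep_interval >= 2, "sweep_interval must be >= 2")
  chk(p$sweep_steps >= p$sweep_interval, "sweep_steps too short")
  p
}

# Switch-on probability resolved by stimulus mode (1/50 single-channel,
# 1/500 overlapping) unless fixed explicitly.
resolve_p_off <- function(params, mode) {
  if (!is.null(params$p_off)) return(params$p_off)
  switch(mode, single_channel = 1 / 50, overlapping = 1 / 500,
         stop("unknown stimulus mode: ", mode))
}
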