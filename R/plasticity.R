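#' Excitatory Hebbian update with multiplicative synaptic noise
#'
#' \eqn{\Delta w_i = \alpha^e x_i y + \eta_i w_i}, where \eqn{\eta_i} is
#' drawn independently per synapse and per step from a uniform distribution
#' on \eqn{[-\eta_{bound}, \eta_{bound}]}. The noise term models synaptic
#' turnover and is multiplicative, so a silent (zero) synapse is unaffected
#' by it. Weight bounds and normalisation are applied separately by
#' [apply_weight_constraints()].
#'
#' @param w_e excitatory weight vector.
#' @param x_e matching non-negative input vector.
#' @param y postsynaptic rate (scalar, >= 0).
#' @param params a [model_params()] object.
#' @param eta optional noise vector (length of \code{w_e}); when \code{NULL}
#'   it is drawn from the current RNG stream.
#' @return updated (pre-constraint) weight vector.
#' @export
excitatory_hebbian_step <- function(w_e, x_e, y, params, eta = NULL) {
  stopifnot(length(x_e) == length(w_e), y >= 0, all(x_e >= 0))
  if (is.null(eta))
    eta <- stats::runif(length(w_e), -params$eta_bound, params$eta_bound)
  w_e + params$alpha_e * x_e * y + eta * w_e
}

#' Inhibitory plasticity update (rate-based co-tuning rule)
#'
#' Rate-based form of the inhibitory rule that drives the output rate to the
#' target \eqn{\rho}: the magnitude of each inhibitory weight changes by
#' \eqn{\Delta m_j = \alpha^i x_j (y - \rho)}, clipped at zero from below.
#' Inhibition therefore strengthens when the neuron fires above target and
#' weakens below it, developing excitatory/inhibitory co-tuning. Stored
#' weights are \eqn{w = -m}.
#'
#' @param m_i inhibitory weight magnitudes (>= 0).
#' @param x_i matching non-negative input vector.
#' @param y postsynaptic rate.
#' @param params a [model_params()] object.
#' @return updated (pre-constraint) magnitude vector.
#' @export
inhibitory_step <- function(m_i, x_i, y, params) {
  stopifnot(length(x_i) == length(m_i), all(m_i >= 0), all(x_i >= 0))
  pmax(m_i + params$alpha_i * x_i * (y - params$rho), 0)
}

#' Apply weight bounds and L1 normalisation
#'
#' Excitatory weights are clipped to \code{[w_min, w_max]} and each class
#' (ON and OFF separately) is multiplicatively rescaled to sum
#' \code{excit_l1}, so the joint excitatory L1 norm is \code{2 * excit_l1}.
#' Inhibitory magnitudes are normalised per class against the target sum
#' \code{inhib_l1}: with \code{inhib_norm = "cap"} (default) a class is
#' rescaled only when its sum exceeds the target, so inhibition can grow
#' gradually from its zero initialisation; with \code{"exact"} any nonzero
#' class is rescaled to the target. An all-zero class (the initial state)
#' is always left unchanged.
#'
#' @param w a [synaptic_weights()] object.
#' @param params a [model_params()] object.
#' @return a [synaptic_weights()] object satisfying the constraints.
#' @export
apply_weight_constraints <- function(w, params) {
  norm_e <- function(v) {
    v <- pmin(pmax(v, params$w_min), params$w_max)
    s <- sum(v)
    if (s <= 0)
      stop("excitatory weight class is all zero; L1 constraint unsatisfiable")
    v * (params$excit_l1 / s)
  }
  norm_i <- function(v) {
    m <- pmax(-v, 0)
    s <- sum(m)
    if (s <= 0) return(rep(0, length(v)))
    if (params$inhib_norm == "cap" && s <= params$inhib_l1) return(-m)
    -m * (params$inhib_l1 / s)
  }
  synaptic_weights(norm_e(w$w_on_e), norm_e(w$w_off_e),
                   norm_i(w$w_on_i), norm_i(w$w_off_i))
}

#' Running-mean state for the synaptic-scaling rule
#'
#' @param running_mean_y cumulative mean output rate since simulation start.
#' @param n_obs number of observed steps.
#' @return an object of class \code{scaling_state}.
#' @export
scaling_state <- function(running_mean_y = 0, n_obs = 0L) {
  stopifnot(running_mean_y >= 0, n_obs >= 0)
  structure(list(running_mean_y = running_mean_y, n_obs = as.integer(n_obs)),
            class = "scaling_state")
}

#' Homeostatic synaptic-scaling update (alternative to Hebbian learning)
#'
#' If the output rate exceeds the average output over the whole simulation
#' so far, all excitatory weights are scaled down multiplicatively by
#' \eqn{1 - 10^{-5}}; if it is below the average they are scaled up by
#' \eqn{1 + 10^{-5}}. The running mean (initially 0) is then updated with
#' the current rate. The uniform multiplicative update preserves the ratio
#' between any two excitatory weights.
#'
#' @param w_e named list with excitatory weight vectors \code{w_on_e} and
#'   \code{w_off_e} (a [synaptic_weights()] object works).
#' @param y current output rate.
#' @param state a [scaling_state()].
#' @param params a [model_params()] object.
#' @return list with elements \code{w_on_e}, \code{w_off_e}, \code{state}.
#' @export
synaptic_scaling_step <- function(w_e, y, state, params) {
  f <- params$scaling_factor
  fac <- if (y > state$running_mean_y) 1 - f
         else if (y < state$running_mean_y) 1 + f
         else 1
  n_obs <- state$n_obs + 1L
  mean_y <- state$running_mean_y + (y - state$running_mean_y) / n_obs
  list(w_on_e = w_e$w_on_e * fac, w_off_e = w_e$w_off_e * fac,
       state = scaling_state(mean_y, n_obs))
}
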