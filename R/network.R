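#' Gaussian input tuning matrix with circular boundary
#'
#' Each of the N input channels is tuned to the N stimulus channels with a
#' Gaussian profile over circular index distance, so channel 1 and channel N
#' are neighbours. With the default convention the entry is
#' \eqn{T_{ij} = \exp(-d(i,j)^2 / (2\sigma))} where
#' \eqn{d(i,j) = \min(|i-j|, n - |i-j|)}; the alternative convention uses
#' \eqn{2\sigma^2} in the denominator.
#'
#' @param sigma tuning width (channel indices); must be positive.
#' @param n number of channels; at least 2.
#' @param denominator \code{"2sigma"} (default) or \code{"2sigma2"}.
#' @return an \code{n x n} symmetric circulant matrix with unit diagonal.
#' @export
#' @examples
#' T <- build_tuning_matrix(1.5, 10)
#' T[1, 2]  # exp(-1/3)
build_tuning_matrix <- function(sigma, n,
                                denominator = c("2sigma", "2sigma2")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be an integer >= 2")
  n <- as.integer(n)
  idx <- seq_len(n) - 1L
  d <- abs(outer(idx, idx, "-"))
  d <- pmin(d, n - d)
  den <- if (denominator == "2sigma") 2 * sigma else 2 * sigma^2
  exp(-d^2 / den)
}

# Tuning matrix implied by a parameter set.
tuning_matrix <- function(params) {
  build_tuning_matrix(params$sigma, params$n_channels,
                      params$tuning_denominator)
}

#' Apply input tuning to a stimulus vector
#'
#' The activity of input channel i is the tuning-weighted sum over stimulus
#' channels, \eqn{x_i = \sum_j T_{ij} s_j}.
#'
#' @param T tuning matrix from [build_tuning_matrix()].
#' @param s non-negative stimulus vector of length \code{ncol(T)}.
#' @return input vector of length \code{nrow(T)}.
#' @export
apply_tuning <- function(T, s) {
  if (length(s) != ncol(T))
    stop("stimulus length ", length(s), " does not match ", ncol(T),
         " tuning columns")
  if (any(s < 0)) stop("stimulus entries must be >= 0")
  drop(T %*% s)
}

#' Membrane voltage of the threshold-linear neuron
#'
#' The voltage is the weighted sum over all four input classes:
#' excitatory and inhibitory ON inputs and excitatory and inhibitory OFF
#' inputs. Inhibitory weights are non-positive, so their terms subtract.
#'
#' @param w a [synaptic_weights()] object.
#' @param x a named list (or [input_frame()]) with non-negative vectors
#'   \code{x_on_e}, \code{x_off_e}, \code{x_on_i}, \code{x_off_i}.
#' @return scalar voltage.
#' @export
membrane_voltage <- function(w, x) {
  n <- length(w$w_on_e)
  lens <- c(length(x$x_on_e), length(x$x_off_e),
            length(x$x_on_i), length(x$x_off_i))
  if (any(lens != n))
    stop("input lengths (", paste(lens, collapse = ","),
         ") do not match weight length ", n)
  sum(w$w_on_e * x$x_on_e) + sum(w$w_off_e * x$x_off_e) +
    sum(w$w_on_i * x$x_on_i) + sum(w$w_off_i * x$x_off_i)
}

#' Threshold-linear firing rate
#'
#' \eqn{y = u - \theta} when \eqn{u > \theta}, else 0.
#'
#' @param u membrane voltage (vectorised).
#' @param theta firing threshold.
#' @return non-negative rate(s).
#' @export
firing_rate <- function(u, theta) {
  pmax(u - theta, 0)
}

#' Synaptic weight state of one model neuron
#'
#' Holds the four length-N weight vectors: excitatory and inhibitory ON
#' weights and excitatory and inhibitory OFF weights. Excitatory entries lie
#' in \code{[w_min, w_max]}; inhibitory entries are stored as the actual
#' (non-positive) weights.
#'
#' @param w_on_e,w_off_e excitatory weight vectors.
#' @param w_on_i,w_off_i inhibitory weight vectors (entries <= 0).
#' @return an object of class \code{synaptic_weights}.
#' @export
synaptic_weights <- function(w_on_e, w_off_e, w_on_i, w_off_i) {
  n <- length(w_on_e)
  stopifnot(length(w_off_e) == n, length(w_on_i) == n, length(w_off_i) == n)
  if (any(w_on_i > 1e-12) || any(w_off_i > 1e-12))
    stop("inhibitory weights must be <= 0")
  structure(list(w_on_e = as.numeric(w_on_e), w_off_e = as.numeric(w_off_e),
                 w_on_i = as.numeric(w_on_i), w_off_i = as.numeric(w_off_i)),
            class = "synaptic_weights")
}

#' Initial weights: uniform excitation at 1/(2N), zero inhibition
#'
#' @param params a [model_params()] object.
#' @return a [synaptic_weights()] object.
#' @export
initial_weights <- function(params) {
  n <- params$n_channels
  w0 <- rep(1 / (2 * n), n)
  synaptic_weights(w0, w0, rep(0, n), rep(0, n))
}

#' @export
print.synaptic_weights <- function(x, ...) {
  cat("<synaptic_weights> N =", length(x$w_on_e), "\n")
  cat("  sum ON_e =", format(sum(x$w_on_e)),
      " sum OFF_e =", format(sum(x$w_off_e)),
      " sum ON_i =", format(sum(x$w_on_i)),
      " sum OFF_i =", format(sum(x$w_off_i)), "\n")
  invisible(x)
}

#' One time step of input to all four synapse classes
#'
#' Excitatory and inhibitory inputs of a class receive the same drive, so
#' \code{x_on_i = x_on_e} and \code{x_off_i = x_off_e} by construction.
#'
#' @param x_on,x_off non-negative drive vectors for the ON and OFF classes.
#' @return an object of class \code{input_frame}.
#' @export
input_frame <- function(x_on, x_off) {
  stopifnot(length(x_on) == length(x_off))
  if (any(x_on < 0) || any(x_off < 0))
    stop("input entries must be >= 0")
  structure(list(x_on_e = x_on, x_off_e = x_off,
                 x_on_i = x_on, x_off_i = x_off),
            class = "input_frame")
}
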