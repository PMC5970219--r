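# Independent reference implementations used as oracles. These are written
# directly from the model definition (voltage -> rate -> updates ->
# constraints) with scalar loops, deliberately sharing no code with the
# package internals.

# Scalar reference for one plasticity step sequence over given drive
# matrices. Draws synaptic noise as runif(N) for the ON class then the OFF
# class, matching the documented RNG order.
reference_sim <- function(x_on, x_off, w_on_e, w_off_e, m_on, m_off, p,
                          use_inhib = TRUE, plastic_inhib = TRUE,
                          rule = "hebbian") {
  n_steps <- nrow(x_on)
  N <- ncol(x_on)
  scaling_mean <- 0
  scaling_n <- 0
  for (t in seq_len(n_steps)) {
    u <- 0
    for (i in seq_len(N)) {
      u <- u + w_on_e[i] * x_on[t, i] + w_off_e[i] * x_off[t, i]
      if (use_inhib)
        u <- u - m_on[i] * x_on[t, i] - m_off[i] * x_off[t, i]
    }
    y <- if (u > p$theta) u - p$theta else 0

    if (rule == "hebbian") {
      eta_on <- stats::runif(N, -p$eta_bound, p$eta_bound)
      for (i in seq_len(N))
        w_on_e[i] <- w_on_e[i] + p$alpha_e * x_on[t, i] * y +
          eta_on[i] * w_on_e[i]
      eta_off <- stats::runif(N, -p$eta_bound, p$eta_bound)
      for (i in seq_len(N))
        w_off_e[i] <- w_off_e[i] + p$alpha_e * x_off[t, i] * y +
          eta_off[i] * w_off_e[i]
    } else {
      fac <- if (y > scaling_mean) 1 - p$scaling_factor
             else if (y < scaling_mean) 1 + p$scaling_factor else 1
      w_on_e <- w_on_e * fac
      w_off_e <- w_off_e * fac
      scaling_n <- scaling_n + 1
      scaling_mean <- scaling_mean + (y - scaling_mean) / scaling_n
    }

    if (use_inhib && plastic_inhib) {
      for (i in seq_len(N)) {
        m_on[i] <- max(m_on[i] + p$alpha_i * x_on[t, i] * (y - p$rho), 0)
        m_off[i] <- max(m_off[i] + p$alpha_i * x_off[t, i] * (y - p$rho), 0)
      }
    }

    if (rule == "hebbian") {
      clipnorm <- function(w) {
        w <- pmin(pmax(w, p$w_min), p$w_max)
        w * p$excit_l1 / sum(w)
      }
      w_on_e <- clipnorm(w_on_e)
      w_off_e <- clipnorm(w_off_e)
    }
    if (use_inhib && plastic_inhib) {
      capnorm <- function(m) {
        s <- sum(m)
        if (s > 0 && (p$inhib_norm == "exact" || s > p$inhib_l1))
          m <- m * p$inhib_l1 / s
        m
      }
      m_on <- capnorm(m_on)
      m_off <- capnorm(m_off)
    }
  }
  list(w_on_e = w_on_e, w_off_e = w_off_e, m_on = m_on, m_off = m_off)
}

# Brute-force two-sample KS statistic: maximal ECDF gap over the pooled
# sample points.
reference_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(q) mean(a <= q) - mean(b <= q), numeric(1))))
}

# Pearson correlation from first principles.
reference_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small deterministic parameter set for fast unit tests.
tiny_params <- function(...) {
  model_params(n_steps_pre = 2000L, n_steps_sound = 2000L,
               t_young = 500L, t_adult = 2000L, ...)
}
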