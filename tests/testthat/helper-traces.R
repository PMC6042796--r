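# Shared builders for synthetic traces used across tests.

# A pure step in elastic stress: displacement jumps to `d_um` at the second
# sample and holds. Useful for step-response checks of the QLV filter.
step_stimulus <- function(d_um, total_s = 8, dt_s = 1e-3) {
  time <- seq(0, total_s, by = dt_s)
  tibble::tibble(time = time, displacement = c(0, rep(d_um, length(time) - 1)))
}

# A stress trace that steps from 0 to `S` Pa at the second sample.
step_stress <- function(S, total_s = 2, dt_s = 1e-4) {
  time <- seq(0, total_s, by = dt_s)
  tibble::tibble(time = time, stress = c(0, rep(S, length(time) - 1)))
}

# Constant-current drive for LIF tests: per-complex current such that a
# cluster of size 1 receives `pA`.
constant_current <- function(pA, total_s = 3, dt_s = 1e-4) {
  time <- seq(0, total_s, by = dt_s)
  tibble::tibble(time = time, i_total = c(0, rep(pA, length(time) - 1)))
}

# Brute-force discrete convolution of the generator kernels with stress
# increments (direct double loop over the step construction); the
# independent oracle for generator_current().
brute_force_current <- function(stress, params) {
  dsig <- c(0, diff(stress$stress))
  t <- stress$time
  n <- length(t)
  itot <- numeric(n)
  for (k in seq_len(n)) {
    lags <- t[k] - t[seq_len(k)]
    itot[k] <- sum((kernel_RI(lags, params) + kernel_SI(lags, params) +
                      kernel_USI(lags, params)) * dsig[seq_len(k)])
  }
  pmax(itot, 0)
}

# Midpoint-rule quadrature of the QLV hereditary integral; the independent
# oracle for qlv_stress().
quadrature_qlv <- function(stimulus, params) {
  sig_e <- elastic_stress(stimulus$displacement, params)
  t <- stimulus$time
  n <- length(t)
  dsig <- diff(sig_e)
  tmid <- (t[-1] + t[-n]) / 2
  out <- numeric(n)
  for (k in 2:n) {
    lag <- t[k] - tmid[seq_len(k - 1)]
    G <- params$Ginf + params$G1 * exp(-lag / params$tau1_s) +
      params$G2 * exp(-lag / params$tau2_s)
    out[k] <- sum(G * dsig[seq_len(k - 1)])
  }
  pmax(out, 0)
}
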