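#' Fit an exponential decay to an electrophysiology-style trace
#'
#' Fits the decaying segment of a trace (from its maximum onward) with
#' nonlinear least squares, using either the pure exponential form
#' \eqn{y = A e^{-x/\tau}} (`"a_exp"`, the form used for voltage-clamp
#' current decays) or the exponential-plus-offset form
#' \eqn{y = A e^{-x/\tau} + b} (`"a_exp_plus_b"`, used for current-clamp
#' membrane-potential decays that settle on a steady plateau). Time is
#' re-zeroed at the trace maximum before fitting.
#'
#' @param trace A tibble with columns `time` (s) and `value` (pA or mV).
#' @param form `"a_exp"` or `"a_exp_plus_b"`.
#' @return An object of class `"exp_fit"`: a list with elements `tau_s`,
#'   `amplitude`, `offset` (0 for the pure form), `r_squared`, `form`,
#'   `converged`, `n`, and the fitted segment in `$segment`.
#' @seealso [tidy.exp_fit()], [glance.exp_fit()]
#' @export
fit_exponential <- function(trace, form = c("a_exp", "a_exp_plus_b")) {
  form <- match.arg(form)
  if (nrow(trace) < 5) stop("Need at least 5 samples to fit.", call. = FALSE)
  i0 <- which.max(trace$value)
  seg <- trace[i0:nrow(trace), , drop = FALSE]
  if (nrow(seg) < 5) stop("Decaying segment is too short to fit.", call. = FALSE)
  x <- seg$time - seg$time[1]
  y <- seg$value

  off0 <- if (form == "a_exp_plus_b") {
    mean(utils::tail(y, max(3, ceiling(length(y) * 0.05))))
  } else {
    0
  }
  amp0 <- max(y) - off0
  # crude tau guess: first crossing of amp0/e above the offset
  below <- which((y - off0) <= amp0 / exp(1))
  tau0 <- if (length(below)) max(x[below[1]], diff(range(x)) / 100) else diff(range(x)) / 3

  fit <- if (form == "a_exp") {
    try(minpack.lm::nlsLM(
      y ~ A * exp(-x / tau),
      start = list(A = amp0, tau = tau0),
      lower = c(A = -Inf, tau = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      y ~ A * exp(-x / tau) + b,
      start = list(A = amp0, tau = tau0, b = off0),
      lower = c(A = -Inf, tau = .Machine$double.eps, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
  }

  if (inherits(fit, "try-error")) {
    out <- list(
      tau_s = NA_real_, amplitude = NA_real_, offset = NA_real_,
      r_squared = NA_real_, form = form, converged = FALSE,
      n = length(y), segment = seg,
      diagnostics = as.character(fit)
    )
    return(structure(out, class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  out <- list(
    tau_s = unname(cf["tau"]),
    amplitude = unname(cf["A"]),
    offset = if (form == "a_exp_plus_b") unname(cf["b"]) else 0,
    r_squared = r2,
    form = form,
    converged = TRUE,
    n = length(y),
    segment = seg,
    diagnostics = NULL
  )
  if (!is.finite(out$tau_s) || out$tau_s <= 0) {
    out$converged <- FALSE
    out$diagnostics <- "fitted time constant is not positive"
  }
  structure(out, class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit>", x$form, if (!x$converged) "(not converged)", "\n")
  cat(sprintf("  tau = %.6g s, amplitude = %.6g, offset = %.6g, R^2 = %.4f, n = %d\n",
              x$tau_s, x$amplitude, x$offset, x$r_squared, x$n))
  invisible(x)
}

#' Peak / steady-state ratio of a decaying trace
#'
#' Splits a step-response trace into the fraction of the response that decays
#' and the fraction that persists: `K_steady` is the mean of the final 10%
#' of the trace divided by the trace maximum, and `K_peak = 1 - K_steady`.
#'
#' @param trace A tibble with columns `time` and `value`.
#' @param steady_frac Fraction of the trace tail averaged as "steady state".
#' @return A tibble with columns `K_peak` and `K_steady`.
#' @export
peak_steady_ratio <- function(trace, steady_frac = 0.1) {
  n <- nrow(trace)
  if (n < 2) stop("Trace too short.", call. = FALSE)
  peak <- max(trace$value)
  if (peak <= 0) stop("Trace must have a positive peak.", call. = FALSE)
  tail_n <- max(1, ceiling(n * steady_frac))
  steady <- mean(utils::tail(trace$value, tail_n)) / peak
  tibble::tibble(K_peak = 1 - steady, K_steady = steady)
}

#' Summarise a set of fitted time constants
#'
#' Arithmetic mean and sample standard deviation over a collection of fitted
#' values (e.g. one of the packaged reference tables).
#'
#' @param values A numeric vector, a data frame with a `value` column, or a
#'   list of `exp_fit` objects (their `tau_s` is used).
#' @return A tibble with columns `n`, `mean`, `sd`.
#' @export
summarize_table_fits <- function(values) {
  v <- if (is.data.frame(values)) {
    values$value
  } else if (is.list(values) && all(vapply(values, inherits, logical(1), "exp_fit"))) {
    vapply(values, function(f) f$tau_s, numeric(1))
  } else {
    values
  }
  v <- as.numeric(v)
  v <- v[!is.na(v)]
  if (length(v) < 2) {
    stop("Need at least two values for a mean and standard deviation.", call. = FALSE)
  }
  tibble::tibble(n = length(v), mean = mean(v), sd = stats::sd(v))
}

#' Fit the free current-scaling parameters in the whole-end-organ model
#'
#' Estimates the three linear stress-to-current coefficients (a, b, c) of the
#' generator function by matching simulated firing to reference spike trains
#' at two stimulus magnitudes, following the model's fitting convention:
#' reference spikes are converted to instantaneous firing frequency, smoothed
#' with a 5-sample moving average, and logarithmically resampled to 50 points
#' (weighting the early hold); the model's smoothed IFF is interpolated at
#' those time points and the Levenberg-Marquardt algorithm minimises the
#' residuals (equivalently, maximises the coefficient of determination R^2).
#' The two per-magnitude fits are averaged for the final estimate. All
#' biologically derived parameters (time constants, K ratios) stay fixed at
#' the values in `config`.
#'
#' @param ref_spikes A named list of two spike-train tibbles (or numeric
#'   spike-time vectors), `low` and `high`.
#' @param config A [sim_config()] describing stimulus, skin, generator
#'   preset, and end organ. The per-magnitude stimuli are the config's
#'   low/high defaults.
#' @param init Initial `c(a, b, c)` in pA/Pa. The default spreads a target
#'   peak per-complex current of 15 pA (mid-range of the 10-20 pA expected
#'   for a 17-complex end organ) evenly over the active components.
#' @param n_points Number of log-sampled comparison points per magnitude.
#' @param window IFF smoothing window.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return An object of class `"free_param_fit"`: estimates per magnitude,
#'   their average (`a`, `b`, `c`), and per-magnitude R^2.
#' @seealso [tidy.free_param_fit()], [glance.free_param_fit()]
#' @export
fit_free_parameters <- function(ref_spikes,
                                config = sim_config(),
                                init = NULL,
                                n_points = 50,
                                window = 5,
                                max_iter = 40) {
  stopifnot(all(c("low", "high") %in% names(ref_spikes)))
  gen <- config$generator
  active <- c(TRUE, gen$b > 0, gen$c > 0)   # RI always present

  fits <- purrr::map(c(low = "low", high = "high"), function(mag) {
    stim <- default_stimulus(
      magnitude = mag,
      reference_um = config$stimulus$reference_um,
      low_fraction = config$stimulus$low_fraction,
      ramp_s = config$stimulus$ramp_s,
      total_s = config$stimulus$total_s,
      dt_s = config$stimulus$dt_s
    )
    stress <- qlv_stress(stim, config$skin)
    basis <- generator_basis(stress, gen)

    ref_t <- if (is.numeric(ref_spikes[[mag]])) ref_spikes[[mag]] else ref_spikes[[mag]]$time
    if (length(ref_t) < 3) {
      stop("Reference spike train `", mag, "` has too few spikes to fit.", call. = FALSE)
    }
    ref_iff <- log_sample(smooth_iff(compute_iff(ref_t), window = window), n = n_points)
    penalty <- 2 * max(ref_iff$iff)

    if (is.null(init)) {
      peak_target <- 15 / max(basis$time_profile)   # 15 pA per-complex peak
      init0 <- rep(0, 3)
      init0[active] <- peak_target / sum(active)
    } else {
      init0 <- init
    }

    residual_fun <- function(par) {
      par <- pmax(par, 0)
      itot <- pmax(par[1] * basis$X_RI + par[2] * basis$X_SI + par[3] * basis$X_USI, 0)
      spk <- lif_spike_times(
        basis$time,
        outer(itot, as.numeric(config$end_organ$cluster_sizes)),
        config$end_organ, basis$dt
      )
      if (nrow(spk) < 3) return(ref_iff$iff + penalty)
      model_sm <- smooth_iff(compute_iff(spk$time), window = window)
      ref_iff$iff - iff_at(model_sm, ref_iff$time)
    }

    lm_fit <- minpack.lm::nls.lm(
      par = init0,
      lower = rep(0, 3),
      fn = residual_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, epsfcn = 1e-4
      )
    )
    par <- pmax(lm_fit$par, 0)
    par[!active] <- 0
    res <- residual_fun(par)
    r2 <- 1 - sum(res^2) / sum((ref_iff$iff - mean(ref_iff$iff))^2)
    list(par = par, r_squared = r2, info = lm_fit$info, niter = lm_fit$niter)
  })

  avg <- (fits$low$par + fits$high$par) / 2
  structure(
    list(
      a = avg[1], b = avg[2], c = avg[3],
      per_magnitude = tibble::tibble(
        magnitude = c("low", "high"),
        a = c(fits$low$par[1], fits$high$par[1]),
        b = c(fits$low$par[2], fits$high$par[2]),
        c = c(fits$low$par[3], fits$high$par[3]),
        r_squared = c(fits$low$r_squared, fits$high$r_squared)
      ),
      r_squared = mean(c(fits$low$r_squared, fits$high$r_squared)),
      config = config
    ),
    class = "free_param_fit"
  )
}

# Unit-coefficient component currents for a fixed stress trace: the generator
# current is linear in (a, b, c) before clamping, so fitting only needs these
# three basis traces.
generator_basis <- function(stress, gen) {
  dt <- trace_dt(stress$time)
  X_RI <- exp_track(c(0, diff(stress$stress)), dt, gen$tau_RI_ms / 1000)
  X_SI <- if (gen$b > 0) {
    gen$K_SI_peak * exp_track(c(0, diff(stress$stress)), dt, gen$tau_SI_ms / 1000) +
      gen$K_SI_steady * stress$stress
  } else {
    numeric(nrow(stress))
  }
  X_USI <- if (gen$c > 0) {
    exp_track(c(0, diff(stress$stress)), dt, gen$tau_USI_ms / 1000)
  } else {
    numeric(nrow(stress))
  }
  list(
    time = stress$time, dt = dt,
    X_RI = X_RI, X_SI = X_SI, X_USI = X_USI,
    time_profile = pmax(X_RI + X_SI + X_USI, .Machine$double.eps)
  )
}

#' @export
print.free_param_fit <- function(x, ...) {
  cat("<free_param_fit>\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g pA/Pa (mean of low/high fits)\n",
              x$a, x$b, x$c))
  cat(sprintf("  R^2: low = %.4f, high = %.4f\n",
              x$per_magnitude$r_squared[1], x$per_magnitude$r_squared[2]))
  invisible(x)
}
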