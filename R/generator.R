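#' Generator-function parameters
#'
#' The eight parameters of the three-component generator function plus the
#' genotype switch. The four presets are the fitted parameter sets for the
#' base wildtype model (with the ultra-slowly inactivating, USI, component),
#' the two alternate wildtype variants used to probe the need for the USI
#' current, and the Atoh1 conditional-knockout model in which the Merkel-cell
#' (slowly inactivating, SI) component is absent:
#'
#' | preset | tau_RI | tau_SI | tau_USI | K_peak | K_steady | a | b | c |
#' |---|---|---|---|---|---|---|---|---|
#' | `wildtype_with_USI`     | 8.0 | 200.0 | 1744.6 | 0.87 | 0.13 | 0.74 | 0.24 | 0.07 |
#' | `wildtype_no_USI_long_SI` | 8.3 | 569.8 | — | 0.82 | 0.18 | 0.99 | 0.26 | — |
#' | `wildtype_no_USI`       | 8.0 | 200.0 | — | 0.81 | 0.19 | 0.74 | 0.36 | — |
#' | `atoh1_cko`             | 8.0 | — | 1744.6 | — | — | 0.74 | — | 0.07 |
#'
#' Time constants are in milliseconds; `a`, `b`, `c` are the linear
#' stress-to-current coefficients in pA/Pa for the RI, SI, and USI components.
#' `K_SI_peak + K_SI_steady = 1` whenever the SI component is active.
#'
#' @param preset Preset name (see table above).
#' @param ... Named overrides (`tau_RI_ms`, `tau_SI_ms`, `tau_USI_ms`,
#'   `K_SI_peak`, `K_SI_steady`, `a`, `b`, `c`). Overriding `K_SI_peak`
#'   without `K_SI_steady` co-updates the latter to `1 - K_SI_peak`.
#' @return An object of class `"generator_params"`.
#' @export
generator_params <- function(preset = c("wildtype_with_USI",
                                        "wildtype_no_USI_long_SI",
                                        "wildtype_no_USI",
                                        "atoh1_cko"),
                             ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    wildtype_with_USI = list(
      tau_RI_ms = 8.0, tau_SI_ms = 200.0, tau_USI_ms = 1744.6,
      K_SI_peak = 0.87, K_SI_steady = 0.13, a = 0.74, b = 0.24, c = 0.07
    ),
    wildtype_no_USI_long_SI = list(
      tau_RI_ms = 8.3, tau_SI_ms = 569.8, tau_USI_ms = NA_real_,
      K_SI_peak = 0.82, K_SI_steady = 0.18, a = 0.99, b = 0.26, c = 0
    ),
    wildtype_no_USI = list(
      tau_RI_ms = 8.0, tau_SI_ms = 200.0, tau_USI_ms = NA_real_,
      K_SI_peak = 0.81, K_SI_steady = 0.19, a = 0.74, b = 0.36, c = 0
    ),
    atoh1_cko = list(
      tau_RI_ms = 8.0, tau_SI_ms = NA_real_, tau_USI_ms = 1744.6,
      K_SI_peak = NA_real_, K_SI_steady = NA_real_, a = 0.74, b = 0, c = 0.07
    )
  )
  p$genotype <- preset
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("Unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if ("K_SI_peak" %in% names(dots) && !("K_SI_steady" %in% names(dots))) {
    dots$K_SI_steady <- 1 - dots$K_SI_peak
  }
  p[names(dots)] <- dots
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  si_active <- p$b > 0
  usi_active <- p$c > 0
  stopifnot(p$a >= 0, p$b >= 0, p$c >= 0, p$tau_RI_ms > 0)
  if (p$genotype == "atoh1_cko" && p$b != 0) {
    stop("The Atoh1-CKO genotype has no Merkel cells: `b` must be 0.", call. = FALSE)
  }
  if (si_active) {
    stopifnot(is.finite(p$tau_SI_ms), p$tau_SI_ms > 0)
    if (abs(p$K_SI_peak + p$K_SI_steady - 1) > 1e-9) {
      stop("K_SI_peak + K_SI_steady must equal 1 when the SI component is active.",
           call. = FALSE)
    }
  }
  if (usi_active) stopifnot(is.finite(p$tau_USI_ms), p$tau_USI_ms > 0)
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params> genotype:", x$genotype, "\n")
  cat(sprintf("  RI : tau = %g ms, a = %g pA/Pa\n", x$tau_RI_ms, x$a))
  if (x$b > 0) {
    cat(sprintf("  SI : tau = %g ms, b = %g pA/Pa, K_peak = %g, K_steady = %g\n",
                x$tau_SI_ms, x$b, x$K_SI_peak, x$K_SI_steady))
  } else {
    cat("  SI : absent\n")
  }
  if (x$c > 0) {
    cat(sprintf("  USI: tau = %g ms, c = %g pA/Pa\n", x$tau_USI_ms, x$c))
  } else {
    cat("  USI: absent\n")
  }
  invisible(x)
}

#' Generator-function kernels
#'
#' The three convolution kernels that map a unit step increase in compressive
#' stress at lag zero to current at lag `t_since_s`:
#' \deqn{k_{RI}(t) = a\, e^{-t/\tau_{RI}}}
#' \deqn{k_{SI}(t) = b\,(K_{peak}\, e^{-t/\tau_{SI}} + K_{steady})}
#' \deqn{k_{USI}(t) = c\, e^{-t/\tau_{USI}}}
#' The SI kernel does not decay to zero: its floor is `b * K_SI_steady`,
#' which is what sustains current through a long hold. Kernels of inactive
#' components (`b = 0` or `c = 0`) are identically zero.
#'
#' @param t_since_s Lag(s) since the stress step, in seconds (>= 0).
#' @param params A [generator_params()] object.
#' @return Kernel weight(s) in pA/Pa.
#' @export
kernel_RI <- function(t_since_s, params) {
  check_lag(t_since_s)
  params$a * exp(-t_since_s / (params$tau_RI_ms / 1000))
}

#' @rdname kernel_RI
#' @export
kernel_SI <- function(t_since_s, params) {
  check_lag(t_since_s)
  if (params$b == 0) return(rep(0, length(t_since_s)))
  params$b * (params$K_SI_peak * exp(-t_since_s / (params$tau_SI_ms / 1000)) +
                params$K_SI_steady)
}

#' @rdname kernel_RI
#' @export
kernel_USI <- function(t_since_s, params) {
  check_lag(t_since_s)
  if (params$c == 0) return(rep(0, length(t_since_s)))
  params$c * exp(-t_since_s / (params$tau_USI_ms / 1000))
}

check_lag <- function(t) {
  if (any(t < 0)) stop("Kernel lag must be non-negative.", call. = FALSE)
  invisible(t)
}

#' Generator current of one Merkel cell-neurite complex
#'
#' The core transformation of the model: the per-complex receptor current is
#' the convolution of the stress derivative with the sum of the three kernels,
#' \deqn{I(t) = \int_0^t \left[k_{RI} + k_{SI} + k_{USI}\right](t - x)\,
#'   \frac{d\sigma}{dx}\, dx,}
#' so that each increment of stress injects current proportional to its size
#' which then decays with the component time constants, while the
#' non-decaying SI floor integrates to `b * K_SI_steady * sigma(t)`. The
#' total current is clamped at zero (zero is the baseline; component traces
#' are not clamped individually). The integral is evaluated with per-step
#' recursive exponential updates, exact for the discretised step-increment
#' construction of the stress trace.
#'
#' @param stress A stress tibble (`time`, `stress`) on a uniform grid with
#'   `stress[1] == 0`.
#' @param params A [generator_params()] object.
#' @return A tibble with columns `time` (s), `i_RI`, `i_SI`, `i_USI` and
#'   `i_total` (pA). Generator parameters are attached as the
#'   `"generator_params"` attribute.
#' @export
generator_current <- function(stress, params) {
  dt <- trace_dt(stress$time)
  if (any(!is.finite(stress$stress))) {
    stop("Stress trace contains non-finite values.", call. = FALSE)
  }
  if (abs(stress$stress[1]) > 1e-12) {
    stop("Stress trace must start at zero.", call. = FALSE)
  }
  dsig <- c(0, diff(stress$stress))
  i_RI <- params$a * exp_track(dsig, dt, params$tau_RI_ms / 1000)
  if (params$b > 0) {
    i_SI <- params$b * params$K_SI_peak *
      exp_track(dsig, dt, params$tau_SI_ms / 1000) +
      params$b * params$K_SI_steady * stress$stress
  } else {
    i_SI <- numeric(length(dsig))
  }
  if (params$c > 0) {
    i_USI <- params$c * exp_track(dsig, dt, params$tau_USI_ms / 1000)
  } else {
    i_USI <- numeric(length(dsig))
  }
  out <- tibble::tibble(
    time = stress$time,
    i_RI = i_RI,
    i_SI = i_SI,
    i_USI = i_USI,
    i_total = pmax(i_RI + i_SI + i_USI, 0)
  )
  attr(out, "generator_params") <- params
  attr(out, "stim_params") <- attr(stress, "stim_params")
  out
}

# Exponentially decaying memory of stress increments:
#   y_k = y_{k-1} exp(-dt/tau) + dsig_k
# i.e. the discrete convolution sum_j exp(-(t_k - t_j)/tau) dsig_j.
exp_track <- function(dsig, dt, tau) {
  as.numeric(stats::filter(dsig, exp(-dt / tau), method = "recursive"))
}

#' Sweep one generator parameter
#'
#' Recomputes the per-complex generator current for each value of a single
#' parameter, all other parameters held at `base_params`. Sweeping
#' `K_SI_peak` co-updates `K_SI_steady = 1 - K_SI_peak` so the two ratios
#' keep summing to one. The conventional sweep ranges are mean +/- one
#' standard deviation of the fitted decay constants: tau_RI over 1/8/15 ms
#' and tau_SI over 50/200/350 ms.
#'
#' @param stress A stress tibble.
#' @param base_params A [generator_params()] object.
#' @param name `"tau_RI"`, `"tau_SI"` or `"K_SI_peak"`.
#' @param values Numeric vector of parameter values (ms for time constants).
#' @return A tibble with one row per swept value: columns `param`, `value`,
#'   and a list-column `current` of generator-current tibbles.
#' @export
sweep_parameter <- function(stress, base_params,
                            name = c("tau_RI", "tau_SI", "K_SI_peak"),
                            values) {
  name <- match.arg(name)
  field <- switch(name,
    tau_RI = "tau_RI_ms",
    tau_SI = "tau_SI_ms",
    K_SI_peak = "K_SI_peak"
  )
  runs <- purrr::map(values, function(v) {
    p <- unclass(base_params)
    p[[field]] <- v
    if (name == "K_SI_peak") p$K_SI_steady <- 1 - v
    p <- structure(validate_generator_params(p), class = "generator_params")
    generator_current(stress, p)
  })
  tibble::tibble(param = name, value = values, current = runs)
}

#' Write component currents to CSV
#'
#' @param current A generator-current tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_current_csv <- function(current, path) {
  readr::write_csv(
    tibble::tibble(
      time_s = current$time,
      I_RI_pA = current$i_RI,
      I_SI_pA = current$i_SI,
      I_USI_pA = current$i_USI,
      I_total_pA = current$i_total
    ),
    path
  )
  invisible(path)
}
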