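#' Tidy an exponential-decay fit
#'
#' @param x An `exp_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.exp_fit <- function(x, ...) {
  terms <- c("tau_s", "amplitude")
  est <- c(x$tau_s, x$amplitude)
  if (x$form == "a_exp_plus_b") {
    terms <- c(terms, "offset")
    est <- c(est, x$offset)
  }
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidy.exp_fit
#' @return `glance()` returns a one-row tibble with `r_squared`, `tau_s`,
#'   `form`, `n`, `converged`.
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, tau_s = x$tau_s, form = x$form,
    n = x$n, converged = x$converged
  )
}

#' Tidy a free-parameter (end-organ) fit
#'
#' @param x A `free_param_fit` object.
#' @param ... Unused.
#' @return One row per coefficient with the per-magnitude and averaged
#'   estimates.
#' @export
tidy.free_param_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(x$a, x$b, x$c),
    low = c(x$per_magnitude$a[1], x$per_magnitude$b[1], x$per_magnitude$c[1]),
    high = c(x$per_magnitude$a[2], x$per_magnitude$b[2], x$per_magnitude$c[2])
  )
}

#' @rdname tidy.free_param_fit
#' @export
glance.free_param_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    r_squared_low = x$per_magnitude$r_squared[1],
    r_squared_high = x$per_magnitude$r_squared[2]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
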