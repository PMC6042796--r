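#' Ramp-and-hold displacement stimulus
#'
#' Builds the displacement-clamped stimulus that drives the skin model: a
#' linearly decelerating ramp from zero to the target indentation followed by
#' a static hold. The ramp has constant (negative) acceleration, so the
#' displacement profile is quadratic,
#' \deqn{d(t) = D\,(2t/T_r - (t/T_r)^2), \quad 0 \le t \le T_r,}
#' and \eqn{d(t) = D} during the hold. Initial velocity is \eqn{2D/T_r},
#' falling linearly to zero at the end of the ramp.
#'
#' @param displacement_um Final indentation depth D in micrometres (> 0).
#' @param ramp_s Ramp duration \eqn{T_r} in seconds.
#' @param total_s Total stimulus duration in seconds (must exceed `ramp_s`).
#' @param dt_s Sampling interval in seconds (default 0.1 ms).
#'
#' @return A tibble with columns `time` (s) and `displacement` (um), sampled
#'   on the uniform grid `seq(0, total_s, by = dt_s)`. Stimulus parameters are
#'   attached as the `"stim_params"` attribute.
#'
#' @examples
#' stim <- ramp_and_hold(displacement_um = 100, ramp_s = 0.3, total_s = 1)
#' stim[stim$time == 0.1, ] # mid-ramp: 75 um
#' @export
ramp_and_hold <- function(displacement_um,
                          ramp_s = 0.3,
                          total_s = 5,
                          dt_s = 1e-4) {
  if (!is.numeric(displacement_um) || length(displacement_um) != 1 ||
      !is.finite(displacement_um) || displacement_um < 0) {
    stop("`displacement_um` must be a single non-negative number.", call. = FALSE)
  }
  if (ramp_s <= 0 || total_s <= 0 || dt_s <= 0) {
    stop("Durations and time step must be positive.", call. = FALSE)
  }
  if (ramp_s >= total_s) {
    stop("`ramp_s` must be smaller than `total_s`.", call. = FALSE)
  }
  time <- seq(0, total_s, by = dt_s)
  u <- pmin(time / ramp_s, 1)
  displacement <- displacement_um * (2 * u - u^2)
  out <- tibble::tibble(time = time, displacement = displacement)
  attr(out, "stim_params") <- list(
    displacement_um = displacement_um,
    ramp_s = ramp_s,
    total_s = total_s,
    dt_s = dt_s
  )
  out
}

#' Default low/high magnitude stimuli
#'
#' The two stimulus magnitudes used throughout the package: `"high"` is the
#' reference indentation and `"low"` is half of it. The reference depth is a
#' configuration choice (recordings this model emulates used indentations of
#' order one quarter of the skin thickness); see the methods vignette.
#'
#' @param magnitude `"low"` or `"high"`.
#' @param reference_um Reference (high-magnitude) indentation depth in um.
#' @param low_fraction Fraction of `reference_um` used for the low magnitude.
#' @inheritParams ramp_and_hold
#' @return A stimulus tibble as returned by [ramp_and_hold()].
#' @export
default_stimulus <- function(magnitude = c("high", "low"),
                             reference_um = 60,
                             low_fraction = 0.5,
                             ramp_s = 0.3,
                             total_s = 5,
                             dt_s = 1e-4) {
  magnitude <- match.arg(magnitude)
  depth <- if (magnitude == "high") reference_um else low_fraction * reference_um
  out <- ramp_and_hold(depth, ramp_s = ramp_s, total_s = total_s, dt_s = dt_s)
  attr(out, "stim_params")$magnitude <- magnitude
  out
}

#' Read / write stimulus traces
#'
#' Two-column CSV interchange (`time_s`, `displacement_um`).
#'
#' @param stimulus A stimulus tibble.
#' @param path File path.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns a stimulus tibble.
#' @export
write_stimulus_csv <- function(stimulus, path) {
  readr::write_csv(
    tibble::tibble(time_s = stimulus$time, displacement_um = stimulus$displacement),
    path
  )
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "displacement_um") %in% names(raw))) {
    stop("Stimulus CSV needs columns `time_s` and `displacement_um`.", call. = FALSE)
  }
  tibble::tibble(time = raw$time_s, displacement = raw$displacement_um)
}

# shared helper: check that a trace sits on a uniform grid and return dt
trace_dt <- function(time, tol = 1e-9) {
  if (length(time) < 2) stop("Trace needs at least two samples.", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > tol * max(1, abs(dt[1])))) {
    stop("Trace must be sampled on a uniform time grid.", call. = FALSE)
  }
  dt[1]
}
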