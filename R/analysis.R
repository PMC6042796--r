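#' Instantaneous firing frequency
#'
#' Converts a spike train into instantaneous firing frequencies: the
#' reciprocal of each inter-spike interval, timestamped at the latter spike
#' of the pair.
#'
#' @param spikes A spike-train tibble (`time` sorted ascending), or a numeric
#'   vector of spike times in seconds.
#' @return A tibble with columns `time` (s) and `iff` (Hz); `n_spikes - 1`
#'   rows. With fewer than two spikes an empty tibble is returned with a
#'   warning.
#' @export
compute_iff <- function(spikes) {
  t <- if (is.numeric(spikes)) spikes else spikes$time
  if (length(t) < 2) {
    warning("Fewer than two spikes: IFF trace is empty.", call. = FALSE)
    return(tibble::tibble(time = numeric(0), iff = numeric(0)))
  }
  isi <- diff(t)
  if (any(isi <= 0)) stop("Spike times must be strictly increasing.", call. = FALSE)
  tibble::tibble(time = t[-1], iff = 1 / isi)
}

#' Moving-average smoothing of an IFF trace
#'
#' Centred moving average over `window` samples (the conventional window is
#' five). At the edges the window shrinks symmetrically so the trace keeps
#' its length and endpoints are averaged over the samples available.
#'
#' @param iff An IFF tibble (`time`, `iff`).
#' @param window Odd window width in samples; `window = 1` is the identity.
#' @return An IFF tibble of the same length with smoothed `iff`.
#' @export
smooth_iff <- function(iff, window = 5) {
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer.", call. = FALSE)
  }
  n <- nrow(iff)
  if (n == 0 || window == 1) return(iff)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, iff$iff))
  idx <- seq_len(n)
  h <- pmin(half, idx - 1, n - idx)    # symmetric shrink at edges
  lo <- idx - h
  hi <- idx + h
  tibble::tibble(time = iff$time, iff = (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Logarithmic resampling of an IFF trace
#'
#' Picks `n` samples at time points spaced logarithmically between the first
#' and last IFF timestamps, weighting the early hold more heavily than the
#' late hold. Values are taken from the nearest existing sample
#' (nearest-neighbour selection, not interpolation), so every sampled value
#' occurs in the input trace.
#'
#' @param iff An IFF tibble with at least 2 rows.
#' @param n Number of samples (default 50).
#' @return An IFF tibble with `n` rows; `time` holds the (nearest-neighbour)
#'   timestamps actually selected.
#' @export
log_sample <- function(iff, n = 50) {
  if (nrow(iff) < 2) stop("Need at least two IFF samples to resample.", call. = FALSE)
  if (any(iff$time <= 0)) {
    stop("Logarithmic sampling requires strictly positive timestamps.", call. = FALSE)
  }
  targets <- exp(seq(log(iff$time[1]), log(iff$time[nrow(iff)]), length.out = n))
  picks <- vapply(targets, function(tt) which.min(abs(iff$time - tt)), integer(1))
  tibble::tibble(time = iff$time[picks], iff = iff$iff[picks])
}

#' Stimulus phase windows
#'
#' The three analysis windows used to summarise firing: the ramp
#' `[0, ramp_s]`, the early hold (first 0.5 s after the ramp), and the late
#' hold (2 s to 5 s of the stimulus).
#'
#' @param ramp_s End of the ramp (s).
#' @param early_hold_s Duration of the early-hold window after the ramp (s).
#' @param late_hold Two-element numeric, start and end of the late-hold
#'   window (s).
#' @return A named list of `c(start, end)` windows.
#' @export
phase_windows <- function(ramp_s = 0.3, early_hold_s = 0.5,
                          late_hold = c(2, 5)) {
  list(
    ramp = c(0, ramp_s),
    early_hold = c(ramp_s, ramp_s + early_hold_s),
    late_hold = late_hold
  )
}

#' Phase-resolved firing rates
#'
#' Mean instantaneous firing frequency within each phase window. A window
#' containing spikes but fewer than two IFF samples falls back to spike count
#' divided by window length; a window with no spikes reports 0 Hz.
#'
#' @param spikes A spike-train tibble or numeric vector of spike times.
#' @param windows A list of windows from [phase_windows()].
#' @return A tibble with columns `phase`, `rate_hz`, `n_spikes`.
#' @export
phase_rates <- function(spikes, windows = phase_windows()) {
  t <- if (is.numeric(spikes)) spikes else spikes$time
  iff <- if (length(t) >= 2) compute_iff(t) else tibble::tibble(time = numeric(0), iff = numeric(0))
  purrr::map_dfr(names(windows), function(nm) {
    w <- windows[[nm]]
    in_w_spikes <- sum(t >= w[1] & t <= w[2])
    vals <- iff$iff[iff$time >= w[1] & iff$time <= w[2]]
    rate <- if (length(vals) >= 1) {
      mean(vals)
    } else if (in_w_spikes >= 1) {
      in_w_spikes / (w[2] - w[1])
    } else {
      0
    }
    tibble::tibble(phase = nm, rate_hz = rate, n_spikes = in_w_spikes)
  })
}

#' Evaluate a (smoothed) IFF trace at arbitrary times
#'
#' Linear interpolation within the span of the trace; 0 Hz outside it (the
#' afferent is silent before the second spike and after the last one).
#'
#' @param iff An IFF tibble.
#' @param at Times (s) at which to evaluate.
#' @return Numeric vector of rates (Hz).
#' @export
iff_at <- function(iff, at) {
  if (nrow(iff) == 0) return(rep(0, length(at)))
  if (nrow(iff) == 1) {
    return(ifelse(abs(at - iff$time[1]) < .Machine$double.eps^0.5, iff$iff[1], 0))
  }
  out <- stats::approx(iff$time, iff$iff, xout = at, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Hold-phase adaptation (IFF decline fraction)
#'
#' Fractional decline of the smoothed IFF between two hold-phase time points,
#' `1 - r(t_late) / r(t_early)`; a slowly adapting response keeps declining
#' (large fraction), a plateaued response does not (fraction near zero).
#' Because firing can be sparse late in the hold, each rate is the mean
#' smoothed IFF over a half-width `half_window_s` window around its time
#' point (the late window is clipped at `t_late` so firing cessation is not
#' smeared over). A window without IFF samples contributes a rate of 0, so a
#' response that has ceased by `t_late` has a decline of 1; if there is no
#' firing around `t_early` the decline is `NA`.
#'
#' @param spikes A spike-train tibble or numeric vector of spike times.
#' @param t_early,t_late Evaluation times (s), default 2 and 5.
#' @param window Smoothing window passed to [smooth_iff()].
#' @param half_window_s Averaging half-width around each time point (s).
#' @return A single decline fraction.
#' @export
hold_decline <- function(spikes, t_early = 2, t_late = 5, window = 5,
                         half_window_s = 0.5) {
  t <- if (is.numeric(spikes)) spikes else spikes$time
  if (length(t) < 2) return(NA_real_)
  sm <- smooth_iff(compute_iff(t), window = window)
  win_rate <- function(lo, hi) {
    v <- sm$iff[sm$time >= lo & sm$time <= hi]
    if (length(v)) mean(v) else 0
  }
  r_early <- win_rate(t_early - half_window_s, t_early + half_window_s)
  r_late <- win_rate(t_late - half_window_s, t_late)
  if (r_early <= 0) return(NA_real_)
  1 - r_late / r_early
}

#' Write an IFF trace to CSV
#'
#' @param iff An IFF tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_iff_csv <- function(iff, path) {
  readr::write_csv(tibble::tibble(time_s = iff$time, iff_hz = iff$iff), path)
  invisible(path)
}
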