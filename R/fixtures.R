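#' Packaged reference measurement tables
#'
#' Three small tables of published reference measurements that anchor the
#' biologically derived generator parameters:
#'
#' * `reference_tau_ri()` — 44 decay time constants (ms) fitted to
#'   voltage-clamp current recordings from mechanosensory neurons across nine
#'   preparations; their mean (about 8 ms) sets `tau_RI`.
#' * `reference_tau_si()` — 12 decay time constants (ms) fitted to
#'   current-clamp membrane-potential recordings from three isolated Merkel
#'   cells; used for `tau_SI`.
#' * `reference_k_si_peak()` — 12 peak-to-steady-state ratios from the same
#'   Merkel-cell recordings; the range that constrains `K_SI_peak`.
#'
#' @return A tibble with columns `fiber` (or `cell`), `run`, `value`.
#' @export
reference_tau_ri <- function() {
  readr::read_csv(
    system.file("extdata", "tau_ri_ms.csv", package = "merkelsim", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' @rdname reference_tau_ri
#' @export
reference_tau_si <- function() {
  readr::read_csv(
    system.file("extdata", "tau_si_ms.csv", package = "merkelsim", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' @rdname reference_tau_ri
#' @export
reference_k_si_peak <- function() {
  readr::read_csv(
    system.file("extdata", "k_si_peak.csv", package = "merkelsim", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Synthetic exponential-decay traces
#'
#' Generates patch-clamp-like decay traces \eqn{y = A e^{-t/\tau} + b} with
#' additive Gaussian noise, for exercising and validating the
#' exponential-fitting layer when real recordings are not at hand.
#' Reproducible under `seed`.
#'
#' @param n Number of traces.
#' @param true_tau_s Decay time constant (s).
#' @param amplitude Peak amplitude A (pA or mV).
#' @param offset Steady-state offset b (0 for a pure exponential).
#' @param noise_sd Gaussian noise standard deviation, absolute units.
#' @param seed RNG seed.
#' @param dt_s Sampling interval (default 0.1 ms, i.e. 10 kHz).
#' @param duration_s Trace duration; defaults to ten time constants.
#' @return A list of `n` tibbles with columns `time` and `value`.
#' @export
make_synthetic_decay_traces <- function(n,
                                        true_tau_s,
                                        amplitude = 1,
                                        offset = 0,
                                        noise_sd = 0,
                                        seed = 1L,
                                        dt_s = 1e-4,
                                        duration_s = 10 * true_tau_s) {
  stopifnot(n >= 0, true_tau_s > 0, noise_sd >= 0)
  if (n == 0) return(list())
  time <- seq(0, duration_s, by = dt_s)
  clean <- amplitude * exp(-time / true_tau_s) + offset
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      tibble::tibble(
        time = time,
        value = clean + stats::rnorm(length(time), sd = noise_sd)
      )
    })
  })
}

#' Synthetic reference spike trains from the forward model
#'
#' Runs the forward model at known generator parameters and returns its
#' low- and high-magnitude spike trains, for parameter-recovery studies of
#' [fit_free_parameters()]. Refitting to real recordings instead requires
#' user-supplied spike-time CSVs ([read_spikes_csv()]).
#'
#' @param config A [sim_config()]; its generator holds the "true" parameters.
#' @return A named list of two spike-train tibbles, `low` and `high`.
#' @export
make_reference_spikes <- function(config = sim_config()) {
  list(
    low = run_simulation(config, magnitude = "low")$spikes,
    high = run_simulation(config, magnitude = "high")$spikes
  )
}
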