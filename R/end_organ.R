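#' End-organ configuration
#'
#' Architecture and spike-generation parameters of the whole SAI end organ.
#' The afferent branches into heminodes, each fed by a cluster of Merkel
#' cell-neurite complexes; the default `{8, 5, 3, 1}` structure has four
#' heminodes and 17 complexes in total. Each heminode is a leaky
#' integrate-and-fire (LIF) unit
#' \deqn{C \frac{dV}{dt} = -V/R + I(t)}
#' with R = 5 GOhm, C = 30 pF, firing threshold 30 mV above baseline, and a
#' 1 ms refractory period. When any heminode fires, the potentials of all
#' heminodes are reset to baseline (the clusters feed one axon).
#'
#' @param cluster_sizes Integer vector of complexes per cluster (all >= 1).
#' @param R_gohm Membrane resistance in GOhm.
#' @param C_pf Membrane capacitance in pF.
#' @param V_threshold_mv Firing threshold above baseline, mV.
#' @param refractory_s Refractory period in seconds.
#' @param refractory_scope `"global"` (default): after any spike, no heminode
#'   may fire and all potentials are held at baseline for the refractory
#'   period. `"per_heminode"`: only the spiking unit is silenced (all are
#'   still reset by the cross-heminode rule).
#' @return An object of class `"end_organ_config"`.
#' @export
end_organ_config <- function(cluster_sizes = c(8, 5, 3, 1),
                             R_gohm = 5,
                             C_pf = 30,
                             V_threshold_mv = 30,
                             refractory_s = 1e-3,
                             refractory_scope = c("global", "per_heminode")) {
  refractory_scope <- match.arg(refractory_scope)
  if (length(cluster_sizes) < 1 || any(cluster_sizes < 1) ||
      any(cluster_sizes != round(cluster_sizes))) {
    stop("`cluster_sizes` must be positive integers.", call. = FALSE)
  }
  stopifnot(R_gohm > 0, C_pf > 0, V_threshold_mv > 0, refractory_s > 0)
  structure(
    list(
      cluster_sizes = as.integer(cluster_sizes),
      R_gohm = R_gohm, C_pf = C_pf,
      V_threshold_mv = V_threshold_mv,
      refractory_s = refractory_s,
      refractory_scope = refractory_scope
    ),
    class = "end_organ_config"
  )
}

#' @export
print.end_organ_config <- function(x, ...) {
  cat("<end_organ_config> clusters {", paste(x$cluster_sizes, collapse = ", "),
      "} =", sum(x$cluster_sizes), "complexes\n")
  cat(sprintf("  LIF: R = %g GOhm, C = %g pF, threshold = %g mV, refractory = %g ms (%s)\n",
              x$R_gohm, x$C_pf, x$V_threshold_mv, x$refractory_s * 1000,
              x$refractory_scope))
  invisible(x)
}

#' Per-heminode input currents
#'
#' All complexes are assumed identical, so the current entering heminode k is
#' the shared per-complex total current multiplied by the cluster size.
#'
#' @param current A generator-current tibble (uses its `i_total` column), or
#'   any tibble with `time` and `i_total`.
#' @param config An [end_organ_config()].
#' @return A long tibble with columns `time`, `heminode`, `size`, `current`
#'   (pA).
#' @export
heminode_currents <- function(current, config) {
  sizes <- config$cluster_sizes
  purrr::map_dfr(seq_along(sizes), function(k) {
    tibble::tibble(
      time = current$time,
      heminode = k,
      size = sizes[k],
      current = sizes[k] * current$i_total
    )
  })
}

#' Simulate spike generation at the heminodes
#'
#' Integrates one LIF unit per heminode by forward Euler on the trace grid
#' (threshold checked after each step), with the cross-heminode reset rule:
#' the first unit to reach threshold emits a spike and all potentials return
#' to baseline. During the refractory period potentials are held at baseline.
#' Simultaneous threshold crossings are resolved deterministically in favour
#' of the heminode with the larger instantaneous input current (then the
#' lower index). The model is fully deterministic: no noise source.
#'
#' @param current A per-complex generator-current tibble (its `i_total` is
#'   scaled by each cluster size), or a long tibble from
#'   [heminode_currents()].
#' @param config An [end_organ_config()].
#' @return A tibble of class `"spike_train"` with columns `time` (s) and
#'   `heminode` (1-based cluster index of the unit that fired).
#' @export
simulate_spikes <- function(current, config) {
  if (all(c("heminode", "current") %in% names(current))) {
    wide <- tidyr::pivot_wider(
      current[c("time", "heminode", "current")],
      names_from = "heminode", values_from = "current"
    )
    time <- wide$time
    imat <- as.matrix(wide[-1])
  } else {
    time <- current$time
    imat <- outer(current$i_total, as.numeric(config$cluster_sizes))
  }
  dt <- trace_dt(time)
  lif_spike_times(time, imat, config, dt)
}

# Shared LIF engine. imat: n x k matrix of heminode input currents (pA).
# Uses the forward-Euler recurrence V_j = alpha V_{j-1} + beta I_{j-1},
# alpha = 1 - dt/tau, beta = dt * 1000 / C  (pA -> mV/s via C in pF), run
# segment-by-segment with stats::filter between spikes.
lif_spike_times <- function(time, imat, config, dt) {
  n <- length(time)
  k <- ncol(imat)
  tau <- config$R_gohm * config$C_pf / 1000   # GOhm * pF = ms -> s
  alpha <- 1 - dt / tau
  if (alpha <= 0) {
    stop("Time step too large for stable forward-Euler LIF integration.",
         call. = FALSE)
  }
  beta <- dt * 1000 / config$C_pf
  thr <- config$V_threshold_mv
  ref_steps <- ceiling(config$refractory_s / dt)
  per_hemi <- config$refractory_scope == "per_heminode"

  spike_t <- numeric(0)
  spike_h <- integer(0)
  start <- 1L                      # index holding the current V state
  v0 <- rep(0, k)                  # potentials at time[start]
  silent_until <- rep(0L, k)       # per-heminode refractory end (step index)
  block <- 4096L                   # filter window; state carried across blocks
  while (start < n) {
    seg <- start:min(start + block - 1L, n - 1L)  # drive indices (left endpoints)
    m <- length(seg)
    v <- matrix(0, m, k)
    for (j in seq_len(k)) {
      drive <- beta * imat[seg, j]
      if (per_hemi && silent_until[j] > start) {
        drive[seq_len(min(m, silent_until[j] - start))] <- 0
      }
      v[, j] <- stats::filter(drive, alpha, method = "recursive", init = v0[j])
    }
    crossed <- v >= thr
    if (!any(crossed)) {           # no spike in this block: carry state forward
      start <- seg[m] + 1L
      v0 <- v[m, ]
      next
    }
    hit_row <- min(which(rowSums(crossed) > 0))
    idx <- start + hit_row         # V after step hit_row lives at time[idx]
    cand <- which(crossed[hit_row, ])
    if (length(cand) > 1) {
      cand <- cand[order(-imat[idx - 1L, cand], cand)][1]
    }
    spike_t <- c(spike_t, time[idx])
    spike_h <- c(spike_h, cand[1])
    v0 <- rep(0, k)                # cross-heminode reset to baseline
    if (per_hemi) {
      silent_until[cand[1]] <- idx + ref_steps
      start <- idx                 # integration resumes immediately
    } else {
      start <- idx + ref_steps     # potentials held at baseline over refractory
    }
  }
  out <- tibble::tibble(time = spike_t, heminode = as.integer(spike_h))
  class(out) <- c("spike_train", class(out))
  attr(out, "end_organ_config") <- config
  attr(out, "duration_s") <- time[n]
  out
}

#' Write spike times to CSV
#'
#' @param spikes A spike-train tibble.
#' @param path File path.
#' @param heminode Include the heminode provenance column?
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path, heminode = TRUE) {
  out <- tibble::tibble(spike_time_s = spikes$time)
  if (heminode) out$heminode_id <- spikes$heminode
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!"spike_time_s" %in% names(raw)) {
    stop("Spike CSV needs a `spike_time_s` column.", call. = FALSE)
  }
  out <- tibble::tibble(
    time = raw$spike_time_s,
    heminode = if ("heminode_id" %in% names(raw)) {
      as.integer(raw$heminode_id)
    } else {
      NA_integer_
    }
  )
  if (is.unsorted(out$time, strictly = TRUE)) {
    stop("Spike times must be strictly increasing.", call. = FALSE)
  }
  class(out) <- c("spike_train", class(out))
  out
}
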