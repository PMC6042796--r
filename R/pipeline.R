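#' Simulation configuration
#'
#' Bundles the per-stage parameter sets for a full end-organ simulation:
#' stimulus geometry, skin surrogate, generator preset, end-organ
#' architecture, and analysis windows. All defaults reproduce the base
#' wildtype model.
#'
#' @param genotype Generator preset name (see [generator_params()]).
#' @param magnitude Default stimulus magnitude, `"low"` or `"high"`.
#' @param reference_um Reference (high) indentation depth, um.
#' @param low_fraction Low-magnitude fraction of `reference_um`.
#' @param ramp_s,total_s,dt_s Stimulus timing (s).
#' @param skin A [skin_params()] object.
#' @param generator A [generator_params()] object; overrides `genotype`.
#' @param end_organ An [end_organ_config()].
#' @param windows Phase windows from [phase_windows()].
#' @param seed RNG seed recorded in manifests (only synthetic-trace noise is
#'   random; the simulation pipeline itself is deterministic).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(genotype = "wildtype_with_USI",
                       magnitude = "high",
                       reference_um = 60,
                       low_fraction = 0.5,
                       ramp_s = 0.3,
                       total_s = 5,
                       dt_s = 1e-4,
                       skin = skin_params(),
                       generator = NULL,
                       end_organ = end_organ_config(),
                       windows = NULL,
                       seed = 1L) {
  if (is.null(generator)) generator <- generator_params(genotype)
  if (is.null(windows)) windows <- phase_windows(ramp_s = ramp_s)
  structure(
    list(
      stimulus = list(
        magnitude = magnitude, reference_um = reference_um,
        low_fraction = low_fraction, ramp_s = ramp_s,
        total_s = total_s, dt_s = dt_s
      ),
      skin = skin,
      generator = generator,
      end_organ = end_organ,
      windows = windows,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  stimulus: %s magnitude, ref %g um (low = %g%%), ramp %g s, total %g s, dt %g s\n",
              x$stimulus$magnitude, x$stimulus$reference_um,
              100 * x$stimulus$low_fraction, x$stimulus$ramp_s,
              x$stimulus$total_s, x$stimulus$dt_s))
  print(x$skin)
  print(x$generator)
  print(x$end_organ)
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(
    list(
      stimulus = config$stimulus,
      skin = unclass(config$skin),
      generator = unclass(config$generator),
      end_organ = unclass(config$end_organ),
      windows = lapply(config$windows, as.numeric),
      seed = config$seed
    ),
    path
  )
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  skin <- do.call(skin_params, c(
    list(preset = raw$skin$preset),
    raw$skin[setdiff(names(raw$skin), "preset")]
  ))
  gen <- do.call(generator_params, c(
    list(preset = raw$generator$genotype),
    raw$generator[setdiff(names(raw$generator), "genotype")]
  ))
  eo <- end_organ_config(
    cluster_sizes = raw$end_organ$cluster_sizes,
    R_gohm = raw$end_organ$R_gohm,
    C_pf = raw$end_organ$C_pf,
    V_threshold_mv = raw$end_organ$V_threshold_mv,
    refractory_s = raw$end_organ$refractory_s,
    refractory_scope = raw$end_organ$refractory_scope
  )
  sim_config(
    magnitude = raw$stimulus$magnitude,
    reference_um = raw$stimulus$reference_um,
    low_fraction = raw$stimulus$low_fraction,
    ramp_s = raw$stimulus$ramp_s,
    total_s = raw$stimulus$total_s,
    dt_s = raw$stimulus$dt_s,
    skin = skin,
    generator = gen,
    end_organ = eo,
    windows = raw$windows,
    seed = raw$seed
  )
}

#' Run the full simulation pipeline
#'
#' Executes stimulus -> skin -> generator -> end organ -> analysis and
#' returns all intermediate traces. Optionally writes every trace as CSV
#' plus a YAML run manifest (config echo, package version, seed).
#'
#' @param config A [sim_config()].
#' @param magnitude Stimulus magnitude override (`"low"` / `"high"`).
#' @param stress Optional externally supplied stress tibble (e.g. from
#'   [read_stress_csv()]); skips the stimulus and skin stages.
#' @param out_dir Optional output directory for CSVs and `manifest.yaml`.
#' @return An object of class `"sai_run"`: a list with elements `stimulus`,
#'   `stress`, `current`, `spikes`, `iff`, `iff_smooth`, `phase_rates`,
#'   and `config`.
#' @export
run_simulation <- function(config = sim_config(),
                           magnitude = NULL,
                           stress = NULL,
                           out_dir = NULL) {
  if (is.null(magnitude)) magnitude <- config$stimulus$magnitude
  stimulus <- NULL
  if (is.null(stress)) {
    stimulus <- default_stimulus(
      magnitude = magnitude,
      reference_um = config$stimulus$reference_um,
      low_fraction = config$stimulus$low_fraction,
      ramp_s = config$stimulus$ramp_s,
      total_s = config$stimulus$total_s,
      dt_s = config$stimulus$dt_s
    )
    stress <- qlv_stress(stimulus, config$skin)
  }
  current <- generator_current(stress, config$generator)
  spikes <- simulate_spikes(current, config$end_organ)
  iff <- if (nrow(spikes) >= 2) {
    compute_iff(spikes)
  } else {
    tibble::tibble(time = numeric(0), iff = numeric(0))
  }
  iff_smooth <- smooth_iff(iff)
  rates <- phase_rates(spikes, config$windows)

  run <- structure(
    list(
      stimulus = stimulus, stress = stress, current = current,
      spikes = spikes, iff = iff, iff_smooth = iff_smooth,
      phase_rates = rates, magnitude = magnitude, config = config
    ),
    class = "sai_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.sai_run <- function(x, ...) {
  cat("<sai_run>", x$config$generator$genotype, "/", x$magnitude, "magnitude\n")
  cat(sprintf("  peak stress %.3g Pa, peak per-complex current %.3g pA, %d spikes\n",
              max(x$stress$stress), max(x$current$i_total), nrow(x$spikes)))
  print(x$phase_rates)
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Writes every trace of an `sai_run` as CSV plus a YAML manifest and a
#' config echo into `out_dir`.
#'
#' @param run An `sai_run` from [run_simulation()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$stimulus)) {
    write_stimulus_csv(run$stimulus, file.path(out_dir, "stimulus.csv"))
  }
  write_stress_csv(run$stress, file.path(out_dir, "stress.csv"))
  write_current_csv(run$current, file.path(out_dir, "current.csv"))
  write_spikes_csv(run$spikes, file.path(out_dir, "spikes.csv"))
  write_iff_csv(run$iff, file.path(out_dir, "iff.csv"))
  readr::write_csv(run$phase_rates, file.path(out_dir, "phase_rates.csv"))
  manifest <- list(
    package = "merkelsim",
    version = as.character(utils::packageVersion("merkelsim")),
    seed = run$config$seed,
    magnitude = run$magnitude,
    genotype = run$config$generator$genotype,
    skin_preset = run$config$skin$preset,
    Ginf = run$config$skin$Ginf,
    n_spikes = nrow(run$spikes)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  write_sim_config(run$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Skin-viscoelasticity sweep
#'
#' Reruns the pipeline with the long-time relaxation ratio `Ginf` of the
#' skin surrogate set to each of the requested values (default the
#' biologically observed extremes and median 0.81 / 0.35 / 0.10, on the
#' 418-um skin preset), with the generator's USI component disabled. This
#' probes whether skin viscoelastic relaxation alone can produce slowly
#' adapting firing.
#'
#' @param config Base [sim_config()] (its generator is replaced by the
#'   no-USI wildtype preset unless `keep_generator = TRUE`).
#' @param Ginf_values Numeric vector of long-time modulus ratios.
#' @param keep_generator Keep `config$generator` instead of the no-USI preset.
#' @return A tibble with columns `Ginf` and a list-column `run` of
#'   [run_simulation()] bundles.
#' @export
run_s4_sweep <- function(config = sim_config(),
                         Ginf_values = c(0.81, 0.35, 0.10),
                         keep_generator = FALSE) {
  gen <- if (keep_generator) config$generator else generator_params("wildtype_no_USI")
  runs <- purrr::map(Ginf_values, function(g) {
    cfg <- config
    cfg$skin <- skin_params(
      "s4_418um",
      Ginf = g,
      stress_scale = config$skin$stress_scale
    )
    cfg$generator <- gen
    run_simulation(cfg)
  })
  tibble::tibble(Ginf = Ginf_values, run = runs)
}
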