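#' Skin mechanics parameters
#'
#' Parameter set for the one-dimensional quasi-linear viscoelastic (QLV)
#' surrogate of skin mechanics: a one-term Ogden hyperelastic law in uniaxial
#' compression filtered through a two-term Prony-series reduced relaxation
#' function
#' \deqn{G(t) = G_\infty + G_1 e^{-t/\tau_1} + G_2 e^{-t/\tau_2}.}
#'
#' Two presets are provided. `"default_380um"` is the main parameter set
#' (mu = 1.3 kPa, alpha = 7.9, tau1 = 0.08 s, tau2 = 1.2 s, G1 = 0.59,
#' G2 = 0.10, Ginf = 0.31, thickness 380 um). `"s4_418um"` is the
#' viscoelasticity-sweep variant (thickness 418 um, tau2 = 1.21 s) whose
#' `Ginf` is meant to be varied over \{0.81, 0.35, 0.10\}; when `Ginf` is
#' overridden, `G1` and `G2` are rescaled proportionally so the relaxation
#' function still starts at 1.
#'
#' @param preset `"default_380um"` or `"s4_418um"`.
#' @param Ginf Optional override of the long-time modulus ratio.
#' @param stress_scale Dimensionless calibration factor applied to the elastic
#'   stress. The default is calibrated so that the wildtype high-magnitude
#'   per-complex peak generator current falls in the 10-20 pA range
#'   (see the methods vignette).
#' @param ... Named overrides of individual fields (`mu_kpa`, `alpha`,
#'   `tau1_s`, `tau2_s`, `G1`, `G2`, `thickness_um`).
#' @return An object of class `"skin_params"` (a named list).
#' @export
skin_params <- function(preset = c("default_380um", "s4_418um"),
                        Ginf = NULL,
                        stress_scale = NULL,
                        ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    default_380um = list(
      mu_kpa = 1.3, alpha = 7.9, tau1_s = 0.08, tau2_s = 1.2,
      G1 = 0.59, G2 = 0.10, Ginf = 0.31,
      thickness_um = 380, stress_scale = 0.22
    ),
    s4_418um = list(
      mu_kpa = 1.3, alpha = 7.9, tau1_s = 0.08, tau2_s = 1.21,
      G1 = 0.59, G2 = 0.10, Ginf = 0.31,
      thickness_um = 418, stress_scale = 0.22
    )
  )
  p$preset <- preset
  if (!is.null(Ginf)) {
    if (Ginf <= 0 || Ginf >= 1) stop("`Ginf` must lie in (0, 1).", call. = FALSE)
    rescale <- (1 - Ginf) / (p$G1 + p$G2)
    p$G1 <- p$G1 * rescale
    p$G2 <- p$G2 * rescale
    p$Ginf <- Ginf
  }
  if (!is.null(stress_scale)) p$stress_scale <- stress_scale
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("Unknown skin parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(dots)] <- dots
  validate_skin_params(p)
  structure(p, class = "skin_params")
}

validate_skin_params <- function(p) {
  stopifnot(
    p$mu_kpa > 0, p$alpha > 0, p$thickness_um > 0, p$stress_scale > 0,
    p$tau1_s > 0, p$tau2_s > p$tau1_s,
    p$G1 > 0, p$G2 > 0, p$Ginf > 0
  )
  if (abs(p$G1 + p$G2 + p$Ginf - 1) > 1e-6) {
    stop("Prony weights must satisfy G1 + G2 + Ginf = 1.", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.skin_params <- function(x, ...) {
  cat("<skin_params> preset:", x$preset, "\n")
  cat(sprintf(
    "  mu = %.2f kPa, alpha = %.2f, thickness = %g um, stress_scale = %g\n",
    x$mu_kpa, x$alpha, x$thickness_um, x$stress_scale
  ))
  cat(sprintf(
    "  Prony: G1 = %.3f (tau1 = %g s), G2 = %.3f (tau2 = %g s), Ginf = %.3f\n",
    x$G1, x$tau1_s, x$G2, x$tau2_s, x$Ginf
  ))
  invisible(x)
}

#' Instantaneous (elastic) compressive stress
#'
#' One-term Ogden law for uniaxial compression of the skin column. With
#' compressive stretch \eqn{\lambda = 1 - d/h} (indentation depth d, skin
#' thickness h) the compressive-positive stress is
#' \deqn{\sigma_e = s \cdot \frac{2\mu}{\alpha}
#'   \left(\lambda^{-\alpha/2 - 1} - \lambda^{\alpha - 1}\right),}
#' where `s` is the calibration factor `stress_scale`. Zero indentation gives
#' zero stress and stress grows monotonically with indentation.
#'
#' @param displacement_um Indentation depth(s) in micrometres
#'   (`0 <= d < thickness`).
#' @param params A [skin_params()] object.
#' @return Compressive stress in Pa (vectorised over `displacement_um`).
#' @export
elastic_stress <- function(displacement_um, params) {
  if (any(displacement_um < 0)) {
    stop("Indentation must be non-negative.", call. = FALSE)
  }
  if (any(displacement_um >= params$thickness_um)) {
    stop("Indentation must be smaller than the skin thickness.", call. = FALSE)
  }
  lambda <- 1 - displacement_um / params$thickness_um
  mu_pa <- params$mu_kpa * 1000
  params$stress_scale * (2 * mu_pa / params$alpha) *
    (lambda^(-params$alpha / 2 - 1) - lambda^(params$alpha - 1))
}

#' Quasi-linear viscoelastic stress response
#'
#' Converts a displacement stimulus into interior compressive stress:
#' the elastic stress history \eqn{\sigma_e(t)} from [elastic_stress()] is
#' passed through the hereditary integral
#' \deqn{\sigma(t) = \int_0^t G(t - s)\, \dot\sigma_e(s)\, ds}
#' with the two-term Prony relaxation function of the parameter set. The
#' integral is evaluated with recursive exponential filters that are exact
#' when \eqn{\sigma_e} is piecewise linear on the sampling grid; the result is
#' clamped at zero to guard against interpolation undershoot.
#'
#' @param stimulus A stimulus tibble from [ramp_and_hold()] (uniform grid).
#' @param params A [skin_params()] object.
#' @return A stress tibble with columns `time` (s) and `stress` (Pa,
#'   compressive positive); the skin parameters are attached as the
#'   `"skin_params"` attribute and stimulus parameters are carried through.
#' @export
qlv_stress <- function(stimulus, params) {
  dt <- trace_dt(stimulus$time)
  sig_e <- elastic_stress(stimulus$displacement, params)
  stress <- params$Ginf * sig_e +
    prony_branch(sig_e, dt, params$tau1_s) * params$G1 +
    prony_branch(sig_e, dt, params$tau2_s) * params$G2
  out <- tibble::tibble(time = stimulus$time, stress = pmax(stress, 0))
  attr(out, "skin_params") <- params
  attr(out, "stim_params") <- attr(stimulus, "stim_params")
  out
}

# One Prony branch: y(t) = int_0^t exp(-(t-s)/tau) de(s), exact for piecewise-
# linear e. With constant slope r over a step, the update is
#   y_k = y_{k-1} exp(-dt/tau) + r tau (1 - exp(-dt/tau)).
prony_branch <- function(e, dt, tau) {
  a <- exp(-dt / tau)
  x <- c(0, diff(e)) * (tau / dt) * (1 - a)
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Import an externally computed stress trace
#'
#' Reads a two-column CSV (`time_s`, `stress_Pa`) — for example the output of
#' a finite-element skin model — validates it, and linearly resamples it onto
#' a uniform simulation grid.
#'
#' @param path CSV path.
#' @param dt_s Target sampling interval; defaults to the median input spacing.
#' @return A stress tibble (`time`, `stress`).
#' @export
read_stress_csv <- function(path, dt_s = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "stress_Pa") %in% names(raw))) {
    stop("Stress CSV needs columns `time_s` and `stress_Pa`.", call. = FALSE)
  }
  if (any(diff(raw$time_s) <= 0)) {
    stop("Stress CSV time column must be strictly increasing.", call. = FALSE)
  }
  if (any(raw$stress_Pa < 0)) {
    stop("Compressive stress must be non-negative.", call. = FALSE)
  }
  if (is.null(dt_s)) dt_s <- stats::median(diff(raw$time_s))
  grid <- seq(min(raw$time_s), max(raw$time_s), by = dt_s)
  tibble::tibble(
    time = grid,
    stress = pmax(stats::approx(raw$time_s, raw$stress_Pa, xout = grid)$y, 0)
  )
}

#' @rdname read_stress_csv
#' @param stress A stress tibble.
#' @export
write_stress_csv <- function(stress, path) {
  readr::write_csv(
    tibble::tibble(time_s = stress$time, stress_Pa = stress$stress),
    path
  )
  invisible(path)
}
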