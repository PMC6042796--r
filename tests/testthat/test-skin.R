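test_that("elastic stress matches the Ogden closed form and is monotone", {
  p <- skin_params(stress_scale = 1)
  expect_equal(elastic_stress(0, p), 0)
  # independent hand evaluation at stretch 0.9 (indentation 0.1 * thickness)
  lambda <- 0.9
  mu <- 1300; alpha <- 7.9
  expected <- (2 * mu / alpha) * (lambda^(-alpha / 2 - 1) - lambda^(alpha - 1))
  expect_equal(elastic_stress(0.1 * p$thickness_um, p), expected,
               tolerance = 1e-12)
  d <- seq(0, 300, by = 10)
  expect_true(all(diff(elastic_stress(d, p)) > 0))
  # stress_scale is a pure multiplier
  p2 <- skin_params(stress_scale = 2)
  expect_equal(elastic_stress(50, p2), 2 * elastic_stress(50, p))
})

test_that("full compression and negative indentation are rejected", {
  p <- skin_params()
  expect_error(elastic_stress(p$thickness_um, p), "thickness")
  expect_error(elastic_stress(-1, p), "non-negative")
})

test_that("Prony weights must sum to one", {
  expect_error(skin_params(G1 = 0.7), "G1 \\+ G2 \\+ Ginf")
  expect_error(skin_params(Ginf = 1.2), "0, 1")
  # overriding Ginf rescales G1/G2 proportionally
  p <- skin_params(Ginf = 0.10)
  expect_equal(p$G1 + p$G2 + p$Ginf, 1, tolerance = 1e-12)
  expect_equal(p$G1 / p$G2, 5.9, tolerance = 1e-9)
})

test_that("QLV step response spans the full modulus down to Ginf", {
  p <- skin_params(stress_scale = 1)
  stim <- step_stimulus(50, total_s = 12, dt_s = 1e-3)
  S <- elastic_stress(50, p)
  sig <- qlv_stress(stim, p)
  # instantaneous response is the full modulus (G1 + G2 + Ginf = 1)
  expect_equal(sig$stress[2], S, tolerance = 1e-2)
  # long-time limit is Ginf * S
  expect_equal(sig$stress[nrow(sig)], p$Ginf * S, tolerance = 1e-3)
  # relaxation ratio equals Ginf / (G1 + G2 + Ginf)
  expect_equal(sig$stress[nrow(sig)] / sig$stress[2],
               p$Ginf / (p$G1 + p$G2 + p$Ginf), tolerance = 1e-2)
})

test_that("recursive QLV filter agrees with quadrature of the integral", {
  p <- skin_params()
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 1, dt_s = 1e-4)
  fast <- qlv_stress(stim, p)
  slow <- quadrature_qlv(stim, p)
  expect_lt(max(abs(fast$stress - slow)) / max(slow), 1e-6)
})

test_that("ramp-and-hold stress peaks near end of ramp then relaxes", {
  p <- skin_params()
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 5, dt_s = 1e-3)
  sig <- qlv_stress(stim, p)
  # viscoelastic relaxation makes the stress peak slightly lead the ramp end
  k_peak <- which.max(sig$stress)
  expect_lt(sig$time[k_peak], 0.3 + 1e-9)
  expect_gt(sig$time[k_peak], 0.15)
  hold <- sig$stress[sig$time > sig$time[k_peak]]
  expect_true(all(diff(hold) <= 1e-9))
  # decays toward the Ginf-scaled elastic stress from above
  expect_gt(sig$stress[nrow(sig)], p$Ginf * elastic_stress(60, p) * 0.999)
})

test_that("lower Ginf produces strictly more hold-phase relaxation", {
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 5, dt_s = 1e-3)
  ratio <- vapply(c(0.81, 0.35, 0.10), function(g) {
    sig <- qlv_stress(stim, skin_params("s4_418um", Ginf = g))
    sig$stress[nrow(sig)] / max(sig$stress)
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
})

test_that("stress CSV import validates, resamples, and round-trips", {
  raw <- tibble::tibble(time_s = c(0, 0.1, 0.3, 0.4),
                        stress_Pa = c(0, 10, 30, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path)
  tr <- read_stress_csv(path, dt_s = 0.05)
  expect_equal(tr$time, seq(0, 0.4, by = 0.05))
  expect_equal(tr$stress[tr$time == 0.2], 20)  # linear interpolation

  bad <- tibble::tibble(time_s = c(0, 0.2, 0.1), stress_Pa = c(0, 1, 2))
  readr::write_csv(bad, path)
  expect_error(read_stress_csv(path), "increasing")
  neg <- tibble::tibble(time_s = c(0, 0.1), stress_Pa = c(0, -5))
  readr::write_csv(neg, path)
  expect_error(read_stress_csv(path), "non-negative")

  sig <- qlv_stress(ramp_and_hold(30, total_s = 0.5, dt_s = 1e-3), skin_params())
  write_stress_csv(sig, path)
  back <- read_stress_csv(path, dt_s = 1e-3)
  expect_equal(back$stress, sig$stress, tolerance = 1e-9)
})
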