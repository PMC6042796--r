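wt <- generator_params("wildtype_with_USI")

test_that("kernels evaluate the fitted exponential forms", {
  # RI: a e^(-t/tau)
  expect_equal(kernel_RI(0, wt), 0.74)
  expect_equal(kernel_RI(0.008, wt), 0.74 / exp(1))
  expect_lt(kernel_RI(0.08, wt), 1e-4 * 0.74)
  # SI: b (Kp e^(-t/tau) + Ks) -- floor b*Ks, value b at zero lag
  expect_equal(kernel_SI(0, wt), 0.24)
  expect_equal(kernel_SI(100 * 0.2, wt), 0.24 * 0.13, tolerance = 1e-9)
  # USI: c e^(-t/tau)
  expect_equal(kernel_USI(0, wt), 0.07)
  expect_equal(kernel_USI(1.7446, wt), 0.07 / exp(1))
  expect_error(kernel_RI(-0.01, wt), "non-negative")
})

test_that("genotype switches silence the right components", {
  cko <- generator_params("atoh1_cko")
  expect_equal(kernel_SI(c(0, 0.1, 1), cko), c(0, 0, 0))
  no_usi <- generator_params("wildtype_no_USI")
  expect_equal(kernel_USI(c(0, 0.1, 1), no_usi), c(0, 0, 0))
  expect_error(generator_params("atoh1_cko", b = 0.1), "Merkel")
  expect_error(generator_params("wildtype_with_USI", K_SI_steady = 0.5),
               "sum|equal 1")
})

test_that("step response is linear with the summed kernel coefficient", {
  tr <- step_stress(10, total_s = 2, dt_s = 1e-4)
  cur <- generator_current(tr, wt)
  # instantaneous response: (a + b + c) * 10 = 10.5 pA
  expect_equal(cur$i_total[2], 10.5, tolerance = 1e-9)
  # 1 s later: independent evaluation of the closed forms
  k <- which.min(abs(tr$time - (tr$time[2] + 1)))
  lag <- tr$time[k] - tr$time[2]
  expect_equal(cur$i_RI[k], 0.74 * exp(-lag / 0.008) * 10, tolerance = 1e-9)
  expect_equal(cur$i_SI[k], 0.24 * (0.87 * exp(-lag / 0.2) + 0.13) * 10,
               tolerance = 1e-9)
  expect_equal(cur$i_USI[k], 0.07 * exp(-lag / 1.7446) * 10, tolerance = 1e-9)
  expect_equal(cur$i_total[k], 0.7205, tolerance = 1e-3)
})

test_that("whole step response equals the analytic kernel sum", {
  tr <- step_stress(10, total_s = 1, dt_s = 1e-4)
  cur <- generator_current(tr, wt)
  lags <- tr$time[-1] - tr$time[2]
  analytic <- (kernel_RI(lags, wt) + kernel_SI(lags, wt) +
                 kernel_USI(lags, wt)) * 10
  expect_lt(max(abs(cur$i_total[-1] - analytic)) / max(analytic), 1e-6)
})

test_that("a step decrease drops current immediately by the kernel sum", {
  time <- seq(0, 1, by = 1e-4)
  stress <- ifelse(time < 0.5, ifelse(time > 0, 20, 0), 12)
  tr <- tibble::tibble(time = time, stress = stress)
  cur <- generator_current(tr, wt)
  k <- which(time >= 0.5)[1]
  unclamped <- cur$i_RI + cur$i_SI + cur$i_USI
  drop <- unclamped[k - 1] - unclamped[k]
  # the decay between adjacent samples is negligible next to the step
  expect_equal(drop, (0.74 + 0.24 + 0.07) * 8, tolerance = 1e-3)
  # here the drop overshoots the baseline, so the total is clamped at zero
  expect_equal(cur$i_total[k], 0)
  # afterwards the current relaxes smoothly: no further jump of step size
  expect_lt(abs(unclamped[k + 1] - unclamped[k]), 0.1 * drop)
})

test_that("generator current is homogeneous of degree one in stress", {
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 1, dt_s = 1e-3)
  sig <- qlv_stress(stim, skin_params())
  cur1 <- generator_current(sig, wt)
  sig3 <- sig
  sig3$stress <- 3 * sig$stress
  cur3 <- generator_current(sig3, wt)
  for (col in c("i_RI", "i_SI", "i_USI", "i_total")) {
    expect_equal(cur3[[col]], 3 * cur1[[col]], tolerance = 1e-12)
  }
})

test_that("recursive filter matches the brute-force discrete convolution", {
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 1, dt_s = 1e-3)
  sig <- qlv_stress(stim, skin_params())
  fast <- generator_current(sig, wt)
  slow <- brute_force_current(sig, wt)
  expect_lt(max(abs(fast$i_total - slow)) / max(slow), 1e-6)
})

test_that("held constant stress decays to the SI steady floor", {
  tr <- step_stress(10, total_s = 60, dt_s = 1e-2)
  cur <- generator_current(tr, wt)
  expect_equal(cur$i_total[nrow(cur)], 0.24 * 0.13 * 10, tolerance = 1e-3)
})

test_that("Atoh1-CKO current is the clamped sum of RI and USI only", {
  stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 1, dt_s = 1e-3)
  sig <- qlv_stress(stim, skin_params())
  cur <- generator_current(sig, generator_params("atoh1_cko"))
  expect_true(all(cur$i_SI == 0))
  expect_equal(cur$i_total, pmax(cur$i_RI + cur$i_USI, 0))
})

test_that("negative summed current is clamped to the zero baseline", {
  time <- seq(0, 1, by = 1e-3)
  stress <- ifelse(time > 0 & time < 0.3, 15, 0)   # release to zero
  cur <- generator_current(tibble::tibble(time = time, stress = stress), wt)
  expect_true(all(cur$i_total >= 0))
  expect_true(any(cur$i_RI + cur$i_SI + cur$i_USI < 0))
})

test_that("component peaks keep the reported ordering at default config", {
  run <- run_simulation(sim_config())
  expect_gt(max(run$current$i_SI), max(run$current$i_RI))
  expect_gt(max(run$current$i_USI), max(run$current$i_RI))
})

test_that("parameter sweeps shift current in the expected phase", {
  stim <- default_stimulus("low")
  sig <- qlv_stress(stim, skin_params())
  ramp_end <- 0.3

  sw <- sweep_parameter(sig, wt, "tau_RI", c(1, 8, 15))
  ramp_peak <- vapply(sw$current, function(cu) {
    max(cu$i_total[cu$time <= ramp_end])
  }, numeric(1))
  expect_true(all(diff(ramp_peak) > 0))

  sw <- sweep_parameter(sig, wt, "tau_SI", c(50, 200, 350))
  early <- vapply(sw$current, function(cu) {
    max(cu$i_total[cu$time > ramp_end & cu$time <= ramp_end + 0.5])
  }, numeric(1))
  expect_true(all(diff(early) > 0))

  sw <- sweep_parameter(sig, wt, "K_SI_peak", c(0.6, 0.87, 0.95))
  late <- vapply(sw$current, function(cu) {
    mean(cu$i_total[cu$time >= 2])
  }, numeric(1))
  # larger K_SI_peak means smaller steady floor: late-hold current falls
  expect_true(all(diff(late) < 0))
  # identity sweep reproduces the base trace exactly
  base <- generator_current(sig, wt)
  expect_equal(sw$current[[2]]$i_total, base$i_total)
})

test_that("halving or doubling the time step barely moves the peak current", {
  peak_at <- function(dt) {
    stim <- ramp_and_hold(60, ramp_s = 0.3, total_s = 1, dt_s = dt)
    max(generator_current(qlv_stress(stim, skin_params()), wt)$i_total)
  }
  p1 <- peak_at(1e-4)
  expect_lt(abs(peak_at(5e-5) / p1 - 1), 1e-3)
  expect_lt(abs(peak_at(2e-4) / p1 - 1), 1e-3)
})
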