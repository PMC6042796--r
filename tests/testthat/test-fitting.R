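test_that("noiseless exponential decays are recovered exactly", {
  tr <- make_synthetic_decay_traces(1, true_tau_s = 0.008, amplitude = 5)[[1]]
  fit <- fit_exponential(tr, "a_exp")
  expect_true(fit$converged)
  expect_equal(fit$tau_s, 0.008, tolerance = 1e-6)
  expect_equal(fit$amplitude, 5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)

  tr2 <- make_synthetic_decay_traces(1, true_tau_s = 0.2, amplitude = 20,
                                     offset = 3)[[1]]
  fit2 <- fit_exponential(tr2, "a_exp_plus_b")
  expect_equal(fit2$tau_s, 0.2, tolerance = 1e-6)
  expect_equal(fit2$offset, 3, tolerance = 1e-6)

  expect_error(fit_exponential(tr[1:3, ]), "at least 5")
})

test_that("exponential fitting is scale-equivariant", {
  tr <- make_synthetic_decay_traces(1, true_tau_s = 0.05, amplitude = 2,
                                    noise_sd = 0.02, seed = 7)[[1]]
  f1 <- fit_exponential(tr, "a_exp")
  tr_k <- tr
  tr_k$value <- 10 * tr$value
  f2 <- fit_exponential(tr_k, "a_exp")
  expect_equal(f2$tau_s, f1$tau_s, tolerance = 1e-6)
  expect_equal(f2$amplitude, 10 * f1$amplitude, tolerance = 1e-6)
})

test_that("tau recovery stays unbiased under noise and tightens as noise falls", {
  recover <- function(noise_sd, n = 100) {
    traces <- make_synthetic_decay_traces(n, true_tau_s = 0.008, amplitude = 5,
                                          noise_sd = noise_sd, seed = 11)
    taus <- vapply(traces, function(tr) fit_exponential(tr, "a_exp")$tau_s,
                   numeric(1))
    mean(taus)
  }
  # 10% noise, 100 replicates: mean recovered tau within 10% of truth
  expect_equal(recover(0.5), 0.008, tolerance = 0.10)
  # bias shrinks toward zero with the noise level
  bias <- vapply(c(0.5, 0.05, 0.005), function(s) {
    abs(recover(s, n = 25) - 0.008) / 0.008
  }, numeric(1))
  expect_lt(bias[2], bias[1] + 0.01)
  expect_lt(bias[3], 0.01)
})

test_that("peak/steady ratio splits a decaying trace", {
  time <- seq(0, 5, by = 1e-3)
  pure <- tibble::tibble(time = time, value = exp(-time / 0.2))
  r <- peak_steady_ratio(pure)
  expect_equal(r$K_steady, 0, tolerance = 1e-6)
  expect_equal(r$K_peak, 1, tolerance = 1e-6)
  const <- tibble::tibble(time = time, value = rep(2, length(time)))
  expect_equal(peak_steady_ratio(const)$K_steady, 1)
  merkel <- tibble::tibble(time = time, value = 0.87 * exp(-time / 0.2) + 0.13)
  r3 <- peak_steady_ratio(merkel)
  expect_equal(r3$K_peak, 0.87, tolerance = 1e-3)
  expect_equal(r3$K_steady, 0.13, tolerance = 1e-3)
})

test_that("table summaries reproduce the reference statistics", {
  t_ri <- reference_tau_ri()
  s <- summarize_table_fits(t_ri)
  expect_equal(s$n, 44)
  expect_equal(round(s$mean), 8)
  expect_equal(round(s$sd), 5)
  t_si <- reference_tau_si()
  expect_equal(summarize_table_fits(t_si)$n, 12)
  expect_equal(nrow(reference_k_si_peak()), 12)
  expect_error(summarize_table_fits(3.2), "at least two")
})

test_that("free-parameter fit is a fixed point at the generating parameters", {
  cfg <- sim_config(dt_s = 2e-4)
  refs <- make_reference_spikes(cfg)
  truth <- c(0.74, 0.24, 0.07)
  fit <- fit_free_parameters(refs, cfg, init = truth, max_iter = 4)
  expect_gt(fit$per_magnitude$r_squared[1], 0.999)
  expect_gt(fit$per_magnitude$r_squared[2], 0.999)
  expect_equal(c(fit$a, fit$b, fit$c), truth, tolerance = 0.02)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(td$estimate, c(fit$a, fit$b, fit$c))
  expect_equal(glance(fit)$r_squared, fit$r_squared)
})

test_that("dropping the USI coefficient degrades the end-organ fit", {
  cfg <- sim_config(dt_s = 2e-4)
  refs <- make_reference_spikes(cfg)   # generated with the USI component
  # the three-parameter family contains the generating model, so its
  # attainable optimum is an essentially perfect fit
  full <- fit_free_parameters(refs, cfg, init = c(0.74, 0.24, 0.07),
                              max_iter = 4)
  cfg_no_usi <- sim_config(genotype = "wildtype_no_USI", dt_s = 2e-4)
  reduced <- fit_free_parameters(refs, cfg_no_usi,
                                 init = c(0.74, 0.36, 0))
  expect_gt(full$r_squared, 0.999)
  expect_gt(full$r_squared, reduced$r_squared)
  expect_equal(reduced$c, 0)
})

test_that("exp_fit tidiers expose estimates and fit quality", {
  tr <- make_synthetic_decay_traces(1, true_tau_s = 0.05, amplitude = 2)[[1]]
  fit <- fit_exponential(tr, "a_exp")
  td <- tidy(fit)
  expect_equal(td$term, c("tau_s", "amplitude"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$tau_s, fit$tau_s)
})
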