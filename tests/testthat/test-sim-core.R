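test_that("transport settles a step under default gains and is reproducible", {
  quiet <- perception_spec(centroid_noise_sd = 0)
  ts <- simulate_transport(1000, 0, perception = quiet)
  expect_true(ts$settled)
  expect_lt(ts$settle_time_s, 5)
  expect_lt(abs(tail(ts$trajectory$error_um, 1)), 5)
  # start at target: settles immediately
  ts0 <- simulate_transport(500, 500, perception = quiet)
  expect_equal(ts0$settle_time_s, 0)
  # determinism under a seed with noise
  a <- simulate_transport(1000, 0, seed = 17)
  b <- simulate_transport(1000, 0, seed = 17)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("a zero-gain loop never settles and reports it without error", {
  ts <- simulate_transport(1000, 0, gains = pd_gains(0, 0),
                           perception = perception_spec(centroid_noise_sd = 0),
                           max_t = 2)
  expect_false(ts$settled)
  expect_true(is.na(ts$settle_time_s))
})

test_that("synthetic puncture traces hit the rupture force at the annotation", {
  tr <- synth_puncture_trace(noise_sd = 0)
  ri <- rupture_annotation(tr)
  expect_equal(max(tr$f_total_mN), 3.9)
  expect_identical(which.max(tr$f_total_mN), ri)
  # clean trace: detector recovers the annotated sample exactly
  ev <- detect_puncture(tr)
  expect_identical(ev$rupture_index, ri)
  # peak components reproduce the configured 3.1 / 2.4 split
  expect_equal(tr$ft_mN[ri] / tr$fz_mN[ri], 3.1 / 2.4, tolerance = 1e-9)
  expect_equal(sqrt(tr$ft_mN[ri]^2 + tr$fz_mN[ri]^2), tr$f_total_mN[ri])
  # with the rupture force set to the exact norm of the split, the peak
  # components are the split itself
  tr2 <- synth_puncture_trace(
    cell_instance(membrane_rupture_force = sqrt(3.1^2 + 2.4^2)),
    noise_sd = 0)
  ri2 <- rupture_annotation(tr2)
  expect_equal(tr2$ft_mN[ri2], 3.1, tolerance = 1e-9)
  expect_equal(tr2$fz_mN[ri2], 2.4, tolerance = 1e-9)
  # determinism
  expect_identical(synth_puncture_trace(noise_sd = 0.05, seed = 2),
                   synth_puncture_trace(noise_sd = 0.05, seed = 2))
})

test_that("perception stub is unbiased noise with calibrated tip error", {
  expect_equal(perception_observe(123.4, 0), 123.4)
  err <- tip_placement_error(10000, seed = 1)
  expect_equal(mean(err), 4.95, tolerance = 0.02 * 4.95)
  expect_lt(quantile(err, 0.999, names = FALSE), 16)
  expect_gte(min(err), 0)
})

test_that("injection cycles execute all phases and account time", {
  cyc <- run_injection_cycle(fast_config(), seed = 11)
  expect_true(cyc$punctured)
  expect_true(is.finite(cyc$tip_error_um))
  expect_equal(cyc$t_total_s, sum(cyc$phase_s))
  expect_true(all(cyc$phase_s >= 0))
  # the default budget lands near 20 s per cell
  expect_equal(cyc$t_total_s, 20, tolerance = 0.15)
  # guaranteed survival when punctured and prob = 1
  cfg <- fast_config(survival = list(mode = "fixed", prob = 1))
  cyc2 <- run_injection_cycle(cfg, seed = 12)
  expect_true(cyc2$punctured)
  expect_true(cyc2$survived)
  # transport timeout marks the cycle failed, not an error
  cfg3 <- fast_config(gains = pd_gains(0, 0))
  cyc3 <- run_injection_cycle(cfg3, seed = 13)
  expect_identical(cyc3$failed_phase, "transport")
  expect_false(cyc3$punctured)
})

test_that("batch counters are conserved and reproducible", {
  b <- run_batch(15, fast_config(), seed = 19)
  expect_identical(b$n_tot, 15L)
  expect_lte(b$n_sur, b$n_puc)
  expect_lte(b$n_puc, b$n_tot)
  expect_identical(b$injected_counter, b$n_puc)
  expect_equal(b$t_tim_s, sum(b$cycles$t_total_s))
  expect_identical(batch_json(b),
                   batch_json(run_batch(15, fast_config(), seed = 19)))
  # single-cell batch stays consistent
  b1 <- run_batch(1, fast_config(), seed = 2)
  expect_identical(b1$n_tot, 1L)
  expect_lte(b1$n_sur, b1$n_puc)
  # counters hold across arbitrary seeds
  for (s in c(101, 202, 303)) {
    bs <- run_batch(8, fast_config(), seed = s)
    expect_true(bs$n_sur <= bs$n_puc && bs$n_puc <= bs$n_tot)
  }
})

test_that("fixed survival probability behaves binomially across seeds", {
  cfg <- fast_config(survival = list(mode = "fixed", prob = 0.84))
  n_seeds <- 24
  n_cells <- 25
  surv <- vapply(seq_len(n_seeds), function(s) {
    run_batch(n_cells, cfg, seed = 4000 + s)$n_sur
  }, 0L)
  p_hat <- sum(surv) / (n_seeds * n_cells)
  se <- sqrt(0.84 * 0.16 / (n_seeds * n_cells))
  expect_lt(abs(p_hat - 0.84), 3 * se)
})

test_that("glance metrics agree with the metric formulas on raw counters", {
  b <- run_batch(12, fast_config(), seed = 31)
  gl <- glance(b)
  expect_equal(gl$efficiency_s_per_cell,
               injection_efficiency(b$t_tim_s, b$n_tot))
  expect_equal(gl$puncture_rate_pct,
               puncture_success_rate(b$n_puc, b$n_tot))
  if (b$n_puc > 0) {
    expect_equal(gl$survival_rate_pct, survival_rate(b$n_sur, b$n_puc))
  }
  expect_identical(nrow(tidy(b)), 12L)
})
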