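test_that("recovery_curve validates its inputs", {
  expect_error(recovery_curve(c(0.1, 0.2), c(1, 2, 3)), "same length")
  expect_error(recovery_curve(c(0.1, 0.1), c(1, 2)), "distinct")
  expect_error(recovery_curve(c(0, 0.5), c(1, 2), scheme = "saturation"),
               "strictly positive")
  expect_silent(recovery_curve(c(0, 0.5), c(-99, 50), scheme = "inversion"))
  expect_error(recovery_curve(c(-0.1, 0.5), c(1, 2), scheme = "inversion"),
               "non-negative")
})

test_that("fit_recovery is exact on noiseless curves", {
  spec0 <- generator_spec(seed = 1, noise_sd_frac = 0)
  sat <- gen_recovery(1.0, m0 = 100, scheme = "saturation", spec = spec0)
  f <- fit_recovery(sat)
  expect_equal(f$t1, 1.0, tolerance = 1e-8)
  expect_equal(f$m0, 100, tolerance = 1e-6)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$dof, 9L)
  inv <- gen_recovery(0.5, m0 = 100, scheme = "inversion", spec = spec0)
  fi <- fit_recovery(inv)
  expect_equal(fi$t1, 0.5, tolerance = 1e-8)
  expect_equal(fi$amplitude, 200, tolerance = 1e-5)  # 2*m0 for inversion
  expect_error(
    fit_recovery(recovery_curve(c(1, 2, 3, 4), c(1, 2, 3, 4))),
    "at least 5")
})

test_that("fit is invariant to intensity rescaling", {
  cur <- gen_recovery(0.8, spec = generator_spec(seed = 7))
  f1 <- fit_recovery(cur)
  cur2 <- recovery_curve(cur$delays, cur$intensities * 137, cur$scheme)
  f2 <- fit_recovery(cur2)
  expect_equal(f2$t1, f1$t1, tolerance = 1e-9)
  expect_equal(f2$t1_se / f1$t1_se, 1, tolerance = 1e-6)
  expect_equal(f2$m0 / f1$m0, 137, tolerance = 1e-9)
})

test_that("Monte-Carlo parameter recovery is unbiased with honest SEs", {
  n <- 200
  t1hat <- se <- numeric(n)
  for (i in seq_len(n)) {
    spec <- generator_spec(seed = i, noise_sd_frac = 0.02,
                           delay_range = c(0.01, 5))
    f <- fit_recovery(gen_recovery(0.8, spec = spec))
    t1hat[i] <- f$t1
    se[i] <- f$t1_se
  }
  ## unbiased within 3 SE of the replicate mean
  expect_lt(abs(mean(t1hat) - 0.8), 3 * sd(t1hat) / sqrt(n))
  ## reported SEs track the empirical spread within 25%
  expect_lt(abs(sd(t1hat) / mean(se) - 1), 0.25)
})

test_that("ill-conditioned curve warns; bound-hitting fit is flagged", {
  ## all delays far short of T1: clean curve, but the fitted T1 sits far
  ## beyond the sampled window
  spec <- generator_spec(seed = 2, noise_sd_frac = 0,
                         delay_range = c(1e-3, 5e-2))
  expect_warning(fit_recovery(gen_recovery(5, spec = spec)),
                 "ill-conditioned")
  ## pure noise around a constant: T1 runs to a search bound -> flagged,
  ## not an error
  flat <- recovery_curve(seq(0.1, 2, length.out = 10),
                         rep(100, 10) + c(-1, 1), scheme = "saturation")
  f <- quiet_fit(flat)
  expect_false(f$converged)
})

test_that("compare_t1 reproduces hand-evaluated z and verdicts", {
  cmp <- compare_t1(fake_fit(1.0, 0.01), fake_fit(2.0, 0.01))
  expect_equal(cmp$z_stat, 1.0 / sqrt(2e-4), tolerance = 1e-10)  # 70.71
  expect_equal(cmp$verdict, "distinct")
  cmp2 <- compare_t1(fake_fit(1.00, 0.5), fake_fit(1.10, 0.5), alpha = 0.05)
  expect_equal(cmp2$z_stat, 0.1 / sqrt(0.5), tolerance = 1e-10)  # 0.1414
  expect_equal(cmp2$p_value, 2 * pnorm(-0.1 / sqrt(0.5)))        # ~0.888
  expect_equal(cmp2$verdict, "equal_within_error")
  same <- compare_t1(fake_fit(1.2, 0.03), fake_fit(1.2, 0.03))
  expect_equal(same$z_stat, 0)
  expect_equal(same$verdict, "equal_within_error")
  ## welch reference is strictly more conservative than normal
  w <- compare_t1(fake_fit(1.0, 0.05), fake_fit(1.15, 0.05),
                  method = "welch")
  z <- compare_t1(fake_fit(1.0, 0.05), fake_fit(1.15, 0.05))
  expect_gt(w$p_value, z$p_value)
  ## degenerate and unconverged inputs
  expect_error(compare_t1(fake_fit(1, 0), fake_fit(1, 0)), "zero")
  bad <- fake_fit(1, 0.1)
  bad$converged <- FALSE
  expect_error(compare_t1(bad, fake_fit(1, 0.1)), "converged")
})

test_that("classify_flexibility maps verdicts to regimes", {
  distinct <- compare_t1(fake_fit(1.0, 0.02), fake_fit(0.5, 0.02))
  expect_equal(classify_flexibility(distinct), "motion_dominated")
  equal <- compare_t1(fake_fit(1.0, 0.5), fake_fit(1.1, 0.5))
  expect_equal(classify_flexibility(equal), "spin_diffusion_dominated")
})

test_that("decision rule has power against real T1 differences", {
  n <- 60
  hits <- vapply(seq_len(n), function(i) {
    pr <- gen_t1_pair(1.0, 0.5, spec = generator_spec(seed = 5000 + i,
                                                      noise_sd_frac = 0.02))
    cmp <- compare_t1(fit_recovery(pr$ring), fit_recovery(pr$methyl))
    cmp$verdict == "distinct"
  }, logical(1))
  expect_true(all(hits))  # 2:1 T1 ratio at 2% noise is always detected
})

test_that("mono-exponential fit is robust to slow two-pool exchange", {
  ## k_ex * t1_a = 0.05: pool-A T1 recovered within 5%
  t1a <- 0.8
  cur <- gen_two_pool(t1a, 0.3, k_ex = 0.05 / t1a,
                      spec = generator_spec(seed = 1, noise_sd_frac = 0))
  f <- fit_recovery(cur)
  expect_lt(abs(f$t1 - t1a) / t1a, 0.05)
})
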