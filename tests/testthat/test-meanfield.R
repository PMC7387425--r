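# printed calibration values (3 significant figures)
P_D_HAT <- 2.59e-3
P_ALPHA_NULL <- 1.39e-3
P_GAMMA_EXC <- 2.59e-3
P_ALPHA_EXC <- 2.08e-3
P_GAMMA_INH <- -2.60e-3

tw_inputs <- function() {
  p <- bone_params()
  list(p = p, v = sqrt(2 * pi) * p$eta * p$iota * p$L_z * p$p_bar)
}

test_that("null calibration reproduces the printed healthy rates", {
  x <- tw_inputs()
  cal <- calibrate_null(x$p$q_target, x$p$p_bar, x$v, x$p$beta, x$p$L_z)
  # closed-form oracle: direct arithmetic on the density balance
  expect_equal(cal$D_hat, 2.375e4 * x$v / 6e3, tolerance = 1e-12)
  expect_equal(cal$D_hat, P_D_HAT, tolerance = 0.02)
  expect_equal(cal$alpha_hat, P_ALPHA_NULL, tolerance = 0.02)

  # scaling: doubling the density target doubles D; alpha is unchanged
  # (alpha = v/(p*Lz*pi*beta^2) after substitution), so the gain rate
  # c = alpha*q*Lz*pi*beta^2 doubles in step with D and the mean degree
  # c/D stays 1
  cal2 <- calibrate_null(2 * x$p$q_target, x$p$p_bar, x$v, x$p$beta, x$p$L_z)
  expect_equal(cal2$D_hat, 2 * cal$D_hat)
  expect_equal(cal2$alpha_hat, cal$alpha_hat)
  ccoef <- x$p$L_z * pi * x$p$beta^2
  expect_equal(cal2$alpha_hat * 2 * x$p$q_target * ccoef / cal2$D_hat,
               cal$alpha_hat * x$p$q_target * ccoef / cal$D_hat)

  expect_error(calibrate_null(-1, 6e3, x$v, 0.025, 0.04), "positive")
})

test_that("switch calibration reproduces both printed configurations", {
  x <- tw_inputs()
  D <- calibrate_null(x$p$q_target, x$p$p_bar, x$v, x$p$beta, x$p$L_z)$D_hat

  exc <- calibrate_switch(D / 2, x$p$q_target, x$p$p_bar, x$v, x$p$beta, x$p$L_z)
  expect_equal(exc$gamma, P_GAMMA_EXC, tolerance = 0.02)
  expect_equal(exc$alpha, P_ALPHA_EXC, tolerance = 0.02)
  expect_equal(exc$c, D / 2 + exc$gamma)

  inh <- calibrate_switch(3 * D / 2, x$p$q_target, x$p$p_bar, x$v, x$p$beta, x$p$L_z)
  expect_equal(inh$gamma, P_GAMMA_INH, tolerance = 0.02)
  # reconstruction oracle for the inhibitory dendrite rate: gain rate D/2
  # spread over the projected osteocyte density (printed value suspected to
  # carry an exponent typo; mantissa agrees)
  expect_equal(inh$alpha, (D / 2) / (x$p$q_target * x$p$L_z * pi * x$p$beta^2),
               tolerance = 1e-12)
  expect_equal(signif(inh$alpha * 1e4, 3), 6.96)

  # lambda > 2*D would need a negative total rate for connected cells
  expect_error(calibrate_switch(2.5 * D, x$p$q_target, x$p$p_bar, x$v,
                                x$p$beta, x$p$L_z), "positivity")
})

test_that("steady state solves the self-consistent fixed point", {
  sw <- steady_state(bone_params())
  expect_equal(sw$q_bar, 2.375e4, tolerance = 1e-6)
  expect_equal(sw$k_ob, 1, tolerance = 1e-6)
  # edge-count oracle: each edge eventually joins two osteocytes, so
  # k_ot = 2 * (edge creation rate) / (osteocyte creation rate) = 2c p / (v q)
  expect_equal(sw$k_ot, 2, tolerance = 1e-6)
  expect_equal(sw$M_bar, sw$q_bar * sw$k_ot / 2)

  exc <- steady_state(bone_params(model_name = "switch"))
  expect_equal(exc$q_bar, 2.375e4, tolerance = 1e-6)
  expect_equal(exc$k_ob, 1, tolerance = 1e-6)
  expect_equal(exc$k_ot, 3, tolerance = 1e-6)

  inh <- steady_state(inh_params())
  expect_equal(inh$k_ot, 1, tolerance = 1e-6)

  # no dendrites: purely density balance
  p0 <- bone_params()
  p0$alpha <- 0
  s0 <- steady_state(p0)
  expect_equal(s0$c, 0)
  expect_equal(s0$k_ob, 0)
  expect_equal(s0$k_ot, 0)
  expect_equal(s0$q_bar, p0$lambda_ * p0$p_bar / s0$v_wave)
})

test_that("k_ot is invariant to lambda, gamma and p_bar", {
  base <- steady_state(bone_params(model_name = "switch"))
  for (lam_fac in c(0.6, 1.4)) {
    p <- bone_params(model_name = "switch")
    p$lambda_ <- p$lambda_ * lam_fac
    expect_equal(steady_state(p)$k_ot, base$k_ot, tolerance = 1e-6)
  }
  p <- bone_params(model_name = "switch")
  p$gamma <- p$gamma * 0.5
  expect_equal(steady_state(p)$k_ot, base$k_ot, tolerance = 1e-6)
  # v_wave scales with p_bar so the ratio cancels
  p <- bone_params(model_name = "switch")
  p$p_bar <- p$p_bar * 2
  expect_equal(steady_state(p)$k_ot, base$k_ot, tolerance = 1e-6)
})

test_that("degree distributions are geometric with the chain ratio", {
  sw <- steady_state(bone_params())
  dd <- degree_distribution(sw)
  expect_equal(dd$s, 0.5, tolerance = 1e-6)
  expect_equal(dd$pmf[1:2], c(0.5, 0.25), tolerance = 1e-6)
  expect_equal(sum(dd$pmf), 1)
  # the steady-state pk itself matches the geometric law
  expect_equal(sw$pk_ob[1:10], dd$pmf[1:10], tolerance = 1e-6)

  p0 <- bone_params()
  p0$alpha <- 0
  d0 <- degree_distribution(steady_state(p0))
  expect_equal(d0$pmf[1], 1)

  cum <- steady_state(bone_params(model_name = "cumulative", lambda_ = 1e-3,
                                  gamma = 5e-4, alpha = 1.4e-3))
  expect_error(degree_distribution(cum), "transient_solve")
})

test_that("transient hierarchy conserves osteoblasts and has the stated limits", {
  p <- bone_params()
  hs <- transient_solve(p, T = 400)
  expect_lt(max(abs(rowSums(hs$v) - p$p_bar)), 1e-8 * p$p_bar)
  # null model: burial rate is degree-independent, so q(x) is exactly flat
  expect_lt(diff(range(hs$q_x)) / mean(hs$q_x), 1e-9)

  he <- transient_solve(bone_params(model_name = "switch"), T = 40)
  expect_equal(he$q_x[1], 2.375e4 / 2, tolerance = 0.01)
  hi <- transient_solve(inh_params(), T = 40)
  expect_equal(hi$q_x[1], 1.5 * 2.375e4, tolerance = 0.01)

  expect_error(transient_solve(p, k_max = 5), "k_max")
})

test_that("transient solution converges to the traveling wave", {
  p <- bone_params(model_name = "switch")
  hs <- transient_solve(p, T = 2500)
  sw <- steady_state(p)
  n <- length(hs$times)
  expect_equal(hs$q_x[n], sw$q_bar, tolerance = 5e-3)
  expect_equal(hs$k_ob_t[n], sw$k_ob, tolerance = 5e-3)
  expect_equal(hs$c_t[n], sw$c, tolerance = 5e-3)
  i <- which.min(abs(hs$times - (2500 - 300)))
  expect_equal(hs$k_ot_x[i], sw$k_ot, tolerance = 5e-3)
  # osteocyte degree distributions are proper pmfs
  expect_equal(rowSums(hs$w), rep(1, n), tolerance = 1e-6)
})
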