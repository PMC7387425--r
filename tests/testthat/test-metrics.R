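test_that("network summaries match hand-counted fixtures", {
  st <- fixture_state("two-cells-one-edge")
  ns <- network_summary(st)
  expect_equal(ns$k_ot_mean, 1)
  expect_equal(ns$q, 2 / 1e-3)     # two osteocytes in 1e-3 mm^3
  expect_equal(ns$M, 1 / 1e-3)
  expect_equal(ns$n_osteocytes, 2L)

  flat <- network_summary(fixture_state("flat-120-blasts"))
  expect_equal(flat$k_ob_mean, 0)
  expect_equal(flat$k_ot_mean, 0)
  expect_equal(flat$M, 0)
  expect_equal(flat$hist_ob, 120L)

  sl <- network_summary(fixture_state("steady-like"))
  expect_equal(sl$k_ob_mean, 1)           # constructed mean degree
  expect_equal(sl$n_osteocytes, 20L)
  expect_equal(sl$k_ot_mean, 120 / 20)    # 120 edges over 20 osteocytes
  # windowing by burial time
  expect_equal(network_summary(fixture_state("two-cells-one-edge"),
                               c(20, 40))$n_osteocytes, 1L)
  expect_error(network_summary(null_run_730(1), c(100, 50)), "empty window")
})

test_that("burial fraction follows the exponential depth law", {
  b <- burial_fraction(2.596804e-3, 6.560348e-4, 5e-3)
  expect_equal(b$fraction, 0.0196, tolerance = 0.02)
  expect_gt(b$one_in, 45)
  expect_lt(b$one_in, 55)

  expect_equal(burial_fraction(2.6e-3, 6.6e-4, 0)$fraction, 0)
  # linearisation oracle for small exponents
  f <- burial_fraction(1e-5, 1e-3, 1e-4)$fraction
  expect_equal(f, 1e-5 * 1e-4 / 1e-3, tolerance = 1e-3)
  expect_error(burial_fraction(-1, 1, 1), "positive")
})

test_that("general-parameter sensitivity rows are configuration-independent", {
  for (cfg in c("excitatory", "inhibitory")) {
    rep <- sensitivity_table(bone_params(), cfg)
    expect_equal(unlist(rep[rep$parameter == "eta", 2:6], use.names = FALSE),
                 c("down", "up", "down", "down", "down"))
    expect_equal(unlist(rep[rep$parameter == "p_bar", 2:6], use.names = FALSE),
                 c("-", "up", "-", "-", "-"))
    expect_equal(unlist(rep[rep$parameter == "kappa_diff", 2:6], use.names = FALSE),
                 rep("-", 5))
  }
  expect_error(sensitivity_table(bone_params(), "excitatory", factor = 1),
               "factor")
})

test_that("simulation/mean-field comparison scores and flags correctly", {
  sw <- steady_state(bone_params())
  fake <- data.frame(q = sw$q_bar, k_ob = sw$k_ob, k_ot = sw$k_ot,
                     v_wave = sw$v_wave)
  rep <- compare_sim_meanfield(fake, sw)
  expect_true(all(rep$z == 0))
  expect_true(all(rep$pass))

  # a deliberately inconsistent k_ot is flagged
  bad <- do.call(rbind, lapply(c(0.98, 1, 1.02), function(f) {
    data.frame(q = sw$q_bar * f, k_ob = sw$k_ob * f, k_ot = 10 * sw$k_ot * f,
               v_wave = sw$v_wave)
  }))
  repb <- compare_sim_meanfield(bad, sw)
  expect_false(repb$pass[repb$stat == "k_ot"])

  expect_error(compare_sim_meanfield(abm_run(bone_params(T = 30)), sw,
                                     window = c(0, 30)), "180")
})

test_that("steady-window estimators are stable under snapshot thinning", {
  tr <- null_run_730(1)
  s <- tr$summary
  w <- s$t >= 365
  full <- mean(s$k_ob_mean[w])
  thin <- mean(s$k_ob_mean[w & (seq_len(nrow(s)) %% 2 == 0)])
  se <- stats::sd(s$k_ob_mean[w]) / sqrt(sum(w) / 100) # generous n_eff
  expect_lt(abs(full - thin), se)
})
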