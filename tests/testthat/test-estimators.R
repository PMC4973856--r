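test_that("naive estimators are the stated convex combinations", {
  expect_equal(round(naive_selected_s(6.5, 7.42, 1 / 3), 2), 7.11)
  expect_equal(naive_selected_s(3, 3, 0.4), 3)
  expect_equal(naive_selected_s(6.5, 7.42, 1e-12), 7.42, tolerance = 1e-9)
  q <- derive_quantities(worked_design(), 100, 100)
  nv <- naive_selected_f(5.4, 6.0, 7.42, 3.82, q, 0.5)
  expect_equal(round(unlist(nv), 2),
               c(D_S_N_F = 6.41, D_Sc_N_F = 4.91, D_F_N = 5.66))
  nv4 <- naive_selected_f(5.7, 5.7, 7.42, 3.82, q, 0.5)
  expect_equal(round(c(nv4$D_S_N_F, nv4$D_Sc_N_F), 2), c(6.56, 4.76))
  nvc <- naive_selected_f(2, 2, 2, 2, q, 0.5)
  expect_equal(unlist(nvc), c(D_S_N_F = 2, D_Sc_N_F = 2, D_F_N = 2))
})

test_that("UMVUE corrections have the right direction for all valid inputs", {
  set.seed(21)
  d <- worked_design()
  q <- derive_quantities(d, 100, 100)
  for (k in 1:40) {
    x <- rnorm(1, 5, 3); y <- x - abs(rnorm(1))  # S selected
    u <- rnorm(1, 5, 3)
    es <- umvue_selected_s(x, y, u, q)
    expect_lt(es$D_S_U, es$D_S_N)
    y2 <- x + abs(rnorm(1))                      # F selected
    v <- rnorm(1, 5, 3); w <- rnorm(1, 5, 3)
    ef <- umvue_selected_f(x, y2, v, w, q, p_combine = 0.5)
    expect_gt(ef$D_S_U_F, ef$D_S_N_F)
    expect_lt(ef$D_Sc_U_F, ef$D_Sc_N_F)
  }
})

test_that("Mills ratio stays finite and the correction vanishes for large separation", {
  expect_true(is.finite(mills_ratio(-40)))
  expect_equal(mills_ratio(-40), 40, tolerance = 1e-2)  # asymptotically -f
  expect_equal(mills_ratio(8), dnorm(8), tolerance = 1e-12)
  # (D_S,N - y) -> +Inf: UMVUE converges to the naive estimate
  q <- derive_quantities(worked_design(), 100)
  es <- umvue_selected_s(6.5, -1e3, 7.42, q)
  expect_equal(es$D_S_U, es$D_S_N, tolerance = 1e-10)
  # and the guard handles very negative f without NaN
  es2 <- umvue_selected_s(6.5, 6.4999, 7.42, q, b = 300)
  expect_true(es2$f_U < -100 && is.finite(es2$D_S_U))
})

test_that("estimators are shift and scale equivariant", {
  d <- worked_design()
  q <- derive_quantities(d, 100, 100)
  base_s <- umvue_selected_s(6.5, 5.6, 7.42, q)
  base_f <- umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5)
  for (delta in c(-3.2, 0.5, 11)) {
    sh <- umvue_selected_s(6.5 + delta, 5.6 + delta, 7.42 + delta, q)
    expect_equal(sh$D_S_U, base_s$D_S_U + delta, tolerance = 1e-12)
    expect_equal(sh$f_U, base_s$f_U, tolerance = 1e-12)
    fh <- umvue_selected_f(5.4 + delta, 6.0 + delta, 7.42 + delta,
                           3.82 + delta, q, p_combine = 0.5)
    expect_equal(fh$D_S_U_F, base_f$D_S_U_F + delta, tolerance = 1e-12)
    expect_equal(fh$D_Sc_U_F, base_f$D_Sc_U_F + delta, tolerance = 1e-12)
    expect_equal(fh$f_V, base_f$f_V, tolerance = 1e-12)
  }
  for (cc in c(0.25, 4)) {
    dc <- asd_design(200, 200, sigma = 13.2 * cc, p_S = 0.5)
    qc <- derive_quantities(dc, 100, 100)
    sc <- umvue_selected_s(6.5 * cc, 5.6 * cc, 7.42 * cc, qc)
    expect_equal(sc$D_S_U, base_s$D_S_U * cc, tolerance = 1e-12)
    fc <- umvue_selected_f(5.4 * cc, 6.0 * cc, 7.42 * cc, 3.82 * cc, qc,
                           p_combine = 0.5)
    expect_equal(fc$D_F_U, base_f$D_F_U * cc, tolerance = 1e-12)
  }
})

test_that("known- and unknown-prevalence estimators coincide at s_X = p_S n1", {
  dk <- asd_design(200, 200, sigma = 13.2, p_S = 0.5, b = 0.4)
  du <- asd_design(200, 200, sigma = 13.2, p_S = "unknown", b = 0.4)
  sk <- stage_summaries(dk, x = 6.9, y = 5.6, u = 7.42)
  su <- stage_summaries(du, x = 6.9, y = 5.6, s_X = 100, u = 7.42)
  ek <- estimate_trial(dk, sk); eu <- estimate_trial(du, su)
  expect_equal(eu$D_S_U, ek$D_S_U, tolerance = 1e-12)
  expect_equal(eu$f_U, ek$f_U, tolerance = 1e-12)
  skf <- stage_summaries(dk, x = 5.4, y = 6.0, v = 7.42, w = 3.82)
  suf <- stage_summaries(du, x = 5.4, y = 6.0, s_X = 100, v = 7.42, w = 3.82,
                         s_V = 100)
  ekf <- estimate_trial(dk, skf); euf <- estimate_trial(du, suf)
  for (nm in c("D_S_U_F", "D_Sc_U_F", "D_F_U", "D_F_N", "f_V", "f_W"))
    expect_equal(euf[[nm]], ekf[[nm]], tolerance = 1e-12)
})

test_that("unknown-prevalence combinations use p_hat and pooled p_hat_star", {
  du <- asd_design(200, 200, sigma = 13.2, p_S = "unknown")
  s <- stage_summaries(du, x = 5.4, y = 6.0, s_X = 90, v = 7.42, w = 3.82,
                       s_V = 120)
  e <- estimate_trial(du, s)
  p_hat <- 90 / 200; p_star <- (90 + 120) / 400
  expect_equal(e$D_F_U, p_hat * e$D_S_U_F + (1 - p_hat) * e$D_Sc_U_F)
  expect_equal(e$D_F_N, p_star * e$D_S_N_F + (1 - p_star) * e$D_Sc_N_F)
  expect_equal(e$prevalence_used$p_hat_star, p_star)
})

test_that("Rao-Blackwell closed form equals the quadrature oracle on a grid", {
  q <- derive_quantities(worked_design(), 100, 100)
  sx <- sqrt(q$sigma2_X); tu <- sqrt(q$tau2_U)
  for (y in seq(4.6, 6.6, length.out = 5)) {
    for (z_S in seq(9, 13, length.out = 5)) {
      # invert the sufficient statistic at an arbitrary admissible (x, u) pair
      # consistent with z_S: pick x on the selected side, set u accordingly
      x <- y + 0.8
      u <- (z_S - (tu / sx) * x) * tu / sx
      cf <- umvue_selected_s(x, y, u, q)
      expect_equal((tu / sx) * x + (sx / tu) * u, z_S, tolerance = 1e-9)
      orc <- rb_oracle_selected_s(y, z_S, q, theta_probe = 0)
      expect_equal(cf$D_S_U, orc, tolerance = 1e-8)
      # sufficiency: the oracle is invariant to the probe mean
      expect_equal(orc, rb_oracle_selected_s(y, z_S, q, theta_probe = 2),
                   tolerance = 1e-8)
    }
  }
})

test_that("F-branch closed forms equal the quadrature oracle", {
  q <- derive_quantities(worked_design(), 100, 100)
  sx <- sqrt(q$sigma2_X); tv <- sqrt(q$tau2_V)
  for (y in c(5.0, 6.0, 7.0)) {
    x <- y - 0.6  # F selected
    for (v in c(5.0, 7.42)) {
      z_SF <- (tv / sx) * x + (sx / tv) * v
      cf <- umvue_selected_f(x, y, v, 3.82, q, p_combine = 0.5)
      expect_equal(cf$D_S_U_F, rb_oracle_selected_f(y, z_SF, q),
                   tolerance = 1e-8)
      expect_equal(rb_oracle_selected_f(y, z_SF, q, theta_probe = -1),
                   rb_oracle_selected_f(y, z_SF, q, theta_probe = 2),
                   tolerance = 1e-8)
    }
  }
})

test_that("futility variants reduce to the plain forms when B is not binding", {
  q <- derive_quantities(worked_design(), 100, 100)
  plain <- umvue_selected_s(6.5, 5.6, 7.42, q)
  expect_equal(umvue_selected_s(6.5, 5.6, 7.42, q, B = -Inf), plain)
  # B below the selection threshold: max picks the Y term
  expect_equal(umvue_selected_s(6.5, 5.6, 7.42, q, B = 5.0), plain)
  plainf <- umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5)
  lowB <- umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5,
                           B = -1e4, p_S = 0.5)
  for (nm in c("D_S_U_F", "D_Sc_U_F", "D_F_U"))
    expect_equal(lowB[[nm]], plainf[[nm]], tolerance = 1e-8)
})

test_that("futility-adjusted closed forms match the frozen quadrature oracles", {
  q <- derive_quantities(worked_design(), 100, 100)
  # S selected, Scenario-1 data, binding bound B = 6.2 > y = 5.6
  es <- umvue_selected_s(6.5, 5.6, 7.42, q, B = 6.2)
  expect_equal(es$D_S_U, 6.521483, tolerance = 1e-6)
  rt <- sqrt(q$sigma2_X + q$tau2_U)
  expect_equal(es$f_U, rt / q$sigma2_X * (es$D_S_N - 6.2), tolerance = 1e-12)
  # F selected, Scenario-3 data, binding bound B = 5.0
  ef <- umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5,
                         B = 5.0, p_S = 0.5)
  expect_equal(ef$D_S_U_F, 7.691516, tolerance = 1e-6)
  expect_true(ef$futility_adjusted)
  # and against the live oracles
  sx <- sqrt(q$sigma2_X); tu <- sqrt(q$tau2_U); tv <- sqrt(q$tau2_V)
  z_S <- (tu / sx) * 6.5 + (sx / tu) * 7.42
  expect_equal(es$D_S_U, rb_oracle_selected_s(5.6, z_S, q, B = 6.2),
               tolerance = 1e-8)
  z_SF <- (tv / sx) * 5.4 + (sx / tv) * 7.42
  expect_equal(ef$D_S_U_F,
               rb_oracle_selected_f(6.0, z_SF, q, B = 5.0, p_S = 0.5),
               tolerance = 1e-8)
})

test_that("futility guards: empty truncation interval and unsupported modes error", {
  q <- derive_quantities(worked_design(), 100, 100)
  # data outside the continuation region: lower bound above the observed x
  expect_error(
    umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5,
                     B = 50, p_S = 0.5),
    "continuation region")
  expect_error(
    umvue_selected_f(5.4, 6.0, 7.42, 3.82, q, p_combine = 0.5, B = 5.0),
    "known prevalence")
  du <- asd_design(200, 200, sigma = 13.2, p_S = "unknown", B = 5)
  expect_error(
    estimate_trial(du, stage_summaries(du, x = 6.5, y = 5.6, s_X = 100,
                                       u = 7.42)),
    "unsupported")
})

test_that("estimate_trial dispatches on the interim decision", {
  d <- worked_design()
  e1 <- estimate_scenario(1)
  expect_equal(e1$selected, "SELECT_S")
  e3 <- estimate_scenario(3)
  expect_equal(e3$selected, "SELECT_F")
  # branch/summary mismatch errors
  expect_error(
    estimate_trial(d, stage_summaries(d, x = 6.5, y = 5.6, v = 1, w = 1)),
    "no stage-2 summary 'u'")
  dB <- worked_design(B = 7)
  expect_error(
    estimate_trial(dB, stage_summaries(dB, x = 6.5, y = 5.6, u = 7.42)),
    "futility bound")
})
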