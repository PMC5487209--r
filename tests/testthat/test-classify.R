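test_that("no-feedback classification is the elimination-rate iff", {
  q <- omal_q()
  v <- classify_nofeedback(q$k1, q$k3, q$k4)
  expect_identical(v$verdict, "no_rebound")

  expect_identical(classify_nofeedback(0.2, 0.3, 0.1)$verdict, "rebound")
  # the iff is strict: equality on either margin is no rebound
  expect_identical(classify_nofeedback(0.1, 0.3, 0.1)$verdict, "no_rebound")
  expect_identical(classify_nofeedback(0.3, 0.1, 0.1)$verdict, "no_rebound")
})

test_that("direct feedback never rebounds when the ligand clears slowly", {
  q <- omal_q()
  for (h in list(make_constant(), make_mainly_linear(2.688, 0.5),
                 make_hyperbolic(0.3))) {
    v <- classify_direct(q$k1, q$k2, q$k3, q$k4, secant_bounds(h))
    expect_identical(v$verdict, "no_rebound")
  }
})

test_that("mainly linear direct feedback has an empty indeterminate band", {
  h <- make_mainly_linear(1.5, 0.5)
  b <- secant_bounds(h)
  k2 <- 0.5
  # rebound iff k4 < k1 and k4 < k3(1+h0)
  expect_identical(classify_direct(0.5, k2, 0.3, 0.2, b)$verdict, "rebound")
  expect_identical(classify_direct(0.5, k2, 0.3, 0.9, b)$verdict,
                   "no_rebound")
  expect_identical(classify_direct(0.5, k2, 0.05, 0.2, b)$verdict,
                   "no_rebound")  # k3(1+h0) = 0.125 < k4
  # sweep: verdict matches the iff everywhere (never indeterminate)
  for (k1 in c(0.05, 0.5, 2)) for (k3 in c(0.05, 0.5, 2))
    for (k4 in c(0.1, 0.8)) {
      v <- classify_direct(k1, k2, k3, k4, b)
      want <- if (k4 < k1 && k4 < k3 * (1 + 1.5)) "rebound" else "no_rebound"
      expect_identical(v$verdict, want)
    }
})

test_that("nonlinear direct feedback has the printed indeterminate band", {
  h <- make_hyperbolic(0.2)        # m = 0.8, M = 4, h0 = 0.8
  b <- secant_bounds(h)
  k1 <- 0.5; k2 <- 0.5; k4 <- 0.2
  l1 <- lambda12(k1, k2, k4)[["lambda1"]]
  lo <- k4 / (1 + b$M); hi <- min(k4 / (1 + b$m), -l1 / (1 + b$h0))
  expect_lt(lo, hi)
  expect_identical(classify_direct(k1, k2, lo * 0.9, k4, b)$verdict,
                   "no_rebound")
  expect_identical(classify_direct(k1, k2, (lo + hi) / 2, k4, b)$verdict,
                   "indeterminate")
  expect_identical(classify_direct(k1, k2, hi * 1.1, k4, b)$verdict,
                   "rebound")
})

test_that("rebound and no-rebound regions never overlap", {
  # consistency ordering 0 < k4/(1+M) <= k4/(1+h0) <= k4/(1+m) <= k4
  set.seed(21)
  for (i in 1:30) {
    h <- make_hyperbolic(runif(1, 0.05, 0.95))
    b <- secant_bounds(h)
    k4 <- exp(runif(1, log(0.02), log(5)))
    cuts <- c(k4 / (1 + b$M), k4 / (1 + b$h0), k4 / (1 + b$m), k4)
    expect_true(all(diff(cuts) >= -1e-12))
    expect_gt(cuts[1], 0)
  }
})

test_that("full-model classifier reproduces the omalizumab alpha bound", {
  p <- omalizumab_params()
  q <- nondimensionalize(p)
  h <- make_mainly_linear(p$R0 * 1, 0.5)    # H0 = 1 dimensional
  b <- secant_bounds(h)
  l1 <- lambda12(q$k1, q$k2, q$k4)[["lambda1"]]
  s <- p$kon * p$R0
  # guaranteed rebound for eps < -lambda1, i.e. alpha < -lambda1 * kon*R0;
  # with the published rounded conversion alpha = eps/0.625 this is 0.135
  expect_equal(-l1 / 0.625, 0.135, tolerance = 5e-3)
  just_below <- (-l1 * s) * 0.99
  just_above <- (-l1 * s) * 1.01
  v1 <- classify_full(q$k1, q$k2, q$k3, q$k4, b$h0, b$m, just_below / s)
  v2 <- classify_full(q$k1, q$k2, q$k3, q$k4, b$h0, b$m, just_above / s)
  expect_identical(v1$verdict, "rebound")
  expect_true(v1$generic)
  expect_identical(v2$verdict, "indeterminate")
})

test_that("full model rebounds for all eps in the big-k3 column", {
  # k1 > k4 and k3 > min(-lambda1/(1+h0), k4/(1+m)): all eps > 0
  h0 <- 1; m <- 1
  for (eps in c(1e-3, 0.1, 10, 1e3)) {
    v <- classify_full(k1 = 0.8, k2 = 0.5, k3 = 1.0, k4 = 0.2,
                       h0 = h0, m = m, eps = eps)
    expect_identical(v$verdict, "rebound")
  }
})

test_that("full-model verdicts outside proven intervals are indeterminate", {
  # k1 <= k4, lambda1 < lambda*+, eps just above eps1+, small k3
  k1 <- 0.05; k2 <- 0.5; k4 <- 0.6; h0 <- 1; m <- 1
  l1 <- lambda12(k1, k2, k4)[["lambda1"]]
  k3 <- -l1 / (1 + h0 + sqrt(h0 * (1 + h0))) * 0.5
  expect_lt(k3, k4 / (1 + m))
  th <- eps_thresholds(k3, h0)
  v <- classify_full(k1, k2, k3, k4, h0, m, th$eps1_plus * 1.01)
  expect_identical(v$verdict, "indeterminate")
  v2 <- classify_full(k1, k2, k3, k4, h0, m, th$eps1_plus * 0.99)
  expect_identical(v2$verdict, "rebound")
  # the full-model classifier never claims absence of rebound
  set.seed(22)
  for (i in 1:40) {
    r <- exp(runif(6, log(1e-2), log(1e2)))
    v <- classify_full(r[1], r[2], r[3], r[4], h0 = r[5], m = r[5] * 0.8,
                       eps = r[6])
    expect_true(v$verdict %in% c("rebound", "indeterminate"))
  }
})

test_that("every parameter set rebounds for small enough eps", {
  set.seed(23)
  for (i in 1:40) {
    r <- exp(runif(5, log(1e-2), log(1e2)))
    h0 <- exp(runif(1, log(0.05), log(5)))
    l1 <- lambda12(r[1], r[2], r[4])[["lambda1"]]
    th <- eps_thresholds(r[3], h0, lambda1 = l1)
    eps_small <- min(-l1, th$eps1_minus, th$eps3[th$eps3 > 0], Inf) * 1e-3
    v <- classify_full(r[1], r[2], r[3], r[4], h0 = h0, m = h0 * 0.5,
                       eps = eps_small)
    expect_identical(v$verdict, "rebound")
  }
})

test_that("generalised classifier covers the psoriasis example", {
  pp <- psoriasis_params()
  red <- ng_to_reduced(pp)
  pk <- pk_block_eigenvalues(pp)
  v <- classify_generalized(pk$leading, red$k3, g1 = red$h0, g2 = 1,
                            eps = red$eps)
  expect_identical(v$verdict, "rebound")
  expect_true(v$generic)
  expect_gt(v$thresholds$eps0, red$eps)

  # linear moderator dynamics reduce to the standard collision threshold
  th <- eps_thresholds(red$k3, red$h0)
  expect_equal(v$thresholds$eps1_minus, th$eps1_minus, tolerance = 1e-12)

  # formula arithmetic: g1 = g2 = k3 = 1 gives eps1- = 3 - sqrt(8)
  v2 <- classify_generalized(-0.5, 1, g1 = 1, g2 = 1, eps = 0.01)
  expect_equal(v2$thresholds$eps1_minus, 3 - sqrt(8), tolerance = 1e-12)

  expect_error(classify_generalized(-0.5, 1, g1 = 1, g2 = 0, eps = 0.01),
               "g1 and g2")
  expect_error(classify_generalized(0.5, 1, g1 = 1, g2 = 1, eps = 0.01),
               "negative")
})

test_that("region grids reproduce the elimination-plane structure", {
  keL <- c(0.05, 0.15, 0.4, 0.8)
  kout <- c(0.05, 0.15, 0.4, 0.8)
  keP <- 0.2; kon <- 0.592; koff <- 0.9; R0 <- 2.688

  g0 <- region_grid(keL, kout, keP, kon, koff, R0)
  want <- ifelse(g0$keL > keP & g0$kout > keP, "rebound", "no_rebound")
  expect_identical(g0$verdict, want)

  # mainly linear direct feedback drops the horizontal boundary to
  # kout = keP/(1 + R0*H0)
  H0 <- 1
  g1 <- region_grid(keL, kout, keP, kon, koff, R0,
                    feedback = make_mainly_linear(R0 * H0, 0.5))
  want1 <- ifelse(g1$keL > keP & g1$kout > keP / (1 + R0 * H0),
                  "rebound", "no_rebound")
  expect_identical(g1$verdict, want1)
  b <- attr(g1, "boundaries")
  expect_equal(b$kout_eq_keP_over_1h0, keP / (1 + R0 * H0))

  # full model at small feedback speed: rebound everywhere sampled
  g2 <- region_grid(keL, kout, keP, kon, koff, R0,
                    feedback = make_mainly_linear(R0 * H0, 0.5),
                    alpha = 1e-4)
  expect_true(all(g2$verdict == "rebound"))

  # nesting: no-feedback rebound region within direct, within full
  expect_true(all(g1$verdict[g0$verdict == "rebound"] == "rebound"))
  expect_true(all(g2$verdict[g1$verdict == "rebound"] == "rebound"))
})

test_that("the direct rebound boundary is decreasing in the feedback slope", {
  keP <- 0.2; R0 <- 2
  H0s <- seq(0.2, 3, length.out = 10)
  cuts <- keP / (1 + R0 * H0s)
  expect_true(all(diff(cuts) < 0))
})
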