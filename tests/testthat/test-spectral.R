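test_that("ligand-complex eigenvalues match the omalizumab values", {
  q <- omal_q()
  l <- lambda12(q$k1, q$k2, q$k4)
  expect_equal(l[["lambda1"]], -0.084, tolerance = 5e-3)
  expect_lt(l[["lambda2"]], l[["lambda1"]])
  expect_lt(l[["lambda1"]], 0)
  expect_gt(q$k2 + q$k4 + l[["lambda1"]], 0)
})

test_that("lambda1 anchors: value at k1 = k4, k2 -> 0, k1 -> Inf", {
  k2 <- 0.7; k4 <- 0.3
  expect_equal(lambda12(k4, k2, k4)[["lambda1"]], -k4, tolerance = 1e-12)
  expect_equal(lambda12(0.2, 1e-12, k4)[["lambda1"]], -k4, tolerance = 1e-6)
  expect_equal(lambda12(1e8, k2, k4)[["lambda1"]], -(k2 + k4),
               tolerance = 1e-6)
  # monotone decreasing in k1
  k1s <- seq(0.01, 5, length.out = 40)
  l1s <- vapply(k1s, function(k1) lambda12(k1, k2, k4)[["lambda1"]], 0)
  expect_true(all(diff(l1s) < 0))
})

test_that("direct-feedback receptor eigenvalue is -k3(1+h0)", {
  expect_equal(lambda34_direct(0.517, 0), -0.517)
  expect_equal(lambda34_direct(0.517, 2.688), -1.9067, tolerance = 1e-4)
})

test_that("moderator-block eigenvalues cover real and complex regimes", {
  # psoriasis reduction: printed eigenvalue closest to zero
  l <- lambda34_full(0.20556, 0.86707, 0.0071296)
  expect_true(l$real)
  expect_equal(l$lambda4, -1.37e-2, tolerance = 1e-2)
  expect_lt(l$lambda3, l$lambda4)

  l0 <- lambda34_full(0.4, 1.3, 0)
  expect_equal(c(l0$lambda3, l0$lambda4), c(-0.4, 0))

  lh <- lambda34_full(0.4, 0, 0.9)
  expect_equal(c(lh$lambda3, lh$lambda4), c(-0.9, -0.4))

  # between the collisions the pair is complex with Re = -(k3+eps)/2
  th <- eps_thresholds(0.4, 1.3)
  eps_mid <- (th$eps1_minus + th$eps1_plus) / 2
  lc <- lambda34_full(0.4, 1.3, eps_mid)
  expect_false(lc$real)
  expect_equal(Re(lc$lambda4), -(0.4 + eps_mid) / 2)
})

test_that("collision thresholds reproduce the psoriasis values", {
  th <- eps_thresholds(0.444 / 2.16, 0.86707, lambda1 = -0.0887)
  expect_lt(abs(th$eps1_minus - 0.0390), 1e-4)
  expect_lt(abs(-(0.444 / 2.16 + th$eps1_minus) / 2 - (-0.122)), 5e-4)
  expect_equal(th$lambda_star_minus, -(0.444 / 2.16 + th$eps1_minus) / 2,
               tolerance = 1e-12)
})

test_that("threshold identities and orderings hold", {
  th <- eps_thresholds(0.1, 0, lambda1 = -0.2)
  expect_equal(th$eps1_minus, 0.1)
  expect_equal(th$eps1_plus, 0.1)
  expect_equal(th$lambda_star_minus, -0.1)
  expect_equal(th$lambda_inf, -0.1)
  expect_equal(th$eps3, 0.3)   # -(k3 + 2*lambda1)

  set.seed(11)
  for (i in 1:50) {
    k3 <- exp(runif(1, log(0.01), log(10)))
    h0 <- exp(runif(1, log(0.01), log(10)))
    th <- eps_thresholds(k3, h0)
    expect_lt(th$lambda_star_plus, th$lambda_inf)
    expect_lt(th$lambda_inf, th$lambda_star_minus)
    expect_lt(th$eps1_minus, th$eps1_plus)
    expect_equal(th$lambda_star_plus, -k3 * th$f_star_plus,
                 tolerance = 1e-12)
    # collision eigenvalue equals -(k3 + eps1)/2 at both collisions
    expect_equal(th$lambda_star_minus, -(k3 + th$eps1_minus) / 2,
                 tolerance = 1e-10)
    expect_equal(th$lambda_star_plus, -(k3 + th$eps1_plus) / 2,
                 tolerance = 1e-10)
  }
})

test_that("the three algebraic forms of eps2 agree where defined", {
  set.seed(12)
  for (i in 1:50) {
    k3 <- exp(runif(1, log(0.05), log(5)))
    h0 <- exp(runif(1, log(0.05), log(5)))
    l1 <- -exp(runif(1, log(0.01), log(5)))
    th <- eps_thresholds(k3, h0, lambda1 = l1)
    if (!isTRUE(th$eps2_defined)) next
    alt1 <- th$eps1_minus -
      (l1 - th$lambda_star_minus)^2 / (l1 - th$lambda_inf)
    alt2 <- th$eps1_plus +
      (l1 - th$lambda_star_plus)^2 / (th$lambda_inf - l1)
    expect_equal(th$eps2, alt1, tolerance = 1e-10)
    expect_equal(th$eps2, alt2, tolerance = 1e-10)
  }
  # pole: lambda1 = lambda_inf is flagged, not raised
  th <- eps_thresholds(0.5, 1, lambda1 = -0.5 * 2)
  expect_false(th$eps2_defined)
  expect_true(is.na(th$eps2))
})

test_that("closed-form spectra match a dense numeric eigendecomposition", {
  draws <- rand_q(300, seed = 101)
  for (q in draws) {
    h0 <- exp(stats::runif(1, log(0.01), log(10)))
    J <- jacobian_at_baseline("full", q, h0)
    num <- sort(Re(eigen(J, only.values = TRUE)$values))
    l12 <- lambda12(q$k1, q$k2, q$k4)
    l34 <- lambda34_full(q$k3, h0, q$eps)
    cl <- sort(Re(c(l12, as.complex(l34$lambda3), as.complex(l34$lambda4))))
    expect_equal(num, unname(cl), tolerance = 1e-8)

    Jd <- jacobian_at_baseline("direct", q, h0)
    numd <- sort(Re(eigen(Jd, only.values = TRUE)$values))
    cld <- sort(c(l12, lambda34_direct(q$k3, h0)))
    expect_equal(numd, unname(cld), tolerance = 1e-8)
  }
})

test_that("printed eigenvector formulas solve (J - lambda I) v = 0", {
  q <- omal_q(0.1)
  h0 <- 2.688
  for (model in c("direct", "full")) {
    J <- jacobian_at_baseline(model, q, h0)
    V <- eigenvectors_at_baseline(model, q, h0)
    lams <- if (model == "direct")
      c(lambda12(q$k1, q$k2, q$k4), lambda34_direct(q$k3, h0))
    else {
      l34 <- lambda34_full(q$k3, h0, q$eps)
      c(lambda12(q$k1, q$k2, q$k4), l34$lambda3, l34$lambda4)
    }
    for (i in seq_along(lams)) {
      v <- V[, i] / max(abs(V[, i]))
      res <- (J %*% v) - as.complex(lams[i]) * v
      expect_lt(max(Mod(res)), 1e-8)
    }
  }
})

test_that("moderator eigenvalues approach their fast and slow limits", {
  k3 <- 0.7; h0 <- 1.9
  # fast feedback: lambda4 -> lambda_inf = -k3(1+h0), lambda3 -> -Inf
  lf <- lambda34_full(k3, h0, 1e6 * k3)
  expect_equal(lf$lambda4, -k3 * (1 + h0), tolerance = 1e-4)
  expect_lt(lf$lambda3, -1e5)
  # slow feedback: lambda4 = -(1+h0) eps + O(eps^2), by Richardson
  s1 <- lambda34_full(k3, h0, 1e-4)$lambda4 / 1e-4
  s2 <- lambda34_full(k3, h0, 1e-5)$lambda4 / 1e-5
  slope <- (10 * s2 - s1) / 9
  expect_equal(slope, -(1 + h0), tolerance = 1e-6)
})

test_that("full-model Jacobian is block lower-triangular as printed", {
  q <- omal_q(0.25)
  J <- jacobian_at_baseline("full", q, 2.688)
  expect_equal(J[c("x", "z"), c("y", "w")],
               matrix(0, 2, 2, dimnames = list(c("x", "z"), c("y", "w"))))
  expect_equal(J["x", "x"], -(q$k1 + 1))
  expect_equal(J["w", "y"], -q$eps * 2.688)
})
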