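# Shared fixtures and small numeric oracles used across the test files.

# dimensionless omalizumab parameters (alpha attached on request)
omal_q <- function(alpha = 0) nondimensionalize(omalizumab_params(alpha))

# random dimensionless parameter draws, log-uniform rates
rand_q <- function(n, seed, lo = 1e-2, hi = 1e2,
                   mu_range = c(0.05, 5), eps_range = c(1e-3, 10)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r <- exp(stats::runif(4, log(lo), log(hi)))
    list(mu = exp(stats::runif(1, log(mu_range[1]), log(mu_range[2]))),
         k1 = r[1], k2 = r[2], k3 = r[3], k4 = r[4],
         eps = exp(stats::runif(1, log(eps_range[1]), log(eps_range[2]))))
  })
}

# central finite-difference Jacobian restricted to selected components
fd_jacobian <- function(f, x, idx = seq_along(x), h = 1e-2) {
  J <- matrix(0, length(idx), length(idx))
  for (j in seq_along(idx)) {
    xp <- x; xm <- x
    xp[idx[j]] <- xp[idx[j]] + h
    xm[idx[j]] <- xm[idx[j]] - h
    J[, j] <- (f(xp)[idx] - f(xm)[idx]) / (2 * h)
  }
  J
}

# classifier-vs-simulator concordance over a (k1, k3) grid.
# Cells whose first-pass outcome contradicts the classifier are re-run
# at tighter tolerances with a finer detection threshold: near region
# boundaries the rebound amplitude shrinks towards zero, so marginal
# cells need more resolution before calling a genuine disagreement.
# Returns a data frame of disagreements (empty when concordant).
concordance_check <- function(model, k1s, k3s, k2, k4, h, eps = NULL,
                              mu = 0.2, delta = 1e-8,
                              rtol = 1e-10, atol = 1e-13) {
  b <- secant_bounds(h)
  bad <- list()
  simulate_verdict <- function(q, delta, rtol, atol, n_out = 4000) {
    tr <- simulate_model(model, q,
                         h = if (model == "basic") NULL else h,
                         rtol = rtol, atol = atol, n_out = n_out)
    det <- detect_rebound(tr, delta = delta)
    list(v = if (det$rebound) "rebound" else "no_rebound",
         rmax = det$rmax_over_r0)
  }
  for (k1 in k1s) for (k3 in k3s) {
    q <- list(mu = mu, k1 = k1, k2 = k2, k3 = k3, k4 = k4, eps = eps)
    v <- switch(model,
                basic = classify_nofeedback(k1, k3, k4),
                direct = classify_direct(k1, k2, k3, k4, b),
                full = classify_full(k1, k2, k3, k4, b$h0, b$m, eps))
    if (v$verdict == "indeterminate") next
    sim <- simulate_verdict(q, delta, rtol, atol)
    if (sim$v != v$verdict)
      sim <- simulate_verdict(q, delta = 1e-12, rtol = 1e-12,
                              atol = 1e-15, n_out = 8000)
    if (sim$v != v$verdict)
      bad[[length(bad) + 1]] <- data.frame(
        k1 = k1, k3 = k3, predicted = v$verdict, simulated = sim$v,
        rmax = sim$rmax)
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(k1 = numeric(), k3 = numeric(), predicted = character(),
               simulated = character(), rmax = numeric())
}
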