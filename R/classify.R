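#' Rebound verdicts
#'
#' All classifiers return a `rebound_verdict`: a verdict
#' (`"rebound"`, `"no_rebound"` or `"indeterminate"`), whether the
#' result is generic (holds for all trajectories outside a measure-zero
#' exceptional set), a region label, the theorem the decision rests on,
#' and the numeric thresholds that were compared.  The full-model
#' classifier never returns `"no_rebound"`: outside the intervals where
#' rebound is proven the theory is silent, and such cells are reported
#' as indeterminate (optionally resolved by simulation).
#'
#' @name rebound_verdict
#' @keywords internal
NULL

new_verdict <- function(verdict, region, theorem, thresholds,
                        generic = FALSE) {
  structure(list(verdict = verdict, generic = generic, region = region,
                 theorem = theorem, thresholds = thresholds),
            class = "rebound_verdict")
}

#' @export
print.rebound_verdict <- function(x, ...) {
  cat("<rebound_verdict>", x$verdict,
      if (x$generic) "(generic)", "\n")
  cat("  region: ", x$region, "\n  basis:  ", x$theorem, "\n", sep = "")
  invisible(x)
}

# relative-tolerance tie detection for boundary handling
.near <- function(a, b, tol = 1e-12) {
  abs(a - b) <= tol * max(abs(a), abs(b), 1e-300)
}

#' Rebound classification without feedback
#'
#' In the basic TMDD model rebound occurs if and only if the complex is
#' eliminated more slowly than both the ligand and the receptor:
#' \eqn{k_4 < k_1} and \eqn{k_4 < k_3} (dimensionally
#' \eqn{k_\mathrm{e(P)} < k_\mathrm{e(L)}} and
#' \eqn{k_\mathrm{e(P)} < k_\mathrm{out}}).  The condition is an iff, so
#' the verdict is never indeterminate; the inequalities are strict.
#'
#' @param k1,k3,k4 dimensionless rate constants, `> 0`.
#' @return A `rebound_verdict`.
#' @export
classify_nofeedback <- function(k1, k3, k4) {
  thr <- list(k1 = k1, k3 = k3, k4 = k4)
  if (k4 < k1 && k4 < k3)
    new_verdict("rebound", "no-feedback: k4 < min(k1, k3)",
                "elimination-rate iff (no feedback)", thr, generic = TRUE)
  else
    new_verdict("no_rebound", "no-feedback: k4 >= k1 or k4 >= k3",
                "elimination-rate iff (no feedback)", thr)
}

#' Rebound classification under direct feedback
#'
#' Applies the direct-feedback (quasi-equilibrium) rebound theorem with
#' the secant bounds `m`, `M` of the feedback function:
#'
#' * no rebound if \eqn{k_1 \le k_4}, or if \eqn{k_1 > k_4} and
#'   \eqn{k_3 \le k_4/(1+M)};
#' * rebound if \eqn{k_1 > k_4} and
#'   \eqn{k_3 > \min(k_4/(1+m),\, -\lambda_1/(1+h_0))} (the boundary
#'   line \eqn{k_3 = -\lambda_1/(1+h_0)} with \eqn{k_3 > k_4/(1+m)} is
#'   itself a rebound case);
#' * otherwise indeterminate (outcome depends on the particular
#'   feedback function).
#'
#' For a mainly linear function \eqn{m = M = h_0}, the indeterminate
#' band is empty, and the verdict is the iff: rebound exactly when
#' \eqn{k_4 < k_1} and \eqn{k_4 < k_3(1+h_0)}.
#'
#' @param k1,k2,k3,k4 dimensionless rate constants, `> 0`.
#' @param bounds a [secant_bounds()] object from the actual feedback
#'   function (fields `m`, `M`, `h0`).
#' @return A `rebound_verdict`.
#' @export
classify_direct <- function(k1, k2, k3, k4, bounds) {
  m <- bounds$m; M <- bounds$M; h0 <- bounds$h0
  l1 <- lambda12(k1, k2, k4)[["lambda1"]]
  thr <- list(k1 = k1, k4 = k4, k3 = k3, lambda1 = l1,
              k4_over_1M = k4 / (1 + M), k4_over_1m = k4 / (1 + m),
              ml1_over_1h0 = -l1 / (1 + h0), m = m, M = M, h0 = h0)
  linear <- .near(m, M) && .near(m, h0)

  if (k1 <= k4)
    return(new_verdict("no_rebound", "direct: k1 <= k4",
                       "direct feedback, slow-ligand region", thr))
  if (linear) {
    if (k4 < k3 * (1 + h0))
      return(new_verdict("rebound", "direct mainly-linear: k4 < k3(1+h0)",
                         "mainly linear feedback iff", thr, generic = TRUE))
    return(new_verdict("no_rebound", "direct mainly-linear: k4 >= k3(1+h0)",
                       "mainly linear feedback iff", thr))
  }
  if (k3 <= thr$k4_over_1M)
    return(new_verdict("no_rebound", "direct: k3 <= k4/(1+M)",
                       "direct feedback, bounded total receptor", thr))
  rb_cut <- min(thr$k4_over_1m, thr$ml1_over_1h0)
  if (k3 > rb_cut ||
      (.near(k3, thr$ml1_over_1h0) && k3 > thr$k4_over_1m))
    return(new_verdict("rebound",
                       "direct: k1 > k4 and k3 > min(k4/(1+m), -lambda1/(1+h0))",
                       "direct feedback, general h", thr, generic = TRUE))
  new_verdict("indeterminate",
              "direct: k4/(1+M) < k3 <= min(k4/(1+m), -lambda1/(1+h0))",
              "direct feedback: no general result in this band", thr)
}

#' Rebound classification for the full feedback-moderator model
#'
#' Implements the final rebound summary for the model with a dynamic
#' feedback moderator.  The decision is organised by the position of
#' \eqn{\lambda_1} relative to the landmarks
#' \eqn{\lambda_*^- > \lambda_\infty > \lambda_*^+} of the
#' receptor--moderator block (rows) and by the column
#' \eqn{k_1 \le k_4} / \eqn{k_1 > k_4}:
#'
#' | row | \eqn{k_1 \le k_4} | \eqn{k_1 > k_4} |
#' |---|---|---|
#' | \eqn{\lambda_*^- \le \lambda_1 < 0} | \eqn{0<\epsilon<-\lambda_1} | all \eqn{\epsilon>0} |
#' | \eqn{\lambda_\infty \le \lambda_1 \le \lambda_*^-} | \eqn{0<\epsilon<\epsilon_3}, or \eqn{0<\epsilon<-\lambda_1} if \eqn{\lambda_1>-k_3} | all \eqn{\epsilon>0} |
#' | \eqn{\lambda_*^+ \le \lambda_1 < \lambda_\infty} | \eqn{0<\epsilon<\epsilon_3} | \eqn{0<\epsilon<\epsilon_2}, or all \eqn{\epsilon>0} if \eqn{k_3>k_4/(1+m)} |
#' | \eqn{\lambda_1 < \lambda_*^+} | \eqn{0<\epsilon<\epsilon_1^+}, or all \eqn{\epsilon>0} if \eqn{k_3>k_4/(1+m)} | same |
#'
#' Inside the listed interval the verdict is `"rebound"` with
#' `generic = TRUE`; everywhere else it is `"indeterminate"` — the
#' theory proves no absence-of-rebound result for finite positive
#' feedback speed.  Boundary collisions (\eqn{\epsilon = \epsilon_2},
#' the triple point \eqn{\lambda_1 = \lambda_*^-}) are rebound cases
#' and are detected with relative tolerance 1e-12.
#'
#' @param k1,k2,k3,k4 dimensionless rate constants, `> 0`.
#' @param h0 feedback slope at baseline, `>= 0`.
#' @param m secant-slope infimum of the feedback function.
#' @param eps dimensionless feedback response speed, `> 0`.
#' @return A `rebound_verdict`.
#' @export
classify_full <- function(k1, k2, k3, k4, h0, m, eps) {
  if (eps <= 0) stop("'eps' must be > 0 (use classify_nofeedback for eps = 0)")
  l1 <- lambda12(k1, k2, k4)[["lambda1"]]
  th <- eps_thresholds(k3, h0, lambda1 = l1)
  thr <- c(list(k1 = k1, k3 = k3, k4 = k4, eps = eps, m = m, h0 = h0),
           th[c("eps1_minus", "eps1_plus", "eps2", "eps3",
                "lambda_star_minus", "lambda_star_plus", "lambda_inf")],
           list(lambda1 = l1))
  k1_col <- k1 > k4
  big_k3 <- k3 > k4 / (1 + m)

  row <- if (l1 >= th$lambda_star_minus) "lambda*- <= lambda1 < 0"
         else if (l1 >= th$lambda_inf) "lambda_inf <= lambda1 <= lambda*-"
         else if (l1 >= th$lambda_star_plus) "lambda*+ <= lambda1 < lambda_inf"
         else "lambda1 < lambda*+"

  all_eps <- FALSE
  upper <- NA_real_
  on_boundary_rebound <- FALSE
  if (row == "lambda*- <= lambda1 < 0") {
    if (k1_col) all_eps <- TRUE
    else {
      upper <- -l1
      # eps = eps2 (< -lambda1 here) is a proven collision rebound case
      on_boundary_rebound <- th$eps2_defined && .near(eps, th$eps2, 1e-9)
    }
  } else if (row == "lambda_inf <= lambda1 <= lambda*-") {
    if (k1_col) all_eps <- TRUE
    else {
      upper <- if (l1 > -k3) -l1 else th$eps3
      on_boundary_rebound <- .near(eps, th$eps3, 1e-9) && k3 > -l1
    }
  } else if (row == "lambda*+ <= lambda1 < lambda_inf") {
    if (k1_col) {
      if (big_k3) all_eps <- TRUE
      else {
        upper <- if (isTRUE(th$eps2_defined)) th$eps2 else Inf
        on_boundary_rebound <- .near(eps, th$eps3, 1e-9)
      }
    } else upper <- th$eps3
  } else {
    if (big_k3) all_eps <- TRUE else upper <- th$eps1_plus
  }

  if (all_eps || (!is.na(upper) && eps < upper) || on_boundary_rebound)
    return(new_verdict("rebound",
                       paste0("full: row ", row, ", ",
                              if (k1_col) "k1 > k4" else "k1 <= k4"),
                       "full feedback model, slow-moderator rebound",
                       thr, generic = TRUE))
  new_verdict("indeterminate",
              paste0("full: row ", row, ", eps outside proven interval"),
              "full feedback model: no result proven for this eps",
              thr)
}

#' Rebound classification for generalised models
#'
#' For multi-compartment TMDD models whose pharmacokinetic (PK) block
#' decouples from the receptor--moderator pair, and for general
#' moderator dynamics \eqn{\dot w = \epsilon\, g(y, w)} with
#' \eqn{g_1 = -\partial g/\partial y(1,1) > 0} and
#' \eqn{g_2 = -\partial g/\partial w(1,1) > 0}, rebound occurs
#' generically for \eqn{0 < \epsilon < \tilde\epsilon_0
#' = \min(\epsilon_1^-, \tilde\epsilon_2)} where
#' \deqn{\epsilon_1^- = \frac{k_3}{g_2^2}\Big(2g_1 + g_2 -
#'   \sqrt{4 g_1 (g_1+g_2)}\Big)}
#' is the eigenvalue-collision speed of the moderator block and
#' \eqn{\tilde\epsilon_2} is the speed at which the moderator-block
#' eigenvalue nearest zero crosses the leading PK-block eigenvalue.
#' For linear moderator dynamics \eqn{g(y,w) = h(y) - w} one has
#' \eqn{(g_1, g_2) = (h_0, 1)} and the threshold reduces to the
#' standard \eqn{\epsilon_1^-}.
#'
#' @param pk_leading leading (closest-to-zero) eigenvalue of the PK
#'   block, strictly negative, on the same dimensionless scale as `k3`.
#' @param k3 dimensionless receptor turnover rate.
#' @param g1,g2 moderator-dynamics slopes at baseline (both `> 0`);
#'   pass `g1 = h0`, `g2 = 1` for linear moderator dynamics.
#' @param eps dimensionless feedback response speed, `> 0`.
#' @return A `rebound_verdict`; `"rebound"` (generic) when
#'   \eqn{0 < \epsilon < \tilde\epsilon_0}, `"indeterminate"` otherwise.
#' @export
classify_generalized <- function(pk_leading, k3, g1, g2 = 1, eps) {
  if (!is.finite(g2) || g2 <= 0 || !is.finite(g1) || g1 <= 0)
    stop("assumption violation: g1 and g2 must be strictly positive")
  if (!is.finite(pk_leading) || pk_leading >= 0)
    stop("leading PK-block eigenvalue must be strictly negative")
  eps1m <- k3 / g2^2 * (2 * g1 + g2 - sqrt(4 * g1 * (g1 + g2)))
  # moderator-block eigenvalue nearest zero crosses pk_leading at
  # eps2t, from the characteristic polynomial
  # lambda^2 + (k3 + eps*g2)*lambda + eps*k3*(g1+g2) = 0
  lp <- pk_leading
  den <- g2 * lp + k3 * (g1 + g2)
  eps2t <- if (abs(den) <= 1e-300) Inf else -lp * (lp + k3) / den
  if (!is.finite(eps2t) || eps2t <= 0) eps2t <- Inf
  eps0 <- min(eps1m, eps2t)
  thr <- list(eps = eps, eps1_minus = eps1m, eps2_tilde = eps2t,
              eps0 = eps0, pk_leading = lp, k3 = k3, g1 = g1, g2 = g2)
  if (eps > 0 && eps < eps0)
    new_verdict("rebound", "generalised: 0 < eps < min(eps1-, eps2~)",
                "generalised slow-moderator rebound", thr, generic = TRUE)
  else
    new_verdict("indeterminate",
                "generalised: eps outside proven slow-feedback interval",
                "generalised model: no result proven for this eps", thr)
}

#' Verdict grid over the elimination-rate plane
#'
#' Classifies every cell of a grid in the
#' \eqn{(k_\mathrm{e(L)}, k_\mathrm{out})} plane, holding
#' \eqn{k_\mathrm{e(P)}}, \eqn{k_\mathrm{on}}, \eqn{k_\mathrm{off}} and
#' \eqn{R_0} fixed, using the no-feedback, direct-feedback, or
#' full-model classifier according to the arguments supplied.  The
#' theoretical boundary lines are attached as the `"boundaries"`
#' attribute for plotting overlays.
#'
#' @param keL,kout numeric vectors of grid coordinates (1/time).
#' @param keP,kon,koff,R0 fixed dimensional constants.
#' @param feedback optional [feedback_fn()]; omit for the no-feedback
#'   classifier.
#' @param alpha optional feedback response speed (1/time); omit (or
#'   `Inf`) for the direct-feedback classifier.
#' @return Data frame with columns `keL`, `kout`, `verdict`, `region`,
#'   `generic`, one row per grid cell.
#' @export
region_grid <- function(keL, kout, keP, kon, koff, R0,
                        feedback = NULL, alpha = NULL) {
  stopifnot(all(keL > 0), all(kout > 0), keP > 0, kon > 0, koff > 0, R0 > 0)
  s <- kon * R0
  bounds <- if (!is.null(feedback)) secant_bounds(feedback)
  grid <- expand.grid(keL = keL, kout = kout, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    k1 <- grid$keL[i] / s; k3 <- grid$kout[i] / s
    k2 <- koff / s; k4 <- keP / s
    if (is.null(feedback))
      classify_nofeedback(k1, k3, k4)
    else if (is.null(alpha) || !is.finite(alpha))
      classify_direct(k1, k2, k3, k4, bounds)
    else
      classify_full(k1, k2, k3, k4, bounds$h0, bounds$m, alpha / s)
  })
  out <- data.frame(grid,
                    verdict = vapply(res, function(v) v$verdict, ""),
                    region = vapply(res, function(v) v$region, ""),
                    generic = vapply(res, function(v) v$generic, TRUE),
                    stringsAsFactors = FALSE)
  b <- list(keL_eq_keP = keP, kout_eq_keP = keP)
  if (!is.null(feedback)) {
    b$kout_eq_keP_over_1h0 <- keP / (1 + bounds$h0)
    b$kout_eq_keP_over_1M <- keP / (1 + bounds$M)
    b$kout_eq_keP_over_1m <- keP / (1 + bounds$m)
  }
  attr(out, "boundaries") <- b
  out
}
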