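#' Eigenvalues of the ligand--complex block
#'
#' The baseline linearisation of the TMDD model splits into a
#' ligand--complex block (states `x`, `z`) and a receptor(--moderator)
#' block.  The ligand--complex eigenvalues are
#' \deqn{\lambda_{1,2} = \tfrac12\Big(-(1+k_1+k_2+k_4) \pm
#'   \sqrt{(1+k_1-k_2-k_4)^2 + 4k_2}\Big),}
#' both real with \eqn{\lambda_2 < \lambda_1 < 0}.  They do not depend
#' on \eqn{k_3} or the feedback.
#'
#' @param k1,k2,k4 dimensionless rate constants, `> 0`.
#' @return Named vector `c(lambda1, lambda2)`.
#' @export
lambda12 <- function(k1, k2, k4) {
  disc <- sqrt((1 + k1 - k2 - k4)^2 + 4 * k2)
  s <- -(1 + k1 + k2 + k4)
  c(lambda1 = (s + disc) / 2, lambda2 = (s - disc) / 2)
}

#' Receptor eigenvalue under direct feedback
#'
#' With the quasi-equilibrium (direct) feedback the receptor block is
#' scalar and its eigenvalue is \eqn{\lambda_3 = -k_3(1 + h_0)}; this
#' also equals the fast-feedback limit \eqn{\lambda_\infty} of the
#' moderator model's \eqn{\lambda_4}.
#'
#' @param k3 dimensionless receptor turnover rate, `> 0`.
#' @param h0 feedback slope at baseline, `>= 0`.
#' @return The single real eigenvalue.
#' @export
lambda34_direct <- function(k3, h0) -k3 * (1 + h0)

#' Receptor--moderator eigenvalues of the full feedback model
#'
#' Eigenvalues of the 2x2 block
#' \eqn{J_0 = \bigl(\begin{smallmatrix} -k_3 & k_3 \\
#' -\epsilon h_0 & -\epsilon \end{smallmatrix}\bigr)}:
#' \deqn{\lambda_{3,4} = \tfrac12\Big(-(k_3+\epsilon) \mp
#'   \sqrt{(k_3-\epsilon)^2 - 4\epsilon k_3 h_0}\Big).}
#' They are real for \eqn{\epsilon \le \epsilon_1^-} or
#' \eqn{\epsilon \ge \epsilon_1^+} and a complex-conjugate pair with
#' real part \eqn{-(k_3+\epsilon)/2} in between.
#'
#' @param k3 dimensionless receptor turnover rate, `> 0`.
#' @param h0 feedback slope at baseline, `>= 0`.
#' @param eps dimensionless feedback response speed, `>= 0`.
#' @return List with `lambda3`, `lambda4` (complex when the
#'   discriminant is negative), `discriminant`, and logical `real`.
#'   `Re(lambda3) <= Re(lambda4)`.
#' @export
lambda34_full <- function(k3, h0, eps) {
  D <- (k3 - eps)^2 - 4 * eps * k3 * h0
  if (D >= 0) {
    r <- sqrt(D)
    list(lambda3 = (-(k3 + eps) - r) / 2,
         lambda4 = (-(k3 + eps) + r) / 2,
         discriminant = D, real = TRUE)
  } else {
    r <- sqrt(-D)
    list(lambda3 = complex(real = -(k3 + eps) / 2, imaginary = -r / 2),
         lambda4 = complex(real = -(k3 + eps) / 2, imaginary = r / 2),
         discriminant = D, real = FALSE)
  }
}

#' Feedback-speed thresholds and landmark eigenvalues
#'
#' Computes the feedback-speed thresholds governing the movement of the
#' receptor--moderator eigenvalues and their position relative to the
#' ligand--complex eigenvalue \eqn{\lambda_1}:
#'
#' * `eps1_minus`, `eps1_plus`: speeds at which \eqn{\lambda_3,\lambda_4}
#'   collide, \eqn{\epsilon_1^\pm = k_3(1 + 2h_0 \pm \sqrt{4h_0(1+h_0)})};
#' * `lambda_star_minus`, `lambda_star_plus`: the collision eigenvalues
#'   \eqn{\lambda_*^\pm = -k_3(1 + h_0 \pm \sqrt{h_0(1+h_0)})};
#' * `lambda_inf`: the fast-feedback limit \eqn{-k_3(1+h_0)}
#'   (so \eqn{\lambda_*^+ < \lambda_\infty < \lambda_*^-});
#' * `f_star_plus`: \eqn{f_*^+(h_0) = 1 + h_0 + \sqrt{h_0(1+h_0)}}, so
#'   that \eqn{\lambda_*^+ = -k_3 f_*^+};
#' * when `lambda1` is given: `eps2`, the speed at which the real
#'   eigenvalue \eqn{\lambda_4} crosses \eqn{\lambda_1},
#'   \eqn{\epsilon_2 = -\lambda_1(\lambda_1+k_3)/(\lambda_1-\lambda_\infty)}
#'   (`NA` with `eps2_defined = FALSE` at the pole
#'   \eqn{\lambda_1 = \lambda_\infty}, where \eqn{\epsilon_2 \to \infty}),
#'   and `eps3`, the speed at which the complex pair's real part
#'   crosses \eqn{\lambda_1}, \eqn{\epsilon_3 = -(k_3 + 2\lambda_1)}.
#'
#' @param k3 dimensionless receptor turnover rate, `> 0`.
#' @param h0 feedback slope at baseline, `>= 0`.
#' @param lambda1 optional ligand--complex leading eigenvalue (`< 0`).
#' @return Named list of thresholds.
#' @export
eps_thresholds <- function(k3, h0, lambda1 = NULL) {
  root <- sqrt(4 * h0 * (1 + h0))
  out <- list(
    eps1_minus = k3 * (1 + 2 * h0 - root),
    eps1_plus = k3 * (1 + 2 * h0 + root),
    lambda_star_minus = -k3 * (1 + h0 - root / 2),
    lambda_star_plus = -k3 * (1 + h0 + root / 2),
    lambda_inf = -k3 * (1 + h0),
    f_star_plus = 1 + h0 + root / 2)
  if (!is.null(lambda1)) {
    den <- lambda1 - out$lambda_inf
    if (abs(den) <= 1e-12 * max(abs(lambda1), abs(out$lambda_inf))) {
      out$eps2 <- NA_real_
      out$eps2_defined <- FALSE
    } else {
      out$eps2 <- -lambda1 * (lambda1 + k3) / den
      out$eps2_defined <- TRUE
    }
    out$eps3 <- -(k3 + 2 * lambda1)
    out$lambda1 <- lambda1
  }
  out
}

#' Baseline Jacobian of the TMDD models
#'
#' The Jacobian of the dimensionless equations at the globally stable
#' baseline state, in the fixed `(x, z, y, w)` state ordering.  For the
#' full model this is the 4x4 matrix
#' \deqn{\begin{pmatrix} -(k_1+1) & \mu k_2 & 0 & 0 \\
#'   1/\mu & -(k_2+k_4) & 0 & 0 \\
#'   -1/\mu & k_2 & -k_3 & k_3 \\
#'   0 & 0 & -\epsilon h_0 & -\epsilon \end{pmatrix},}
#' block lower-triangular in the (x,z)/(y,w) split; for the basic and
#' direct models the 3x3 matrix with receptor diagonal entry
#' \eqn{-k_3(1+h_0)} (with \eqn{h_0 = 0} for the basic model).
#'
#' @param model `"basic"`, `"direct"` or `"full"`.
#' @param q a `tmdd_ndim` parameter list (needs `eps` for the full
#'   model).
#' @param h0 feedback slope at baseline.
#' @return Numeric matrix with dimnames in state order.
#' @export
jacobian_at_baseline <- function(model = c("basic", "direct", "full"),
                                 q, h0 = 0) {
  model <- match.arg(model)
  if (model == "basic") h0 <- 0
  if (model %in% c("basic", "direct")) {
    J <- matrix(c(-(q$k1 + 1), q$mu * q$k2, 0,
                  1 / q$mu, -(q$k2 + q$k4), 0,
                  -1 / q$mu, q$k2, -q$k3 * (1 + h0)),
                3, 3, byrow = TRUE,
                dimnames = list(c("x", "z", "y"), c("x", "z", "y")))
  } else {
    eps <- q$eps
    J <- matrix(c(-(q$k1 + 1), q$mu * q$k2, 0, 0,
                  1 / q$mu, -(q$k2 + q$k4), 0, 0,
                  -1 / q$mu, q$k2, -q$k3, q$k3,
                  0, 0, -eps * h0, -eps),
                4, 4, byrow = TRUE,
                dimnames = list(c("x", "z", "y", "w"),
                                c("x", "z", "y", "w")))
  }
  J
}

#' Spectral summary of the baseline linearisation
#'
#' Gathers the closed-form eigenvalues of the baseline Jacobian, the
#' feedback-speed thresholds, and an assessment of which eigenvalue
#' (real part) lies closest to zero — the one that generically governs
#' the final approach to baseline and hence rebound.
#'
#' @param q a `tmdd_ndim` parameter list.
#' @param h0 feedback slope at baseline.
#' @param model `"basic"`, `"direct"` or `"full"`.
#' @return List of class `spectral_summary`.
#' @export
spectral_summary <- function(q, h0 = 0, model = c("full", "direct", "basic")) {
  model <- match.arg(model)
  l12 <- lambda12(q$k1, q$k2, q$k4)
  out <- list(model = model,
              lambda1 = l12[["lambda1"]], lambda2 = l12[["lambda2"]],
              h0 = h0)
  if (model == "basic") h0 <- 0
  if (model %in% c("basic", "direct")) {
    out$lambda3 <- lambda34_direct(q$k3, h0)
    out$lambda4 <- NA_real_
    out$real34 <- TRUE
    slow <- max(out$lambda1, out$lambda3)
  } else {
    l34 <- lambda34_full(q$k3, h0, q$eps)
    out$lambda3 <- l34$lambda3
    out$lambda4 <- l34$lambda4
    out$discriminant <- l34$discriminant
    out$real34 <- l34$real
    slow <- max(out$lambda1, Re(l34$lambda4))
  }
  out <- c(out, eps_thresholds(q$k3, h0, lambda1 = out$lambda1))
  out$slowest_rate <- -slow
  class(out) <- "spectral_summary"
  out
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> model:", x$model, "\n")
  cat("  lambda1 =", format(x$lambda1), " lambda2 =", format(x$lambda2), "\n")
  cat("  lambda3 =", format(x$lambda3), " lambda4 =", format(x$lambda4),
      if (isFALSE(x$real34)) " (complex pair)", "\n")
  cat("  eps1- =", format(x$eps1_minus), " eps1+ =", format(x$eps1_plus),
      " eps2 =", format(x$eps2), " eps3 =", format(x$eps3), "\n")
  cat("  lambda_inf =", format(x$lambda_inf),
      " lambda*- =", format(x$lambda_star_minus),
      " lambda*+ =", format(x$lambda_star_plus), "\n")
  invisible(x)
}

#' Printed eigenvector formulas of the baseline Jacobian
#'
#' Returns the closed-form eigenvectors associated with the baseline
#' Jacobian, in state order, for cross-checking against a numeric
#' eigendecomposition.  For the 3-state (direct) model the
#' ligand--complex eigenvectors are
#' \eqn{(\mu(\lambda_i + k_3(1+h_0))(k_2+k_4+\lambda_i),\;
#' \lambda_i + k_3(1+h_0),\; -(\lambda_i + k_4))}; for the 4-state
#' model the moderator-block eigenvectors are
#' \eqn{(0, 0, k_3, k_3 + \lambda_i)}.
#'
#' @param model `"direct"` or `"full"`.
#' @param q a `tmdd_ndim` list.
#' @param h0 feedback slope at baseline.
#' @return Matrix whose columns are the (unnormalised) eigenvectors,
#'   ordered \eqn{\lambda_1, \lambda_2, \lambda_3(,\lambda_4)}.
#' @export
eigenvectors_at_baseline <- function(model = c("direct", "full"), q, h0) {
  model <- match.arg(model)
  l12 <- lambda12(q$k1, q$k2, q$k4)
  if (model == "direct") {
    l3 <- lambda34_direct(q$k3, h0)
    v <- function(li) c(q$mu * (li + q$k3 * (1 + h0)) * (q$k2 + q$k4 + li),
                        li + q$k3 * (1 + h0),
                        -(li + q$k4))
    cbind(v(l12[["lambda1"]]), v(l12[["lambda2"]]), c(0, 0, 1))
  } else {
    l34 <- lambda34_full(q$k3, h0, q$eps)
    eps <- q$eps
    v12 <- function(li) {
      den <- (q$k3 + li) * (eps + li) + eps * q$k3 * h0
      c(q$mu * (q$k2 + q$k4 + li), 1,
        -(q$k4 + li) * (eps + li) / den,
        eps * h0 * (q$k4 + li) / den)
    }
    v34 <- function(li) c(0, 0, q$k3, q$k3 + li)
    cbind(v12(l12[["lambda1"]]), v12(l12[["lambda2"]]),
          v34(l34$lambda3), v34(l34$lambda4))
  }
}
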