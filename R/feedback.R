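#' Feedback functions for receptor synthesis
#'
#' A `feedback_fn` represents the dimensionless homeostatic feedback
#' function \eqn{h(y)} that modulates the receptor synthesis rate: the
#' production term of the receptor equation is \eqn{k_3 h(y)} (or
#' \eqn{k_\mathrm{in} H(R)} in dimensional form, with
#' \eqn{h(y) = H(R_0 y)}).  Every valid feedback function satisfies
#'
#' * (h1) \eqn{h(y) > 0} for all \eqn{y \ge 0},
#' * (h2) \eqn{h(1) = 1} (the baseline is preserved),
#' * (h3) \eqn{h(y) > 1} on \eqn{[0,1)} and \eqn{0 < h(y) < 1} on
#'   \eqn{(1,\infty)} (negative feedback),
#' * (h4) \eqn{h \in C^2([0,\infty))}.
#'
#' The slope at baseline \eqn{h_0 = -h'(1) \ge 0} is the key scalar: it
#' enters every eigenvalue and rebound threshold.
#'
#' @param evaluate function of `y` returning \eqn{h(y)}; must be
#'   vectorised.
#' @param derivative function of `y` returning \eqn{h'(y)}.
#' @param family character label, one of `"constant"`,
#'   `"mainly_linear"`, `"hyperbolic"`, `"custom"`.
#' @param params named list of family-specific constants.
#' @param h0 value of \eqn{-h'(1)}; computed from `derivative` when
#'   omitted.
#' @return An object of class `feedback_fn`.
#' @seealso [make_constant()], [make_mainly_linear()],
#'   [make_hyperbolic()], [validate_feedback()], [secant_bounds()]
#' @export
feedback_fn <- function(evaluate, derivative, family = "custom",
                        params = list(), h0 = NULL) {
  stopifnot(is.function(evaluate), is.function(derivative))
  family <- match.arg(family,
                      c("constant", "mainly_linear", "hyperbolic", "custom"))
  if (is.null(h0)) h0 <- -derivative(1)
  structure(list(evaluate = evaluate, derivative = derivative,
                 family = family, params = params, h0 = h0),
            class = "feedback_fn")
}

#' @export
print.feedback_fn <- function(x, ...) {
  cat("<feedback_fn> family:", x$family, "\n")
  cat("  h0 = -h'(1) =", format(x$h0), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' No-feedback (constant) function
#'
#' Returns \eqn{h \equiv 1}, the declared no-feedback case to which the
#' model reduces when the feedback response speed is zero.  Assumption
#' (h3) holds only as equalities, which the validator treats as
#' acceptable for this family.
#'
#' @return A `feedback_fn` with \eqn{h(y)=1}, \eqn{h'(y)=0},
#'   \eqn{h_0=0}.
#' @export
make_constant <- function() {
  feedback_fn(function(y) rep(1, length(y)),
              function(y) rep(0, length(y)),
              family = "constant", h0 = 0)
}

#' Mainly linear feedback function
#'
#' The piecewise feedback function that is exactly linear,
#' \eqn{h(y) = 1 + h_0(1-y)}, on \eqn{[0,\, 1+\beta/h_0]} and continues
#' with a smooth bounded tail for larger `y`.  At the junction
#' \eqn{y_\beta = 1+\beta/h_0} the linear branch has value
#' \eqn{1-\beta}; the tail matches its value, its slope \eqn{-h_0} and a
#' zero second derivative there, and stays strictly inside \eqn{(0,1)}.
#'
#' The tail used here is
#' \deqn{h_1(y_\beta + s) = (1-\beta) - h_0\,\sigma\,\tanh(s/\sigma),
#'   \qquad \sigma = (1-\beta)/(2 h_0),}
#' which is \eqn{C^\infty}, matches all three junction conditions, and
#' takes values in \eqn{((1-\beta)/2,\, 1-\beta]}.
#'
#' @param h0 baseline slope \eqn{-h'(1)}, dimensionless, `> 0`.
#' @param beta kink offset, dimensionless, in `(0, 1)`; the linear
#'   branch extends to \eqn{y = 1 + \beta/h_0}.
#' @return A `feedback_fn` of family `"mainly_linear"`.
#' @examples
#' h <- make_mainly_linear(h0 = 1, beta = 0.5)
#' h$evaluate(c(0, 1, 1.5))   # 2, 1, 0.5
#' @export
make_mainly_linear <- function(h0, beta) {
  if (!is.numeric(h0) || length(h0) != 1L || !is.finite(h0) || h0 <= 0)
    stop("'h0' must be a single finite value > 0")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must lie strictly in (0, 1)")
  yk <- 1 + beta / h0
  sigma <- (1 - beta) / (2 * h0)
  ev <- function(y) {
    ifelse(y <= yk,
           1 + h0 * (1 - y),
           (1 - beta) - h0 * sigma * tanh((y - yk) / sigma))
  }
  dv <- function(y) {
    ifelse(y <= yk, -h0,
           -h0 / cosh((y - yk) / sigma)^2)
  }
  feedback_fn(ev, dv, family = "mainly_linear",
              params = list(h0 = h0, beta = beta), h0 = h0)
}

#' Hyperbolic feedback function
#'
#' The rational feedback function
#' \deqn{h(y) = \frac{1}{F^0 + (1-F^0)\,y}, \qquad F^0 \in (0,1),}
#' which arises from Michaelis--Menten-type moderator kinetics (it is
#' the dimensionless form of the %CD11a production feedback in the
#' efalizumab/psoriasis model).  Its baseline slope is
#' \eqn{h_0 = 1 - F^0}.
#'
#' @param F0 dimensionless asymptote parameter in `(0, 1)`;
#'   \eqn{h(y) \to 1/F^0} as \eqn{y \to 0} and \eqn{h \to 0} as
#'   \eqn{y \to \infty}... the baseline fraction of maximal synthesis.
#' @return A `feedback_fn` of family `"hyperbolic"`.
#' @export
make_hyperbolic <- function(F0) {
  if (!is.numeric(F0) || length(F0) != 1L || F0 <= 0 || F0 >= 1)
    stop("'F0' must lie strictly in (0, 1)")
  ev <- function(y) 1 / (F0 + (1 - F0) * y)
  dv <- function(y) -(1 - F0) / (F0 + (1 - F0) * y)^2
  feedback_fn(ev, dv, family = "hyperbolic",
              params = list(F0 = F0), h0 = 1 - F0)
}

#' Check the feedback-function assumptions on a grid
#'
#' Evaluates assumptions (h1)--(h4) at sampled points and reports each
#' as pass/fail with the first violating point.  (h2) is checked to
#' absolute tolerance `1e-12`; (h3) is checked with strict inequalities
#' except at \eqn{y=1}; (h4) is verified by a surrogate: finiteness of
#' `evaluate`/`derivative` on the grid together with agreement of the
#' supplied derivative with a central finite difference.
#'
#' The `"constant"` family (\eqn{h \equiv 1}) is the declared
#' no-feedback case: (h3) holds there only as equalities and is
#' reported as passing with a note.
#'
#' @param h a [feedback_fn()].
#' @param grid increasing sample of `y` values; must cover `[0, y_max]`
#'   with `y_max >= 5`.  Default: 2001 points on `[0, 10]`.
#' @return A data frame with columns `assumption`, `pass`, `detail`,
#'   of class `feedback_validation`; attribute `ok` is `TRUE` when all
#'   four assumptions pass.
#' @export
validate_feedback <- function(h, grid = seq(0, 10, length.out = 2001)) {
  stopifnot(inherits(h, "feedback_fn"))
  if (max(grid) < 5)
    stop("'grid' must extend to y_max >= 5")
  grid <- sort(unique(c(grid, 1)))
  hy <- h$evaluate(grid)
  dy <- h$derivative(grid)

  first_bad <- function(bad) {
    if (any(bad)) sprintf("first violation at y = %.6g", grid[which(bad)[1]])
    else "ok"
  }

  bad1 <- !(hy > 0)
  r1 <- list(pass = !any(bad1), detail = first_bad(bad1))

  d2 <- abs(h$evaluate(1) - 1)
  r2 <- list(pass = d2 <= 1e-12,
             detail = sprintf("|h(1) - 1| = %.3g", d2))

  if (h$family == "constant") {
    r3 <- list(pass = TRUE,
               detail = "h == 1: declared no-feedback case (equalities)")
  } else {
    below <- grid < 1; above <- grid > 1
    bad3 <- (below & !(hy > 1)) | (above & !(hy < 1 & hy > 0))
    r3 <- list(pass = !any(bad3), detail = first_bad(bad3))
  }

  # (h4) surrogate: finite values, and every secant slope between
  # neighbouring grid points lies in the range of h' there (mean value
  # theorem), with slack for the curvature of h' within one cell.
  fin <- is.finite(hy) & is.finite(dy)
  n <- length(grid)
  sec <- diff(hy) / diff(grid)
  dlo <- pmin(dy[-n], dy[-1]); dhi <- pmax(dy[-n], dy[-1])
  slack <- abs(dy[-1] - dy[-n]) + 1e-7 * (1 + pmax(abs(dy[-1]), abs(dy[-n])))
  mvt_ok <- sec >= dlo - slack & sec <= dhi + slack
  bad4 <- !fin | c(!mvt_ok, FALSE) | c(FALSE, !mvt_ok)
  r4 <- list(pass = !any(bad4), detail = first_bad(bad4))

  out <- data.frame(
    assumption = c("h1: h(y) > 0",
                   "h2: h(1) = 1",
                   "h3: sign of h - 1",
                   "h4: smooth C^2 (surrogate)"),
    pass = c(r1$pass, r2$pass, r3$pass, r4$pass),
    detail = c(r1$detail, r2$detail, r3$detail, r4$detail),
    stringsAsFactors = FALSE)
  class(out) <- c("feedback_validation", class(out))
  attr(out, "ok") <- all(out$pass)
  out
}

#' Secant-slope bounds of a feedback function
#'
#' Computes the infimum `m` and supremum `M` of the secant slopes
#' \deqn{\tilde h(y) = \frac{h(y) - 1}{1 - y}, \qquad y \in [0, 1),}
#' with the \eqn{y \to 1} limit taken as \eqn{h_0 = -h'(1)}.  These
#' bound the feedback between two straight lines through (1, 1):
#' \eqn{1 + m(1-y) \le h(y) \le 1 + M(1-y)} on \eqn{[0,1]}, and satisfy
#' \eqn{0 \le m \le h_0 \le M}.
#'
#' Closed forms are used for the packaged families (`m = M = h0` for the
#' mainly linear family; \eqn{m = h_0 = 1-F^0}, \eqn{M = (1-F^0)/F^0}
#' for the hyperbolic family; `m = M = 0` for the constant family).
#' Custom functions are handled by a dense grid on `[0, 1)` with the
#' endpoint limit injected explicitly, followed by bounded local
#' refinement around the grid extrema.
#'
#' @param h a [feedback_fn()].
#' @param n number of grid points for the custom-family fallback.
#' @return A list of class `secant_bounds` with elements `m`, `M`, `h0`.
#' @export
secant_bounds <- function(h, n = 2048) {
  stopifnot(inherits(h, "feedback_fn"))
  out <- switch(
    h$family,
    constant = list(m = 0, M = 0),
    mainly_linear = list(m = h$h0, M = h$h0),
    hyperbolic = {
      F0 <- h$params$F0
      list(m = 1 - F0, M = (1 - F0) / F0)
    },
    { # custom: grid + refinement over the half-open interval
      y <- seq(0, 1, length.out = n + 1)[-(n + 1)]
      s <- (h$evaluate(y) - 1) / (1 - y)
      if (any(!is.finite(s))) stop("non-finite secant slope encountered")
      vals <- c(s, h$h0)
      ht <- function(y) (h$evaluate(y) - 1) / (1 - y)
      refine <- function(i, maximise) {
        lo <- y[max(1, i - 1)]; hi <- min(y[min(length(y), i + 1)], 1 - 1e-9)
        stats::optimize(ht, c(lo, hi), maximum = maximise)[[2]]
      }
      imin <- which.min(s); imax <- which.max(s)
      list(m = min(vals, refine(imin, FALSE)),
           M = max(vals, refine(imax, TRUE)))
    })
  structure(list(m = out$m, M = out$M, h0 = h$h0), class = "secant_bounds")
}

#' @export
print.secant_bounds <- function(x, ...) {
  cat("<secant_bounds> m =", format(x$m), " h0 =", format(x$h0),
      " M =", format(x$M), "\n")
  invisible(x)
}

#' Build a feedback function from a configuration list
#'
#' Maps a feedback specification (as found in run configuration files)
#' to a [feedback_fn()].  For the mainly linear family the slope may be
#' given either dimensionless (`h0`) or dimensional (`H0`, per unit
#' receptor concentration), in which case `R0` is required and
#' \eqn{h_0 = R_0 H_0}.
#'
#' @param spec named list with `family` and family-specific constants.
#' @param R0 baseline receptor level, needed only to convert `H0`.
#' @return A `feedback_fn`.
#' @export
feedback_from_spec <- function(spec, R0 = NULL) {
  if (is.null(spec) || is.null(spec$family))
    stop("feedback spec must contain a 'family' field")
  switch(
    spec$family,
    constant = make_constant(),
    mainly_linear = {
      h0 <- spec$h0
      if (is.null(h0)) {
        if (is.null(spec$H0) || is.null(R0))
          stop("mainly_linear feedback needs 'h0', or 'H0' together with R0")
        h0 <- R0 * spec$H0
      }
      beta <- if (is.null(spec$beta)) 0.5 else spec$beta
      make_mainly_linear(h0, beta)
    },
    hyperbolic = make_hyperbolic(spec$F0),
    stop("unknown feedback family: ", spec$family))
}
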