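#' Integrate a TMDD model variant
#'
#' Solves the dimensionless model equations with an adaptive stiff
#' solver (`deSolve::lsoda`).  The default horizon (`"auto"`) is chosen
#' from the slowest spectral rate at baseline so the trajectory
#' completes the dip--return--(rebound) excursion; `"to_steady_state"`
#' keeps doubling the horizon until the state is within `ss_tol` of the
#' baseline steady state (sup norm) or \eqn{\tau = 10^7} is reached.
#' The output grid is dense near \eqn{\tau = 0} (the dip) and
#' log-spaced afterwards.
#'
#' @param model `"basic"`, `"direct"`, `"full"`, `"receptor_only"` or
#'   `"receptor_moderator"`.
#' @param q a `tmdd_ndim` parameter list (see [nondimensionalize()]).
#' @param h a [feedback_fn()]; required except for `"basic"`.
#' @param ic initial state; defaults to [initial_state()] for the
#'   model.
#' @param horizon `"auto"`, `"to_steady_state"`, or a positive number
#'   (final \eqn{\tau}).
#' @param rtol,atol solver tolerances.
#' @param n_out approximate number of output points.
#' @param ss_tol steady-state tolerance for `"to_steady_state"`.
#' @return A `tmdd_traj`: list with `data` (data frame: `tau`,
#'   optionally `t` in dimensional time, and the state columns),
#'   `model`, `q`, `steady_state`, `solver`.
#' @export
simulate_model <- function(model = c("basic", "direct", "full",
                                     "receptor_only", "receptor_moderator"),
                           q, h = NULL, ic = NULL,
                           horizon = "auto",
                           rtol = 1e-10, atol = 1e-12,
                           n_out = 4000, ss_tol = 1e-10) {
  model <- match.arg(model)
  if (model != "basic" && is.null(h))
    stop("'h' (a feedback_fn) is required for model '", model, "'")
  if (model %in% c("full", "receptor_moderator") &&
      (is.null(q$eps) || q$eps < 0))
    stop("'q$eps' must be >= 0 for the moderator models")
  if (is.null(ic)) ic <- initial_state(model)

  deriv <- switch(model,
    basic = function(t, s, p) list(rhs_basic(s, q)),
    direct = function(t, s, p) list(rhs_direct(s, q, h)),
    full = function(t, s, p) list(rhs_full(s, q, h)),
    receptor_only = function(t, s, p)
      list(c(y = q$k3 * (h$evaluate(s[["y"]]) - s[["y"]]))),
    receptor_moderator = function(t, s, p)
      list(c(y = q$k3 * (s[["w"]] - s[["y"]]),
             w = q$eps * (h$evaluate(s[["y"]]) - s[["w"]]))))

  ss <- switch(model,
               basic = , direct = c(x = 0, z = 0, y = 1),
               full = c(x = 0, z = 0, y = 1, w = 1),
               receptor_only = c(y = 1),
               receptor_moderator = c(y = 1, w = 1))

  h0 <- if (model == "basic" || is.null(h)) 0 else h$h0
  slow_rate <- {
    rates <- q$k3 * (1 + h0)
    if (model %in% c("full", "receptor_moderator") && q$eps > 0) {
      l34 <- lambda34_full(q$k3, h0, q$eps)
      rates <- -Re(l34$lambda4)
    }
    if (model %in% c("basic", "direct", "full"))
      rates <- min(rates, -lambda12(q$k1, q$k2, q$k4)[["lambda1"]])
    max(rates, 1e-12)
  }

  grid_for <- function(tau_end) {
    t1 <- min(50, tau_end / 10)
    fine <- seq(0, t1, length.out = max(200, round(n_out * 0.4)))
    tail <- exp(seq(log(max(t1, 1e-6)), log(tau_end),
                    length.out = max(200, round(n_out * 0.6))))
    sort(unique(c(fine, tail, tau_end)))
  }

  run <- function(tau_end) {
    times <- grid_for(tau_end)
    solve1 <- function(method)
      deSolve::ode(y = ic, times = times, func = deriv, parms = NULL,
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 50000)
    # lsoda occasionally trips over its own dense-output interpolation
    # once the state is numerically at equilibrium; BDF is the fallback
    out <- tryCatch(solve1("lsoda"), error = function(e) NULL)
    if (is.null(out) || attr(out, "istate")[1] < 0)
      out <- solve1("bdf")
    if (attr(out, "istate")[1] < 0)
      stop("integration failed before tau = ", tau_end)
    out
  }

  if (identical(horizon, "to_steady_state")) {
    tau_end <- max(200, 20 / slow_rate)
    repeat {
      out <- run(tau_end)
      final <- out[nrow(out), names(ic)]
      if (max(abs(final - ss[names(ic)])) < ss_tol || tau_end >= 1e7) break
      tau_end <- min(tau_end * 2, 1e7)
    }
  } else {
    tau_end <- if (identical(horizon, "auto"))
      min(max(200, 60 / slow_rate), 1e7) else as.numeric(horizon)
    out <- run(tau_end)
  }

  dat <- as.data.frame(unclass(out))
  names(dat)[1] <- "tau"
  if (!is.null(q$kon) && !is.null(q$R0))
    dat$t <- dat$tau / (q$kon * q$R0)
  low <- vapply(dat[names(ic)], min, 0)
  if (any(low < -1e-6))
    stop("invariant breach: state component fell below -1e-6 (min = ",
         format(min(low)), ")")
  structure(list(data = dat, model = model, q = q,
                 steady_state = ss,
                 solver = list(rtol = rtol, atol = atol,
                               tau_end = tau_end)),
            class = "tmdd_traj")
}

#' @export
print.tmdd_traj <- function(x, ...) {
  cat("<tmdd_traj>", x$model, "model,", nrow(x$data), "points, tau in [0,",
      format(max(x$data$tau)), "]\n")
  invisible(x)
}

#' Detect rebound in a simulated trajectory
#'
#' Rebound means the receptor, in its return to baseline after the
#' post-dose dip, exceeds the baseline level.  Operationally: find the
#' first time the receptor falls below `1 - delta`; rebound is declared
#' when its maximum after that time exceeds `1 + delta`.  The relative
#' threshold `delta` bounds the smallest reportable rebound (the
#' magnitude vanishes as the feedback speed goes to 0 or past the
#' rebound endpoint) and is reported with every result.
#'
#' @param traj a `tmdd_traj` from [simulate_model()], or a data frame
#'   with a time column and the receptor column.
#' @param delta relative detection threshold (default 1e-6).
#' @param var receptor column name (default `"y"`).
#' @param baseline baseline level of `var` (1 in dimensionless form).
#' @return List of class `rebound_result`: `rebound` (logical),
#'   `rmax_over_r0`, `tmax` (time of the post-nadir maximum, in the
#'   trajectory's time unit; dimensional time when available), `nadir`,
#'   `degenerate` (no dip found), `threshold_used`.
#' @export
detect_rebound <- function(traj, delta = 1e-6, var = "y", baseline = 1) {
  dat <- if (inherits(traj, "tmdd_traj")) traj$data else as.data.frame(traj)
  yv <- dat[[var]] / baseline
  tv <- if (!is.null(dat$t)) dat$t else dat[[1]]
  i0 <- which(yv < 1 - delta)[1]
  if (is.na(i0))
    return(structure(list(rebound = FALSE, rmax_over_r0 = max(yv),
                          tmax = NA_real_, nadir = min(yv),
                          degenerate = TRUE, threshold_used = delta),
                     class = "rebound_result"))
  post <- seq(i0, length(yv))
  imax <- post[which.max(yv[post])]
  structure(list(rebound = yv[imax] > 1 + delta,
                 rmax_over_r0 = yv[imax],
                 tmax = tv[imax],
                 nadir = min(yv),
                 degenerate = FALSE,
                 threshold_used = delta),
            class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat("<rebound_result>", if (x$degenerate) "degenerate (no dip);",
      if (x$rebound) "REBOUND" else "no rebound",
      "- Rmax/R0 =", format(x$rmax_over_r0),
      "at t =", format(x$tmax), "\n")
  invisible(x)
}

#' Scan the feedback response speed
#'
#' Simulates the full feedback-moderator model across a range of
#' dimensional feedback speeds \eqn{\alpha} and reports the rebound
#' magnitude \eqn{R_\mathrm{max}/R_0} and its time for each.  With
#' `endpoint = TRUE` the largest \eqn{\alpha} at which rebound is still
#' detected is located by bisection (to absolute tolerance
#' `endpoint_tol`), bracketing on a coarse log-spaced pre-scan first.
#'
#' @param p a [tmdd_params()] object (its `alpha` field is overridden).
#' @param h a [feedback_fn()].
#' @param alphas feedback speeds to tabulate (1/time); default 16
#'   log-spaced points spanning `alpha_range`.
#' @param alpha_range range searched for the rebound endpoint.
#' @param endpoint locate the rebound endpoint by bisection?
#' @param endpoint_tol absolute bisection tolerance on \eqn{\alpha}.
#' @param delta rebound detection threshold (see [detect_rebound()]).
#' @param rtol,atol solver tolerances.
#' @return List of class `alpha_scan`: `table` (data frame `alpha`,
#'   `rmax_over_r0`, `tmax`, `rebound`) and `endpoint` (`NA` when not
#'   requested or not bracketed).
#' @export
scan_alpha <- function(p, h, alphas = NULL,
                       alpha_range = c(1e-3, 1.2),
                       endpoint = TRUE, endpoint_tol = 1e-3,
                       delta = 1e-6, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "tmdd_params"))
  s <- p$kon * p$R0
  if (is.null(alphas))
    alphas <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                      length.out = 16))
  one <- function(alpha) {
    q <- nondimensionalize(tmdd_params(
      kon = p$kon, koff = p$koff, kout = p$kout, keL = p$keL, keP = p$keP,
      L0 = p$L0, alpha = alpha, R0 = p$R0, units = p$units))
    tr <- simulate_model("full", q, h, rtol = rtol, atol = atol)
    detect_rebound(tr, delta = delta)
  }
  res <- lapply(alphas, one)
  tab <- data.frame(alpha = alphas,
                    rmax_over_r0 = vapply(res, `[[`, 0, "rmax_over_r0"),
                    tmax = vapply(res, `[[`, 0, "tmax"),
                    rebound = vapply(res, `[[`, TRUE, "rebound"))
  ep <- NA_real_
  if (endpoint) {
    rb <- tab$rebound
    # bracket: last rebound alpha followed by a no-rebound alpha
    idx <- which(rb[-length(rb)] & !rb[-1])
    if (length(idx)) {
      lo <- tab$alpha[idx[length(idx)]]
      hi <- tab$alpha[idx[length(idx)] + 1]
      while (hi - lo > endpoint_tol) {
        mid <- (lo + hi) / 2
        if (one(mid)$rebound) lo <- mid else hi <- mid
      }
      ep <- (lo + hi) / 2
    } else if (all(rb)) {
      ep <- Inf
    }
  }
  structure(list(table = tab, endpoint = ep, delta = delta),
            class = "alpha_scan")
}

#' @export
print.alpha_scan <- function(x, ...) {
  cat("<alpha_scan>", nrow(x$table), "feedback speeds; rebound endpoint:",
      format(x$endpoint), "\n")
  invisible(x)
}

#' Monitor the model invariants along a trajectory
#'
#' Checks the analytic invariants of the flow on a simulated
#' trajectory:
#'
#' * non-negativity of every state component;
#' * the total-receptor plane bounds: with `bounds` supplied, if
#'   \eqn{k_4 \ge k_3(1+M)} then \eqn{v = y+z \le 1}, and if
#'   \eqn{k_4 \le k_3(1+m)} then \eqn{v \ge 1} (within `tol`);
#' * the moderator-sign property: while \eqn{y \le 1}, the moderator
#'   must satisfy \eqn{w > 1} for \eqn{\tau > 0} — equivalently, if
#'   \eqn{w} ever touches or drops below 1, rebound must follow, so a
#'   `w <= 1` crossing is recorded as a rebound predictor.
#'
#' @param traj a `tmdd_traj`.
#' @param bounds optional [secant_bounds()] for the plane checks.
#' @param tol numeric slack for the plane and negativity checks.
#' @return List of class `invariant_report` with logical flags and the
#'   observed extrema.
#' @export
monitor_invariants <- function(traj, bounds = NULL, tol = 1e-8) {
  stopifnot(inherits(traj, "tmdd_traj"))
  dat <- traj$data
  q <- traj$q
  comp <- intersect(c("x", "z", "y", "w"), names(dat))
  mins <- vapply(dat[comp], min, 0)
  rep <- list(negativity_ok = all(mins >= -1e-9), component_minima = mins)
  if (!is.null(bounds) && all(c("y", "z") %in% comp)) {
    v <- dat$y + dat$z
    rep$v_max <- max(v); rep$v_min <- min(v)
    if (q$k4 >= q$k3 * (1 + bounds$M))
      rep$v_le_1_ok <- max(v) <= 1 + tol
    if (q$k4 <= q$k3 * (1 + bounds$m))
      rep$v_ge_1_ok <- min(v) >= 1 - tol
  }
  if (all(c("y", "w") %in% comp)) {
    pos <- dat$tau > 0
    # up to the first excursion of y above baseline, w must stay > 1
    i_up <- which(dat$y > 1 + 1e-12)[1]
    below1 <- pos & (if (is.na(i_up)) TRUE
                     else seq_len(nrow(dat)) < i_up)
    rep$w_above_1_while_y_below <- all(dat$w[below1] > 1 - 1e-9)
    crossed <- any(pos & dat$w <= 1)
    rep$w_crossed_below_1 <- crossed
    rep$predicts_rebound <- crossed
  }
  class(rep) <- "invariant_report"
  rep
}
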