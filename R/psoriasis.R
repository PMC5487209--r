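#' Efalizumab/psoriasis model parameters
#'
#' Parameter set for the five-state indirect-response model of
#' efalizumab treatment in psoriasis: three pharmacokinetic (PK)
#' compartments (`Xsc` depot, `X1` central, `X2` peripheral; drug
#' amounts in ug/kg), the total %CD11a on the T-cell surface (`X3`),
#' and the %CD11a production rate (`X4`, the feedback moderator).
#'
#' `Kmc03` (the production-feedback Michaelis constant) is not part of
#' the published list; it is derived here by asserting a baseline total
#' %CD11a of `Y0` (100 by default, the natural normalisation for a
#' percentage variable): `F0 = k30*Y0/k03max` must be the positive root
#' of \eqn{k_\mathrm{03max}F^2 + k_{30}K_\mathrm{mc03}F -
#' k_{30}K_\mathrm{mc03} = 0}, giving
#' \eqn{K_\mathrm{mc03} = k_\mathrm{03max}F_0^2/(k_{30}(1-F_0))}.
#'
#' The default `koff = 0.0154`/day is the modified moderator response
#' rate needed to reproduce the published rebound magnitude; the
#' originally reported value 0.00154/day is available as an explicit
#' alternative (it yields a smaller rebound, about 110% of baseline).
#' Note the published binding affinity (0.033 ug/mL, about 200 pM) and
#' the `koff`-implied affinity (about 2 pM at a typical `kon`) are
#' mutually inconsistent; that discrepancy has no computational
#' resolution and is simply inherited with the parameter set.
#'
#' @param ka depot absorption rate (1/day).
#' @param k10,k12,k21 central elimination and distribution rates
#'   (1/day).
#' @param k30 %CD11a turnover rate (1/day).
#' @param koff moderator response rate (1/day).
#' @param Vm,Kmc,Vc Michaelis--Menten drug elimination: maximal rate
#'   (ug/mL/day scale as published), Michaelis constant (ug/mL) and
#'   central volume (mL/kg).
#' @param Vm2 maximal %CD11a removal rate by drug (1/day).
#' @param Fa subcutaneous bioavailability, in (0, 1].
#' @param k03max maximal %CD11a production rate (%CD11a/day).
#' @param Y0 baseline total %CD11a (overridable; 100 by default).
#' @return List of class `psoriasis_params`, including the derived
#'   `F0` and `Kmc03`.
#' @export
psoriasis_params <- function(ka = 0.242, k10 = 0.114, k12 = 0.097,
                             k21 = 0.193, k30 = 0.444, koff = 0.0154,
                             Vm = 26.9, Kmc = 0.033, Vc = 64.3,
                             Vm2 = 2.16, Fa = 0.564, k03max = 334,
                             Y0 = 100) {
  vals <- c(ka = ka, k10 = k10, k12 = k12, k21 = k21, k30 = k30,
            koff = koff, Vm = Vm, Kmc = Kmc, Vc = Vc, Vm2 = Vm2,
            k03max = k03max, Y0 = Y0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates and constants must be strictly positive")
  if (Fa <= 0 || Fa > 1) stop("'Fa' must lie in (0, 1]")
  p <- list(ka = ka, k10 = k10, k12 = k12, k21 = k21, k30 = k30,
            koff = koff, Vm = Vm, Kmc = Kmc, Vc = Vc, Vm2 = Vm2,
            Fa = Fa, k03max = k03max, Y0 = Y0)
  bl <- ng_baseline(p, Y0)
  p$F0 <- bl$F0
  p$Kmc03 <- bl$Kmc03
  class(p) <- "psoriasis_params"
  p
}

#' @export
print.psoriasis_params <- function(x, ...) {
  cat("<psoriasis_params> (day, ug/kg, %CD11a)\n")
  cat("  koff =", x$koff, " Y0 =", x$Y0,
      " F0 =", format(x$F0), " Kmc03 =", format(x$Kmc03), "\n")
  invisible(x)
}

#' Drug-free baseline of the %CD11a feedback loop
#'
#' Computes the baseline moderator fraction
#' \eqn{F_0 = k_{30} Y_0 / k_\mathrm{03max}} and the feedback Michaelis
#' constant \eqn{K_\mathrm{mc03}} that makes \eqn{F_0} the positive
#' root of the baseline quadratic
#' \eqn{k_\mathrm{03max}F^2 + k_{30}K_\mathrm{mc03}F -
#' k_{30}K_\mathrm{mc03} = 0}.  The positive root of that quadratic
#' always lies in (0, 1) for positive parameters, so `F0` must too.
#'
#' @param p list with `k30` and `k03max`.
#' @param Y0 baseline total %CD11a.
#' @return List with `F0` and `Kmc03`.
#' @export
ng_baseline <- function(p, Y0 = 100) {
  F0 <- p$k30 * Y0 / p$k03max
  if (F0 <= 0 || F0 >= 1)
    stop("baseline fraction F0 = k30*Y0/k03max must lie in (0, 1); got ",
         format(F0))
  Kmc03 <- p$k03max * F0^2 / (p$k30 * (1 - F0))
  # round-trip root check
  res <- p$k03max * F0^2 + p$k30 * Kmc03 * F0 - p$k30 * Kmc03
  stopifnot(abs(res) <= 1e-12 * p$k03max)
  list(F0 = F0, Kmc03 = Kmc03)
}

#' Right-hand side of the five-state psoriasis model
#'
#' Time derivatives of the states
#' `(Xsc, X1, X2, X3, X4)`:
#' \deqn{\dot X_\mathrm{sc} = -k_a X_\mathrm{sc}, \quad
#'   \dot X_1 = -(k_{10}+k_{12})X_1 + k_{21}X_2
#'     - \frac{V_m X_1}{K_\mathrm{mc} V_c + X_1} + F_a k_a X_\mathrm{sc},}
#' \deqn{\dot X_2 = k_{12}X_1 - k_{21}X_2, \quad
#'   \dot X_3 = X_4 - k_{30}X_3 - \frac{V_{m2} X_3 X_1}{K_\mathrm{mc}V_c + X_1},}
#' \deqn{\dot X_4 = k_\mathrm{off}\Big[k_\mathrm{03max}
#'   \frac{K_\mathrm{mc03}}{K_\mathrm{mc03}+X_3} - X_4\Big].}
#' With `feedback = FALSE` the production rate is frozen at its
#' baseline (\eqn{\dot X_4 = 0}), the no-feedback control.
#'
#' @param state named vector `c(Xsc=, X1=, X2=, X3=, X4=)`.
#' @param p a [psoriasis_params()] object.
#' @param feedback keep the moderator dynamic?
#' @return Named derivative vector.
#' @export
ng_rhs <- function(state, p, feedback = TRUE) {
  Xsc <- state[["Xsc"]]; X1 <- state[["X1"]]; X2 <- state[["X2"]]
  X3 <- state[["X3"]]; X4 <- state[["X4"]]
  mm <- X1 / (p$Kmc * p$Vc + X1)
  c(Xsc = -p$ka * Xsc,
    X1 = -(p$k10 + p$k12) * X1 + p$k21 * X2 - p$Vm * mm +
      p$Fa * p$ka * Xsc,
    X2 = p$k12 * X1 - p$k21 * X2,
    X3 = X4 - p$k30 * X3 - p$Vm2 * X3 * mm,
    X4 = if (feedback)
      p$koff * (p$k03max * p$Kmc03 / (p$Kmc03 + X3) - X4)
    else 0)
}

#' Reduce the psoriasis model to the generalised feedback framework
#'
#' With \eqn{y = X_3/Y_0}, \eqn{w = X_4/(k_\mathrm{03max}F_0)} and
#' \eqn{\tau = V_{m2} t}, the receptor--moderator pair takes the
#' standard dimensionless form with
#' \deqn{k_3 = \frac{k_{30}}{V_{m2}}, \quad
#'   \epsilon = \frac{k_\mathrm{off}}{V_{m2}}, \quad
#'   h(y) = \frac{1}{F_0 + (1-F_0)y}, \quad h_0 = 1 - F_0.}
#'
#' @param p a [psoriasis_params()] object.
#' @return List with `k3`, `eps`, `h0` and `h` (a hyperbolic
#'   [feedback_fn()]).
#' @export
ng_to_reduced <- function(p) {
  stopifnot(inherits(p, "psoriasis_params"))
  h <- make_hyperbolic(p$F0)
  list(k3 = p$k30 / p$Vm2, eps = p$koff / p$Vm2, h0 = 1 - p$F0, h = h)
}

#' Eigenvalues of the drug (PK) block
#'
#' The PK subsystem `(Xsc, X1, X2)` decouples from the %CD11a
#' equations.  Its linearisation at the drug-free origin (with the
#' Michaelis term linearised as \eqn{V_m/(K_\mathrm{mc}V_c)}) has three
#' real negative eigenvalues; one of them is exactly \eqn{-k_a}
#' (triangular depot row).  Eigenvalues are returned on the
#' dimensionless scale of the reduction, i.e. divided by `Vm2`, so they
#' compare directly with `k3`, `eps` and the moderator-block spectrum.
#'
#' @param p a [psoriasis_params()] object.
#' @return List with `values` (sorted decreasing, i.e. leading first)
#'   and `leading` (closest to zero).
#' @export
pk_block_eigenvalues <- function(p) {
  stopifnot(inherits(p, "psoriasis_params"))
  J <- matrix(c(-p$ka, 0, 0,
                p$Fa * p$ka, -(p$k10 + p$k12 + p$Vm / (p$Kmc * p$Vc)), p$k21,
                0, p$k12, -p$k21),
              3, 3, byrow = TRUE,
              dimnames = list(c("Xsc", "X1", "X2"), c("Xsc", "X1", "X2")))
  ev <- sort(Re(eigen(J, only.values = TRUE)$values) / p$Vm2,
             decreasing = TRUE)
  list(values = ev, leading = ev[1], jacobian = J)
}

#' Initial condition for a bolus dose
#'
#' Builds the initial state for a single dose on top of the drug-free
#' baseline: intravenous doses go to the central compartment `X1`,
#' subcutaneous doses to the depot `Xsc` (bioavailability `Fa` is
#' applied by the absorption transfer term, not here).  Doses in mg/kg
#' are converted to the model's ug/kg drug unit.
#'
#' @param p a [psoriasis_params()] object.
#' @param dose_mg_per_kg dose in mg per kg bodyweight, `>= 0`.
#' @param route `"iv"` or `"sc"`.
#' @return Named state vector `c(Xsc, X1, X2, X3, X4)`.
#' @export
dose_iv <- function(p, dose_mg_per_kg, route = c("iv", "sc")) {
  route <- match.arg(route)
  if (dose_mg_per_kg < 0) stop("dose must be >= 0")
  dose_ug <- dose_mg_per_kg * 1000
  st <- c(Xsc = 0, X1 = 0, X2 = 0, X3 = p$Y0, X4 = p$k30 * p$Y0)
  if (route == "iv") st[["X1"]] <- dose_ug else st[["Xsc"]] <- dose_ug
  st
}

#' Simulate the psoriasis model
#'
#' Stiff integration of the five-state model after a single dose, with
#' the free-receptor readout
#' \eqn{X_3^\mathrm{free} = K_\mathrm{mc}V_c X_3 /
#' (K_\mathrm{mc}V_c + X_1)} appended (free equals total once the
#' central drug amount is gone).
#'
#' @param p a [psoriasis_params()] object.
#' @param dose_mg_per_kg single dose (default 3 mg/kg).
#' @param route `"iv"` or `"sc"`.
#' @param feedback dynamic moderator (`TRUE`) or frozen at baseline
#'   (`FALSE`, the no-feedback control).
#' @param horizon_days simulation horizon (150 days default, well past
#'   the rebound peak).
#' @param rtol,atol solver tolerances.
#' @param n_out number of output points.
#' @return Data frame of class `psoriasis_traj` with columns `t_days`,
#'   `Xsc`, `X1`, `X2`, `X3_total`, `X3_free`, `X4`; the parameter set
#'   is attached as attribute `"params"`.
#' @export
simulate_psoriasis <- function(p, dose_mg_per_kg = 3, route = "iv",
                               feedback = TRUE, horizon_days = 150,
                               rtol = 1e-10, atol = 1e-12, n_out = 3001) {
  stopifnot(inherits(p, "psoriasis_params"))
  ic <- dose_iv(p, dose_mg_per_kg, route)
  deriv <- function(t, s, parms) list(ng_rhs(s, p, feedback = feedback))
  times <- seq(0, horizon_days, length.out = n_out)
  out <- deSolve::ode(y = ic, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration of the psoriasis model failed")
  dat <- as.data.frame(unclass(out))
  names(dat) <- c("t_days", "Xsc", "X1", "X2", "X3_total", "X4")
  dat$X3_free <- p$Kmc * p$Vc * dat$X3_total / (p$Kmc * p$Vc + dat$X1)
  dat <- dat[c("t_days", "Xsc", "X1", "X2", "X3_total", "X3_free", "X4")]
  attr(dat, "params") <- p
  class(dat) <- c("psoriasis_traj", class(dat))
  dat
}
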