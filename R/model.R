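#' Dimensional TMDD parameter set
#'
#' Collects the dimensional rate constants of the one-compartment TMDD
#' model with feedback on the receptor synthesis rate: binding rates
#' `kon` (1/(concentration * time)) and `koff` (1/time), receptor
#' turnover `kin` (concentration/time) and elimination `kout` (1/time),
#' ligand and complex elimination `keL` and `keP` (1/time), bolus dose
#' `L0` (concentration) and feedback response speed `alpha` (1/time,
#' `>= 0`).  The drug-free baseline is \eqn{R_0 = k_\mathrm{in}/k_\mathrm{out}};
#' either `kin` or `R0` may be supplied (both, if consistent).
#'
#' @param kon,koff binding rate constants.
#' @param kout receptor elimination rate.
#' @param keL,keP ligand and complex elimination rates.
#' @param L0 bolus ligand dose.
#' @param alpha feedback response speed, `>= 0` (0 = no feedback).
#' @param kin receptor synthesis rate; derived from `R0` if missing.
#' @param R0 baseline receptor level; derived from `kin` if missing.
#' @param units named list recording the time and concentration units
#'   (metadata only; defaults to day and nM).
#' @return An object of class `tmdd_params`.
#' @export
tmdd_params <- function(kon, koff, kout, keL, keP, L0, alpha = 0,
                        kin = NULL, R0 = NULL,
                        units = list(time = "day", conc = "nM")) {
  if (is.null(kin) && is.null(R0))
    stop("supply at least one of 'kin' or 'R0'")
  if (is.null(R0)) R0 <- kin / kout
  if (is.null(kin)) kin <- kout * R0
  if (abs(kin - kout * R0) > 1e-9 * max(kin, kout * R0))
    stop("'kin', 'kout' and 'R0' are inconsistent: kin must equal kout * R0")
  vals <- c(kon = kon, koff = koff, kin = kin, kout = kout,
            keL = keL, keP = keP, L0 = L0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates, R0 and L0 must be strictly positive")
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be >= 0")
  structure(list(kon = kon, koff = koff, kin = kin, kout = kout,
                 keL = keL, keP = keP, L0 = L0, alpha = alpha,
                 R0 = R0, units = units),
            class = "tmdd_params")
}

#' @export
print.tmdd_params <- function(x, ...) {
  cat("<tmdd_params> (", x$units$time, ",", x$units$conc, ")\n")
  flds <- c("kon", "koff", "kin", "kout", "keL", "keP", "L0", "alpha", "R0")
  for (f in flds) cat(" ", f, "=", format(x[[f]]), "\n")
  invisible(x)
}

#' Non-dimensionalise a TMDD parameter set
#'
#' Scales the model by the baseline receptor level:
#' \eqn{x = L/L_0}, \eqn{y = R/R_0}, \eqn{z = P/R_0}, \eqn{w = F},
#' \eqn{\tau = k_\mathrm{on} R_0\, t}, giving
#' \deqn{\mu = R_0/L_0,\quad k_1 = \frac{k_\mathrm{e(L)}}{k_\mathrm{on}R_0},
#'   \quad k_2 = \frac{k_\mathrm{off}}{k_\mathrm{on}R_0},
#'   \quad k_3 = \frac{k_\mathrm{in}}{k_\mathrm{on}R_0^2}
#'            = \frac{k_\mathrm{out}}{k_\mathrm{on}R_0},
#'   \quad k_4 = \frac{k_\mathrm{e(P)}}{k_\mathrm{on}R_0},
#'   \quad \epsilon = \frac{\alpha}{k_\mathrm{on}R_0}.}
#'
#' @param p a [tmdd_params()] object.
#' @return A list of class `tmdd_ndim` with fields `mu`, `k1`..`k4`,
#'   `eps`, plus the scale constants `kon`, `R0`, `L0` (so that
#'   dimensional time is \eqn{t = \tau/(k_\mathrm{on}R_0)}).
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "tmdd_params"))
  s <- p$kon * p$R0
  q <- list(mu = p$R0 / p$L0,
            k1 = p$keL / s,
            k2 = p$koff / s,
            k3 = p$kout / s,
            k4 = p$keP / s,
            eps = p$alpha / s,
            kon = p$kon, R0 = p$R0, L0 = p$L0)
  # both printed forms of k3 must agree
  stopifnot(abs(p$kin / (p$kon * p$R0^2) - q$k3) <= 1e-12 * q$k3)
  structure(q, class = "tmdd_ndim")
}

#' Rebuild dimensional parameters from dimensionless ones
#'
#' Inverse of [nondimensionalize()]: given the dimensionless parameter
#' set and the three scale constants, reconstructs the dimensional
#' rates.  The round trip reproduces the original parameters to
#' relative 1e-12.
#'
#' @param q a `tmdd_ndim` object, or a plain list with `mu`,
#'   `k1`..`k4`, `eps`.
#' @param kon,R0,L0 scale constants (taken from `q` when present).
#' @return A [tmdd_params()] object.
#' @export
dimensionalize <- function(q, kon = q$kon, R0 = q$R0, L0 = q$L0) {
  if (is.null(kon) || is.null(R0) || is.null(L0) ||
      kon <= 0 || R0 <= 0 || L0 <= 0)
    stop("'kon', 'R0' and 'L0' must be supplied and strictly positive")
  s <- kon * R0
  if (!is.null(q$mu) && abs(q$mu - R0 / L0) > 1e-9 * q$mu)
    stop("'mu' inconsistent with R0/L0")
  tmdd_params(kon = kon, koff = q$k2 * s, kout = q$k3 * s,
              keL = q$k1 * s, keP = q$k4 * s, L0 = L0,
              alpha = q$eps * s, R0 = R0)
}

#' Model right-hand sides (dimensionless)
#'
#' Derivatives of the dimensionless TMDD models with respect to scaled
#' time \eqn{\tau}.  State ordering is fixed as `(x, z, y)` for the
#' three-state models and `(x, z, y, w)` for the full model, matching
#' the listing order of the equations (and keeping the baseline
#' Jacobian block lower-triangular in the (x,z)/(y,w) split).
#'
#' * `rhs_basic`: no feedback (\eqn{h \equiv 1}).
#' * `rhs_direct`: direct (quasi-equilibrium) feedback, synthesis term
#'   \eqn{k_3 h(y)}.
#' * `rhs_full`: dynamic feedback moderator,
#'   \eqn{\dot w = \epsilon(h(y) - w)} and synthesis \eqn{k_3 w}.
#'
#' @param state named numeric vector; `c(x=, z=, y=)` or
#'   `c(x=, z=, y=, w=)`.
#' @param q a `tmdd_ndim` parameter list.
#' @param h a [feedback_fn()].
#' @return Named numeric vector of derivatives in state order.
#' @export
rhs_basic <- function(state, q) {
  x <- state[["x"]]; z <- state[["z"]]; y <- state[["y"]]
  c(x = -q$k1 * x - x * y + q$mu * q$k2 * z,
    z = x * y / q$mu - (q$k2 + q$k4) * z,
    y = q$k3 * (1 - y) - x * y / q$mu + q$k2 * z)
}

#' @rdname rhs_basic
#' @export
rhs_direct <- function(state, q, h) {
  x <- state[["x"]]; z <- state[["z"]]; y <- state[["y"]]
  c(x = -q$k1 * x - x * y + q$mu * q$k2 * z,
    z = x * y / q$mu - (q$k2 + q$k4) * z,
    y = q$k3 * (h$evaluate(y) - y) - x * y / q$mu + q$k2 * z)
}

#' @rdname rhs_basic
#' @export
rhs_full <- function(state, q, h) {
  x <- state[["x"]]; z <- state[["z"]]; y <- state[["y"]]; w <- state[["w"]]
  c(x = -q$k1 * x - x * y + q$mu * q$k2 * z,
    z = x * y / q$mu - (q$k2 + q$k4) * z,
    y = q$k3 * (w - y) - x * y / q$mu + q$k2 * z,
    w = q$eps * (h$evaluate(y) - w))
}

#' Bolus initial condition
#'
#' The standard initial state: system at its drug-free baseline, plus a
#' unit (scaled) bolus of ligand.  For the receptor-only studies the
#' caller supplies `y0` (and `w0`).
#'
#' @param model one of `"basic"`, `"direct"`, `"full"`,
#'   `"receptor_only"`, `"receptor_moderator"`.
#' @param y0,w0 starting receptor/moderator levels for the
#'   receptor-only studies (default baseline, 1).
#' @return Named state vector in the fixed `(x, z, y, w)` ordering.
#' @export
initial_state <- function(model = c("basic", "direct", "full",
                                    "receptor_only", "receptor_moderator"),
                          y0 = 1, w0 = 1) {
  model <- match.arg(model)
  switch(model,
         basic = ,
         direct = c(x = 1, z = 0, y = 1),
         full = c(x = 1, z = 0, y = 1, w = 1),
         receptor_only = c(y = y0),
         receptor_moderator = c(y = y0, w = w0))
}
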