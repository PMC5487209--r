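#' Omalizumab parameter fixture
#'
#' Literature parameter set for the IgE monoclonal antibody
#' omalizumab (units: day, nM): `keL = 0.024`, `keP = 0.201`,
#' `kout = 0.823`, `R0 = 2.688` nM, `koff = 0.900`, `kon = 0.592`
#' /(nM day), `kin = kout * R0 = 2.212224` nM/day, bolus dose
#' `L0 = 14.8148` nM.  These rates satisfy
#' \eqn{k_\mathrm{e(L)} < k_\mathrm{e(P)}}, so no rebound occurs
#' without feedback or with direct feedback (for any feedback
#' function); with a slow feedback moderator, rebound does occur.
#'
#' @param alpha feedback response speed (1/day) to attach, `>= 0`.
#' @return A [tmdd_params()] object.
#' @export
omalizumab_params <- function(alpha = 0) {
  tmdd_params(kon = 0.592, koff = 0.900, kout = 0.823,
              keL = 0.024, keP = 0.201, L0 = 14.8148,
              alpha = alpha, R0 = 2.688,
              units = list(time = "day", conc = "nM"))
}
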