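#' Calcium buffering: bound fraction
#'
#' Fraction of incoming calcium captured by the intracellular buffer,
#' \eqn{P_B = B_{tot} / (Ca_{in} + B_{tot} + K_d)}; the free influx is
#' attenuated by \eqn{(1 - P_B)}.  Decreasing in \eqn{Ca_{in}} (the buffer
#' saturates).
#'
#' @param Ca_in free shell calcium, mM (>= 0).
#' @param p calcium parameter block (\code{lc_params$calcium}).
#' @return dimensionless fraction in [0, 1).
#' @export
ca_bound_fraction <- function(Ca_in, p) {
  if (any(Ca_in < 0)) stop("Ca_in must be >= 0", call. = FALSE)
  p$B_tot / (Ca_in + p$B_tot + p$K_d)
}

#' Shell calcium dynamics
#'
#' Rate of change of free calcium in the sub-membrane shell:
#' buffer-attenuated influx through the high-threshold calcium currents
#' (L-type + N-type) minus Michaelis-Menten pump extrusion,
#' \deqn{dCa/dt = CSF \frac{I_{Ca}}{2 F v}(1 - P_B) - K_s \frac{Ca}{Ca + K_m}.}
#' \code{I_Ca_total} is given in the membrane equation's inward-positive
#' convention, so a (positive) inward calcium current raises \eqn{Ca_{in}};
#' with no calcium current the pump drives \eqn{Ca_{in}} monotonically to 0.
#'
#' @param Ca_in free shell calcium, mM.
#' @param I_Ca_total summed high-threshold calcium current, nA
#'   (inward-positive).
#' @param p calcium parameter block.
#' @return dCa/dt in mM/ms.
#' @export
calcium_rhs <- function(Ca_in, I_Ca_total, p) {
  Ca <- pmax(Ca_in, 0)
  influx <- p$CSF * I_Ca_total * p$ca_conv * (1 - ca_bound_fraction(Ca, p))
  influx - p$K_s_mM_ms * Ca / (Ca + p$K_m)
}

#' SK channel steady-state activation
#'
#' Calcium-dependent steady-state activation of the small-conductance
#' calcium-activated potassium channel,
#' \eqn{m_{SK}^\infty = Ca^n / (Ca^n + K_c^n)} (standard Hill denominator;
#' the printed difference form cannot produce a value in [0, 1]).  The SK
#' current is then \eqn{g_{SK} m_{SK} (E_K - V)} with \eqn{m_{SK}} relaxing
#' to this steady state with time constant \code{sk_tau_a}.
#'
#' @param Ca_in free shell calcium, mM (>= 0).
#' @param p calcium parameter block (\code{n}, \code{K_c}).
#' @return dimensionless activation in [0, 1).
#' @export
sk_activation <- function(Ca_in, p) {
  if (any(Ca_in < 0)) stop("Ca_in must be >= 0", call. = FALSE)
  Ca_in^p$n / (Ca_in^p$n + p$K_c^p$n)
}

#' BK current coupled to the L-type calcium current
#'
#' The big-conductance calcium-activated potassium current is driven by the
#' normalized magnitude of the L-type calcium current rather than by an
#' explicit calcium dependence: \eqn{I_{BK} = g_{BK}\, L\, (E_K - V)} with
#' \eqn{L = |I_{CaL}| / (\bar g_{CaL} |E_{Ca} - V_r|)} (unitless, the
#' normalization evaluated at the resting potential).
#'
#' @param V membrane potential, mV.
#' @param L_magnitude normalized L-type current magnitude, >= 0.
#' @param g_BK maximal conductance, uS.
#' @param E_K potassium reversal, mV.
#' @return current in nA.
#' @export
bk_current <- function(V, L_magnitude, g_BK, E_K) {
  if (any(L_magnitude < 0)) stop("L_magnitude must be >= 0", call. = FALSE)
  g_BK * L_magnitude * (E_K - V)
}
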