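#' Voltage-gated channel kinetics
#'
#' Boltzmann steady-state activation/inactivation and the two time-constant
#' kernels used by the model's voltage-gated channels.
#'
#' \code{gate_steady_state} evaluates the logistic steady state
#' \deqn{x_\infty(V) = 1 / (1 + e^{-(V - V_{1/2})/k})}
#' with signed slope factor \eqn{k}; inactivation curves carry a negative
#' \eqn{k} so the curve decreases with depolarization.
#'
#' \code{gate_time_constant} evaluates, depending on \code{gp$tau_form},
#' \deqn{\tau(V) = a + b\, e^{-((V - V_\tau)/k_\tau)^2}}
#' (\code{"gaussian"}; sodium activation/inactivation and T-type
#' inactivation) or
#' \deqn{\tau(V) = a + b / \cosh((V - V_\tau)/k_\tau)}
#' (\code{"reciprocal_cosh"}; every other gate).  Both kernels peak at
#' \eqn{V_\tau}, where \eqn{\tau = a + b}, and decay to the floor \eqn{a}.
#'
#' @param V membrane potential, mV (vectorized).
#' @param gp gating-parameter list with fields \code{V_half}, \code{k},
#'   \code{a}, \code{b}, \code{V_tau}, \code{k_tau}, \code{tau_form},
#'   \code{exponent}.
#' @return \code{gate_steady_state}: dimensionless value in [0, 1];
#'   \code{gate_time_constant}: time constant in ms (always >= \code{a}).
#' @examples
#' gp <- lc_default_params()$channels$Na$activation
#' gate_steady_state(gp$V_half, gp)   # 0.5 at the half-activation voltage
#' gate_time_constant(-60, gp)
#' @export
gate_steady_state <- function(V, gp) {
  if (any(!is.finite(V))) stop("non-finite membrane potential", call. = FALSE)
  if (gp$k == 0) stop("slope factor k must be non-zero", call. = FALSE)
  1 / (1 + exp(-(V - gp$V_half) / gp$k))
}

#' @rdname gate_steady_state
#' @export
gate_time_constant <- function(V, gp) {
  if (any(!is.finite(V))) stop("non-finite membrane potential", call. = FALSE)
  if (gp$b == 0) return(rep_len(gp$a, length(V)))
  if (!is.finite(gp$k_tau) || gp$k_tau == 0)
    stop("k_tau must be non-zero when b > 0", call. = FALSE)
  u <- (V - gp$V_tau) / gp$k_tau
  if (identical(gp$tau_form, "gaussian")) gp$a + gp$b * exp(-u^2)
  else gp$a + gp$b / cosh(u)
}

#' Ohmic current through a gated channel
#'
#' Evaluates \eqn{I = \phi \,\bar g\, m^\alpha h^\beta (E - V)} (nA) for a
#' standard voltage-gated channel, with the chemosensitivity scaling
#' \eqn{\phi} applied to the maximal conductance.  The current is positive
#' when inward (depolarizing), following the membrane equation's
#' inward-positive convention.
#'
#' @param V membrane potential, mV.
#' @param m activation variable in [0, 1].
#' @param h inactivation variable in [0, 1]; ignored when \code{spec} carries
#'   no inactivation.
#' @param spec channel specification (element of \code{lc_params$channels}).
#' @param phi conductance scaling factor, >= 0 (see \code{\link{chemo_phi}}).
#' @return current in nA (vectorized over \code{V}, \code{m}, \code{h}).
#' @export
channel_current <- function(V, m, h = 1, spec, phi = 1) {
  if (!identical(spec$kind, "standard"))
    stop("channel_current applies to standard gated channels only", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("activation m outside [0, 1]", call. = FALSE)
  if (any(h < 0 | h > 1)) stop("inactivation h outside [0, 1]", call. = FALSE)
  if (any(phi < 0)) stop("phi must be >= 0", call. = FALSE)
  hterm <- if (is.null(spec$inactivation)) 1 else h^spec$inact_exponent
  phi * spec$gbar * m^spec$activation$exponent * hterm * (spec$E_rev - V)
}

#' Inwardly rectifying potassium current
#'
#' Evaluates the rectifier exactly as the model defines it,
#' \deqn{I_{Kir} = \bar g\,(V - E_K - 36) / (1 + e^{(V - E_K + 140)\,ZF/RT}),}
#' and the result enters the membrane current sum at face value: near rest
#' (\eqn{V > E_K + 36}) the numerator is negative, so the current
#' hyperpolarizes, and the exponential denominator suppresses its magnitude
#' at depolarized potentials.
#'
#' @param V membrane potential, mV.
#' @param gbar maximal conductance, uS.
#' @param E_K potassium reversal potential, mV.
#' @param thermal_slope \eqn{ZF/RT}, 1/mV (0.0394 at 295 K for Z = 1).
#' @return current in nA.
#' @export
kir_current <- function(V, gbar, E_K, thermal_slope = 0.0394) {
  if (any(!is.finite(V))) stop("non-finite membrane potential", call. = FALSE)
  gbar * (V - E_K - 36) / (1 + exp((V - E_K + 140) * thermal_slope))
}
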