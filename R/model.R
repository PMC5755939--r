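#' Decompose the passive leak into Na / K / Cl components
#'
#' The total leak conductance is the reciprocal of the input resistance.  The
#' potassium share is the TASK conductance, the sodium share is fixed by
#' requiring the three linear leaks to balance at the resting potential,
#' \deqn{g_{Na} = \frac{R_{in}^{-1}(E_{Cl} - V_r) + g_K (E_{Cl} - E_K)}{E_{Cl} - E_{Na}},}
#' and chloride takes the remainder.  By construction the leak-only membrane
#' rests at the conductance-weighted reversal mix
#' \eqn{\sum_j g_j E_j / \sum_j g_j = V_r}.
#'
#' @param cell cell parameter block (\code{R_in} in MOhm, \code{V_r} in mV,
#'   \code{g_task} in uS).
#' @param E_Na,E_K,E_Cl reversal potentials, mV.
#' @return list with \code{g_total}, \code{g_K}, \code{g_Na}, \code{g_Cl}
#'   (uS); errors if any component comes out negative.
#' @export
leak_decomposition <- function(cell, E_Na, E_K, E_Cl) {
  g_total <- 1 / cell$R_in
  g_K <- cell$g_task
  g_Na <- (g_total * (E_Cl - cell$V_r) + g_K * (E_Cl - E_K)) / (E_Cl - E_Na)
  g_Cl <- g_total - g_K - g_Na
  out <- list(g_total = g_total, g_K = g_K, g_Na = g_Na, g_Cl = g_Cl)
  for (nm in c("g_K", "g_Na", "g_Cl"))
    if (out[[nm]] < 0)
      stop(sprintf("leak decomposition yields %s = %.4g < 0 (check R_in, g_task, reversals)",
                   nm, out[[nm]]), call. = FALSE)
  out
}

# ---- state vector ----------------------------------------------------------

lc_state_names <- function() {
  gates <- c("CaL.m", "CaN.m", "CaT.m", "CaT.h", "H.m", "KA.m", "KA.h",
             "KM.m", "KM.h", "Kdr.m", "Kdr.h", "Na.m", "Na.h")
  c("V", gates, "m_SK", "Ca_in")
}

# 0-based gate index pairs for the compiled layout
lc_gate_index <- function() {
  idx <- list(CaL = c(1L, -1L), CaN = c(2L, -1L), CaT = c(3L, 4L),
              H = c(5L, -1L), KA = c(6L, 7L), KM = c(8L, 9L),
              Kdr = c(10L, 11L), Na = c(12L, 13L))
  idx
}

#' Initial state of the model
#'
#' Membrane potential at the resting value, every voltage gate at its steady
#' state for that potential, SK activation at its calcium steady state, and
#' shell calcium at its baseline concentration.  Every protocol run starts
#' here and is pre-equilibrated before anything is measured.
#'
#' @param p an \code{lc_params} object.
#' @param V starting potential, mV (defaults to the resting potential).
#' @return named numeric state vector (see \code{lc_state_names}).
#' @export
initial_state <- function(p, V = p$cell$V_r) {
  y <- setNames(numeric(16), lc_state_names())
  y["V"] <- V
  for (nm in LC_GATED) {
    chn <- p$channels[[nm]]
    y[paste0(nm, ".m")] <- gate_steady_state(V, chn$activation)
    if (!is.null(chn$inactivation))
      y[paste0(nm, ".h")] <- gate_steady_state(V, chn$inactivation)
  }
  y["Ca_in"] <- p$calcium$Ca0_mM
  y["m_SK"] <- sk_activation(p$calcium$Ca0_mM, p$calcium)
  y
}

# ---- compiled-parameter assembly -------------------------------------------

# Flattens an lc_params + condition + applied current into the fixed-layout
# double vector consumed by the C right-hand side.  phi is folded into geff.
lc_build_parms <- function(p, cond, I_app = 0) {
  phi <- lc_phi_all(cond, p)
  gidx <- lc_gate_index()
  pv <- numeric(195)
  pv[1] <- p$cell$c
  pv[2] <- I_app
  pv[3] <- 8
  for (j in seq_along(LC_GATED)) {
    nm <- LC_GATED[j]
    chn <- p$channels[[nm]]
    a <- chn$activation
    base <- 3 + (j - 1) * 21
    q <- numeric(21)
    q[1] <- phi[[nm]] * chn$gbar
    q[2] <- chn$E_rev
    q[3] <- a$exponent
    q[4] <- gidx[[nm]][1]
    q[5] <- as.numeric(!is.null(chn$inactivation))
    q[6] <- gidx[[nm]][2]
    q[7:13] <- c(a$V_half, a$k, a$a, a$b,
                 ifelse(is.na(a$V_tau), 0, a$V_tau), a$k_tau,
                 as.numeric(identical(a$tau_form, "gaussian")))
    if (!is.null(chn$inactivation)) {
      h <- chn$inactivation
      q[14:20] <- c(h$V_half, h$k, h$a, h$b,
                    ifelse(is.na(h$V_tau), 0, h$V_tau), h$k_tau,
                    as.numeric(identical(h$tau_form, "gaussian")))
    }
    q[21] <- as.numeric(nm %in% c("CaL", "CaN"))
    pv[(base + 1):(base + 21)] <- q
  }
  E_K <- p$reversal$E_K
  idxCaL <- match(p$options$bk_couples_to, LC_GATED) - 1L
  gCa <- p$channels[[p$options$bk_couples_to]]$gbar
  Ldenom <- gCa * abs(p$reversal$E_Ca - p$cell$V_r)
  pv[172:174] <- c(phi[["Kir"]] * p$channels$Kir$gbar, E_K, p$cell$ZFRT)
  pv[175:177] <- c(phi[["BK"]] * p$channels$BK$gbar, idxCaL, Ldenom)
  pv[178:181] <- c(p$channels$SK$gbar, p$calcium$K_c, p$calcium$n,
                   p$calcium$sk_tau_a)
  pv[182:187] <- c(p$leak$g_Na, p$reversal$E_Na,
                   phi[["TASK"]] * p$leak$g_K, E_K,
                   p$leak$g_Cl, p$reversal$E_Cl)
  pv[188:193] <- c(p$calcium$CSF, p$calcium$ca_conv, p$calcium$B_tot,
                   p$calcium$K_d, p$calcium$K_s_mM_ms, p$calcium$K_m)
  pv[194:195] <- c(14, 15)
  pv
}

#' Full model right-hand side
#'
#' Time derivative of the complete state vector: the membrane equation
#' \eqn{c\,dV/dt = \sum_i I_i + I_{app}} over all twelve currents (eight
#' voltage-gated, Kir, BK, SK and the three-component linear leak), the
#' first-order gate relaxations \eqn{dx/dt = (x_\infty - x)/\tau_x}, SK
#' activation, and the shell-calcium balance.  Chemosensitive conductances
#' are scaled by \eqn{\phi} for the given condition.
#'
#' @param state named state vector (\code{\link{initial_state}} layout).
#' @param I_app applied current, nA; positive depolarizes.
#' @param cond chemical condition (object, preset name, or triple).
#' @param p an \code{lc_params} object.
#' @return named vector of derivatives (mV/ms, 1/ms, mM/ms).
#' @export
membrane_rhs <- function(state, I_app, cond, p) {
  dy <- .Call(C_lc_rhs, 0, as.numeric(state), lc_build_parms(p, cond, I_app))
  if (any(!is.finite(dy))) {
    bad <- lc_state_names()[!is.finite(dy)]
    stop("non-finite derivative for state component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  setNames(dy, lc_state_names())
}

#' Per-channel membrane currents
#'
#' Evaluates every membrane current at one or more recorded states, in the
#' inward-positive convention the membrane equation uses.  Vectorized over
#' rows of a simulation result, so current traces can be reconstructed from
#' a recorded run without re-integrating.
#'
#' @param states either a named state vector or a data.frame of recorded
#'   states (columns as in \code{lc_state_names}).
#' @param cond chemical condition the states were recorded under.
#' @param p an \code{lc_params} object.
#' @return data.frame with one column per current (nA): the gated channels,
#'   \code{Kir}, \code{BK}, \code{SK}, and leak components \code{leak_Na},
#'   \code{leak_K}, \code{leak_Cl}.
#' @export
lc_currents <- function(states, cond, p) {
  if (is.null(dim(states))) states <- as.data.frame(as.list(states))
  phi <- lc_phi_all(cond, p)
  V <- states$V
  out <- list()
  for (nm in LC_GATED) {
    chn <- p$channels[[nm]]
    h <- if (is.null(chn$inactivation)) 1 else states[[paste0(nm, ".h")]]
    out[[nm]] <- channel_current(V, states[[paste0(nm, ".m")]], h, chn,
                                 phi[[nm]])
  }
  out$Kir <- kir_current(V, phi[["Kir"]] * p$channels$Kir$gbar,
                         p$reversal$E_K, p$cell$ZFRT)
  cpl <- p$options$bk_couples_to
  Ldenom <- p$channels[[cpl]]$gbar * abs(p$reversal$E_Ca - p$cell$V_r)
  L <- if (Ldenom > 0) abs(out[[cpl]]) / Ldenom else 0
  out$BK <- bk_current(V, L, phi[["BK"]] * p$channels$BK$gbar, p$reversal$E_K)
  out$SK <- p$channels$SK$gbar * states$m_SK * (p$reversal$E_K - V)
  out$leak_Na <- p$leak$g_Na * (p$reversal$E_Na - V)
  out$leak_K <- phi[["TASK"]] * p$leak$g_K * (p$reversal$E_K - V)
  out$leak_Cl <- p$leak$g_Cl * (p$reversal$E_Cl - V)
  as.data.frame(out, check.names = FALSE)
}
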