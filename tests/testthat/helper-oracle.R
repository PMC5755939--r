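# Independent right-hand-side oracle: rebuilds the membrane equation
# term by term with plain arithmetic from the parameter lists, without
# calling any package current/gating function.  Used to cross-check the
# compiled derivatives.

lc_phi_oracle <- function(cond, p) {
  titr <- function(pH, pK, h) 1 / (1 + 10^(h * (pH - pK)))   # default form
  sat <- function(s, s_half, h) 1 / (1 + (s_half / s)^h)
  out <- numeric(0)
  for (nm in names(p$channels)) {
    w <- p$channels[[nm]]$chemo
    if (is.null(w)) { out[nm] <- 1; next }
    tot <- 0
    if (w$w_pHi != 0) tot <- tot + w$w_pHi * titr(cond$pH_i, w$pK_i, w$h_i)
    if (w$w_pHo != 0) tot <- tot + w$w_pHo * titr(cond$pH_o, w$pK_o, w$h_o)
    if (w$w_CO2 != 0) tot <- tot + w$w_CO2 * sat(cond$co2_percent, w$co2_half, w$h_c)
    out[nm] <- 1 - tot
  }
  out
}

rhs_oracle <- function(st, I_app, phi, p) {
  V <- st[["V"]]
  dy <- st * 0
  Isum <- 0; ICa <- 0; Icpl <- 0
  for (nm in c("CaL", "CaN", "CaT", "H", "KA", "KM", "Kdr", "Na")) {
    ch <- p$channels[[nm]]
    a <- ch$activation
    m <- st[[paste0(nm, ".m")]]
    minf <- 1 / (1 + exp(-(V - a$V_half) / a$k))
    tau <- if (a$b == 0) a$a else {
      u <- (V - a$V_tau) / a$k_tau
      if (a$tau_form == "gaussian") a$a + a$b * exp(-u^2)
      else a$a + a$b / cosh(u)
    }
    dy[paste0(nm, ".m")] <- (minf - m) / tau
    hterm <- 1
    if (!is.null(ch$inactivation)) {
      hh <- ch$inactivation
      h <- st[[paste0(nm, ".h")]]
      hinf <- 1 / (1 + exp(-(V - hh$V_half) / hh$k))
      tauh <- if (hh$b == 0) hh$a else {
        u <- (V - hh$V_tau) / hh$k_tau
        if (hh$tau_form == "gaussian") hh$a + hh$b * exp(-u^2)
        else hh$a + hh$b / cosh(u)
      }
      dy[paste0(nm, ".h")] <- (hinf - h) / tauh
      hterm <- h
    }
    I <- phi[nm] * ch$gbar * m^a$exponent * hterm * (ch$E_rev - V)
    Isum <- Isum + I
    if (nm %in% c("CaL", "CaN")) ICa <- ICa + I
    if (nm == p$options$bk_couples_to) Icpl <- I
  }
  E_K <- p$reversal$E_K
  Isum <- Isum + phi["Kir"] * p$channels$Kir$gbar * (V - E_K - 36) /
    (1 + exp((V - E_K + 140) * p$cell$ZFRT))
  L <- abs(Icpl) / (p$channels[[p$options$bk_couples_to]]$gbar *
                    abs(p$reversal$E_Ca - p$cell$V_r))
  Isum <- Isum + phi["BK"] * p$channels$BK$gbar * L * (E_K - V)
  ca <- p$calcium
  Ca <- max(st[["Ca_in"]], 0)
  msinf <- Ca^ca$n / (Ca^ca$n + ca$K_c^ca$n)
  dy["m_SK"] <- (msinf - st[["m_SK"]]) / ca$sk_tau_a
  Isum <- Isum + p$channels$SK$gbar * st[["m_SK"]] * (E_K - V)
  PB <- ca$B_tot / (Ca + ca$B_tot + ca$K_d)
  dCa <- ca$CSF * ICa * ca$ca_conv * (1 - PB) - ca$K_s_mM_ms * Ca / (Ca + ca$K_m)
  if (st[["Ca_in"]] <= 0 && dCa < 0) dCa <- 0
  dy["Ca_in"] <- dCa
  Isum <- Isum + p$leak$g_Na * (p$reversal$E_Na - V) +
    phi["TASK"] * p$leak$g_K * (E_K - V) +
    p$leak$g_Cl * (p$reversal$E_Cl - V)
  dy["V"] <- (Isum + I_app) / p$cell$c
  dy
}
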