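#' Chemical condition of the bath
#'
#' A chemical condition is the (CO2 percentage, extracellular pH,
#' intracellular pH) triple driving the chemosensitive conductance scaling.
#' The three signals are independent inputs: the model does not couple them
#' through buffering chemistry.
#'
#' @param co2_percent CO2 level, percent, in (0, 30].
#' @param pH_o extracellular pH, in [6, 8.2].
#' @param pH_i intracellular pH, in [6, 8.2].
#' @return list of class \code{lc_condition}.
#' @export
chemical_condition <- function(co2_percent, pH_o, pH_i) {
  if (!is.finite(co2_percent) || co2_percent <= 0 || co2_percent > 30)
    stop("co2_percent must lie in (0, 30]", call. = FALSE)
  for (v in c(pH_o, pH_i))
    if (!is.finite(v) || v < 6 || v > 8.2)
      stop("pH values must lie in [6, 8.2]", call. = FALSE)
  structure(list(co2_percent = co2_percent, pH_o = pH_o, pH_i = pH_i),
            class = "lc_condition")
}

#' Named chemical-condition presets
#'
#' The experimental conditions the model is exercised under:
#' normocapnia (\code{N}), isohydric hypercapnia (\code{IH}), isocapnic
#' acidosis (\code{IA}), hypercapnic acidosis (\code{HA}), hypercapnic
#' acidosis with intracellular pH clamped at control (\code{HA*}), and
#' hypocapnic alkalosis (\code{HypoA}).
#'
#' @return named list of \code{lc_condition} objects.
#' @examples
#' condition_presets()$HA
#' @export
condition_presets <- function() {
  list(
    "N"     = chemical_condition(5,    7.45, 7.25),
    "IH"    = chemical_condition(15,   7.45, 7.25),
    "IA"    = chemical_condition(5,    7.10, 7.00),
    "HA"    = chemical_condition(15,   7.10, 7.00),
    "HA*"   = chemical_condition(15,   7.10, 7.25),
    "HypoA" = chemical_condition(2.5,  7.55, 7.30)
  )
}

lc_condition <- function(cond) {
  if (inherits(cond, "lc_condition")) return(cond)
  if (is.character(cond)) {
    pr <- condition_presets()
    if (!cond %in% names(pr))
      stop(sprintf("unknown condition preset '%s'", cond), call. = FALSE)
    return(pr[[cond]])
  }
  if (is.list(cond) || is.numeric(cond))
    return(do.call(chemical_condition, as.list(unname(unlist(cond)))))
  stop("cannot interpret chemical condition", call. = FALSE)
}

#' Hill saturation response
#'
#' The single-signal response \eqn{1 / (1 + (s_{1/2}/s)^h)}: monotone
#' increasing in the signal, 0.5 at the midpoint \eqn{s_{1/2}}, saturating at
#' 1.  For the pH-driven terms the signal is the pH value itself with
#' \eqn{s_{1/2}} the pK of the titration curve; for CO2 it is the percentage
#' at half-maximal activation.
#'
#' @param s signal value (> 0), pH units or percent CO2.
#' @param s_half midpoint, same units.
#' @param h Hill coefficient (> 0); the tabulated pH titrations use h = 15,
#'   giving a near-switch response around the pK.
#' @return dimensionless value in (0, 1).
#' @export
hill_response <- function(s, s_half, h) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("signal must be > 0", call. = FALSE)
  if (s_half <= 0 || h <= 0) stop("s_half and h must be > 0", call. = FALSE)
  1 / (1 + (s_half / s)^h)
}

#' Chemosensitivity conductance scaling
#'
#' The unitless scaling \eqn{\phi = 1 - \sum_s w_s\, \phi_s(s)} applied to a
#' channel's maximal conductance, with one Hill term \eqn{\phi_s} per signal
#' (intracellular pH, extracellular pH, CO2) and signed weights \eqn{w_s}
#' (positive = inhibition, negative = activation).  Signals with zero weight
#' contribute nothing and their Hill parameters are never evaluated.  A
#' non-chemosensitive channel (all weights zero, or \code{w = NULL}) has
#' \eqn{\phi = 1} under every condition.
#'
#' The pH terms model the titration of channel-protein residues, which makes
#' channel modulation grow as the bath acidifies.  Three evaluation forms are
#' available through \code{ph_hill_form}:
#' \itemize{
#'   \item \code{"ph_ratio"} (default): \eqn{1/(1+(pH/pK)^h)}, the Hill
#'     response on the pH numeral with the acid-activated direction; with the
#'     tabulated h = 15 this gives a graded ~20-30\% modulation per 0.1-0.3
#'     pH unit, matching the partial current inhibitions the weights encode.
#'   \item \code{"printed"}: \eqn{1/(1+(pK/pH)^h)}, increasing in pH, so
#'     alkalosis maximizes channel inhibition; retained for sensitivity
#'     analyses of the direction convention.
#'   \item \code{"protonation"}: the base-10 titration fraction
#'     \eqn{1/(1+10^{h(pH-pK)})}; with h = 15 this is a near-binary switch
#'     at the pK (it drives fully weighted channels to zero conductance one
#'     tenth of a pH unit below their pK).
#' }
#' The CO2 term is the same saturation curve on the CO2 percentage in every
#' form.
#'
#' @param cond an \code{lc_condition}, preset name, or (co2, pH_o, pH_i)
#'   triple.
#' @param w chemosensitivity weight block of a channel (or \code{NULL}).
#' @param ph_hill_form one of \code{"ph_ratio"}, \code{"printed"},
#'   \code{"protonation"}.
#' @return scaling factor >= 0; an admissible configuration that yields a
#'   negative value signals miscalibrated weights and raises an error.
#' @export
chemo_phi <- function(cond, w,
                      ph_hill_form = c("ph_ratio", "printed", "protonation")) {
  cond <- lc_condition(cond)
  ph_hill_form <- match.arg(ph_hill_form)
  if (is.null(w)) return(1)
  resp <- function(s, s_half, h, ph_axis) {
    if (!ph_axis) return(hill_response(s, s_half, h))
    switch(ph_hill_form,
           ph_ratio = 1 / (1 + (s / s_half)^h),
           printed = hill_response(s, s_half, h),
           protonation = 1 / (1 + 10^(h * (s - s_half))))
  }
  total <- 0
  if (abs(w$w_pHi) > 0)
    total <- total + w$w_pHi * resp(cond$pH_i, w$pK_i, w$h_i, TRUE)
  if (abs(w$w_pHo) > 0)
    total <- total + w$w_pHo * resp(cond$pH_o, w$pK_o, w$h_o, TRUE)
  if (abs(w$w_CO2) > 0)
    total <- total + w$w_CO2 * resp(cond$co2_percent, w$co2_half, w$h_c, FALSE)
  phi <- 1 - total
  if (phi < 0)
    stop("phi < 0 under an admissible condition: miscalibrated chemosensitivity weights",
         call. = FALSE)
  phi
}

# phi for every channel under one condition (internal; used per segment)
lc_phi_all <- function(cond, p) {
  cond <- lc_condition(cond)
  vapply(p$channels, function(chn)
    chemo_phi(cond, chn$chemo, p$options$ph_hill_form), numeric(1))
}
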