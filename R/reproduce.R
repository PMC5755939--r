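# Published reference values the reproduction reports compare against.
# These are inputs (printed result tables), not fitted quantities.
lc_reference <- function(id) {
  switch(id,
    table1 = data.frame(
      metric = c("threshold", "ahp_depth", "amplitude", "initial_rate"),
      printed = c(-50.3, 16.7, 70, 1.43)),
    table2 = data.frame(
      signal = c("I_s", "CO2", "pH_i", "pH_o"),
      delta = c(0.02, 2, -0.1, -0.1),
      fr_s = c(2.87, 1.46, 1.78, 2.02),
      si = c(100.7, 2.09, 24.47, 41.26)),
    table3 = data.frame(
      stimulus = c("N", "IH", "IA", "HA", "HA*"),
      fr_s = c(1.43, 1.26, 3.03, 2.85, 2.68),
      si = c(0, 11.9, 111.9, 99.3, 87.4)),
    sfa = data.frame(
      protocol = c("electrical", "chemical"),
      peak = c(30, 3.5), steady = c(8, 2.8), ratio = c(3.75, 1.25)),
    stop(sprintf("unknown reference table '%s'", id), call. = FALSE)
  )
}

# Condition perturbed along one signal from normocapnia (Table 2 rows)
lc_table2_condition <- function(signal) {
  switch(signal,
    I_s = list(cond = "N", I_app = 0.02),
    CO2 = list(cond = chemical_condition(7, 7.45, 7.25), I_app = 0),
    pH_i = list(cond = chemical_condition(5, 7.45, 7.15), I_app = 0),
    pH_o = list(cond = chemical_condition(5, 7.35, 7.25), I_app = 0))
}

#' Recompute a published result table
#'
#' Runs the protocols behind one of the model's published summary tables and
#' reports computed versus printed values side by side with relative errors:
#' \code{"table1"} (action-potential morphology and spontaneous rate under
#' normocapnia), \code{"table2"} (firing-rate response to the minimal change
#' of each individual signal), \code{"table3"} (firing rate and sensitivity
#' index for the named chemical conditions), \code{"sfa"} (adaptation ratios
#' for the electrical and chemical step protocols).
#'
#' All firing rates are steady rates over the final 2 s of a 10 s run after
#' 2 s of pre-equilibration; peak rates use the first second of the stimulus
#' segment.
#'
#' @param id one of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"sfa"}.
#' @param p model parameterization.
#' @param sim_ms constant-run length, ms.
#' @param record_dt sampling interval, ms.
#' @return data.frame with columns \code{computed}, \code{printed},
#'   \code{rel_error}.
#' @export
reproduce_table <- function(id, p = lc_default_params(), sim_ms = 10000,
                            record_dt = 0.05) {
  ref <- lc_reference(id)
  rate_at <- function(cond, I_app = 0)
    steady_rate(run_protocol(protocol_constant(cond, I_app, sim_ms,
                                               record_dt = record_dt), p))
  if (id == "table1") {
    sim <- run_protocol(protocol_constant("N", 0, sim_ms,
                                          record_dt = record_dt), p)
    spk <- detect_spikes(sim$V, sim$time)
    m <- ap_morphology(sim$V, sim$time, spk, p$options$dvdt_threshold)
    computed <- c(m$threshold, m$ahp_depth, m$amplitude, steady_rate(sim))
  } else if (id == "table2") {
    computed <- vapply(ref$signal, function(sg) {
      cf <- lc_table2_condition(sg)
      rate_at(cf$cond, cf$I_app)
    }, numeric(1))
    fr_c <- rate_at("N")
    out <- data.frame(ref, computed_fr = computed,
                      computed_si = sensitivity_index(computed, fr_c))
    out$rel_error <- abs(out$computed_fr - out$fr_s) / out$fr_s
    return(out)
  } else if (id == "table3") {
    computed <- vapply(ref$stimulus, rate_at, numeric(1))
    fr_c <- computed[ref$stimulus == "N"]
    out <- data.frame(ref, computed_fr = computed,
                      computed_si = sensitivity_index(computed, fr_c))
    out$rel_error <- abs(out$computed_fr - out$fr_s) / out$fr_s
    return(out)
  } else if (id == "sfa") {
    st <- lapply(c("fig2", "fig3"), sfa_for_protocol, p = p,
                 record_dt = record_dt)
    out <- data.frame(ref,
                      computed_peak = vapply(st, `[[`, 0, "peak_rate"),
                      computed_steady = vapply(st, `[[`, 0, "steady_rate"),
                      computed_ratio = vapply(st, `[[`, 0, "sfa_ratio"))
    out$rel_error <- abs(out$computed_ratio - out$ratio) / out$ratio
    return(out)
  }
  out <- data.frame(ref, computed = computed)
  out$rel_error <- abs(out$computed - out$printed) / abs(out$printed)
  out
}

# Peak/steady/SFA for the canned step protocols: the stimulus segment is the
# second one; peak window = its first second, steady window = its last 2 s.
sfa_for_protocol <- function(name, p, record_dt = 0.05) {
  prot <- protocol_preset(name, record_dt = record_dt)
  sim <- run_protocol(prot, p)
  b <- attr(sim, "boundaries")
  spk <- detect_spikes(sim$V, sim$time)
  rate_statistics(spk, peak_window = c(b[1], b[1] + 1000),
                  steady_window = c(b[2] - 2000, b[2]))
}

#' Export a recorded run as tidy CSV
#'
#' Writes the time grid, membrane potential, shell calcium, SK activation
#' and (optionally) every membrane current to a CSV file, one row per
#' sample, together with a JSON manifest (tolerances, protocol digest) that
#' suffices to re-run the simulation bit-identically - the model itself is
#' fully deterministic.
#'
#' @param sim an \code{lc_sim}.
#' @param path output CSV path.
#' @param p model parameterization; when supplied, per-channel current
#'   columns are appended (currents are reconstructed per segment from the
#'   recorded states).
#' @param manifest write \code{<path>.manifest.json}.
#' @return \code{path}, invisibly.
#' @export
export_csv <- function(sim, path, p = NULL, manifest = TRUE) {
  out <- as.data.frame(sim)[, c("time", "V", "Ca_in", "m_SK")]
  if (!is.null(p)) {
    prot <- attr(sim, "protocol")
    bounds <- c(min(sim$time), attr(sim, "boundaries"))
    cur <- lc_currents(as.data.frame(sim), prot$segments[[1]]$condition, p)
    seg_of <- findInterval(sim$time, bounds, rightmost.closed = TRUE,
                           left.open = TRUE)
    seg_of[seg_of < 1] <- 1
    for (i in unique(seg_of)) {
      rows <- seg_of == i
      cur[rows, ] <- lc_currents(as.data.frame(sim)[rows, , drop = FALSE],
                                 prot$segments[[i]]$condition, p)
    }
    out <- cbind(out, cur)
  }
  write.csv(out, path, row.names = FALSE)
  if (manifest) {
    mf <- list(samples = nrow(out), record_dt = attr(sim, "record_dt"),
               deterministic = TRUE,
               note = "fixed-step dense output from a deterministic stiff solve; identical inputs reproduce this file bit-identically")
    jsonlite::write_json(mf, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
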