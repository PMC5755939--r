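#' Detect spikes in a voltage trace
#'
#' Upward crossings of a fixed voltage criterion (default -20 mV) with a
#' refractory gap of at least 2 ms between accepted crossings; the spike time
#' is the local voltage maximum following the crossing.
#'
#' @param V membrane potential trace, mV.
#' @param time uniformly sampled time grid, ms.
#' @param threshold crossing criterion, mV.
#' @param refractory minimum separation between crossings, ms.
#' @return numeric vector of spike (peak) times, ms; empty when nothing
#'   crosses the criterion.
#' @export
detect_spikes <- function(V, time, threshold = -20, refractory = 2) {
  stopifnot(length(V) == length(time), length(V) >= 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("time grid must be uniform", call. = FALSE)
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (length(up) == 0) return(numeric(0))
  acc <- up[1]
  for (i in up[-1]) if (time[i] - time[tail(acc, 1)] >= refractory)
    acc <- c(acc, i)
  vapply(acc, function(i) {
    j <- i
    n <- length(V)
    while (j < n && V[j + 1] >= V[j]) j <- j + 1
    time[j]
  }, numeric(1))
}

#' Action-potential morphology
#'
#' Spike threshold, afterhyperpolarization depth and amplitude, averaged over
#' the spikes of a trace.  The threshold of each spike is the voltage at
#' which dV/dt first exceeds a slope criterion (default 10 mV/ms) on the
#' rising phase before the peak; the amplitude is peak minus threshold; the
#' AHP depth is threshold minus the voltage minimum in the following
#' inter-spike interval.  All three are invariant under a uniform voltage
#' offset of the whole trace.
#'
#' @param V membrane potential trace, mV.
#' @param time uniform time grid, ms.
#' @param spike_times spike peak times from \code{\link{detect_spikes}}; at
#'   least two spikes are required (the AHP needs a complete inter-spike
#'   interval).
#' @param dvdt_crit slope criterion, mV/ms.
#' @return list with \code{threshold}, \code{ahp_depth}, \code{amplitude}
#'   (mV, means over spikes) and their standard deviations
#'   \code{threshold_sd}, \code{ahp_sd}, \code{amplitude_sd}.
#' @export
ap_morphology <- function(V, time, spike_times, dvdt_crit = 10) {
  if (length(spike_times) < 2)
    stop("at least two spikes are required for morphology", call. = FALSE)
  dt <- time[2] - time[1]
  dVdt <- c(NA, diff(V)) / dt
  thr <- amp <- ahp <- numeric(0)
  for (s in seq_along(spike_times)) {
    ipk <- which.min(abs(time - spike_times[s]))
    i0 <- if (s == 1) max(1, ipk - round(50 / dt))
          else which.min(abs(time - spike_times[s - 1]))
    # measure from the inter-spike voltage minimum so the previous spike's
    # own upstroke cannot satisfy the slope criterion
    i0 <- i0 + which.min(V[i0:ipk]) - 1L
    rise <- i0:ipk
    cross <- rise[which(dVdt[rise] >= dvdt_crit)]
    if (length(cross) == 0) next
    # first sustained crossing on this rising phase
    ith <- cross[1]
    thr <- c(thr, V[ith])
    amp <- c(amp, V[ipk] - V[ith])
    if (s < length(spike_times)) {
      inx <- which.min(abs(time - spike_times[s + 1]))
      ahp <- c(ahp, V[ith] - min(V[ipk:inx]))
    }
  }
  if (length(thr) == 0) stop("no spike reached the dV/dt criterion", call. = FALSE)
  list(threshold = mean(thr), ahp_depth = mean(ahp), amplitude = mean(amp),
       threshold_sd = stats::sd(thr), ahp_sd = stats::sd(ahp),
       amplitude_sd = stats::sd(amp))
}

#' Firing-rate statistics and adaptation ratio
#'
#' Peak rate is the reciprocal of the minimum inter-spike interval inside the
#' peak window (resolving short high-frequency transients that a windowed
#' count would smear); steady rate is the spike count over the steady window
#' divided by its duration; the spike-frequency-adaptation (SFA) ratio is
#' peak over steady.
#'
#' @param spike_times spike times, ms.
#' @param peak_window,steady_window two-element \code{c(start, end)} windows,
#'   ms.
#' @param initial_rate optionally, the unstimulated steady rate (Hz) to carry
#'   through into the result.
#' @return list with \code{initial_rate}, \code{peak_rate},
#'   \code{steady_rate} (Hz) and \code{sfa_ratio} (NA when a window holds no
#'   spikes).
#' @export
rate_statistics <- function(spike_times, peak_window, steady_window,
                            initial_rate = NA_real_) {
  inw <- function(w) spike_times[spike_times >= w[1] & spike_times <= w[2]]
  pk <- inw(peak_window)
  st <- inw(steady_window)
  peak_rate <- if (length(pk) >= 2) 1000 / min(diff(pk)) else 0
  steady_rate <- length(st) / ((steady_window[2] - steady_window[1]) / 1000)
  sfa <- if (peak_rate > 0 && steady_rate > 0) peak_rate / steady_rate
         else NA_real_
  list(initial_rate = initial_rate, peak_rate = peak_rate,
       steady_rate = steady_rate, sfa_ratio = sfa)
}

#' Sensitivity index
#'
#' Percentage change of firing rate relative to the control rate,
#' \eqn{SI = |FR_s - FR_c| / FR_c \times 100}.
#'
#' @param fr_s firing rate under the stimulus, Hz.
#' @param fr_c control firing rate, Hz (> 0).
#' @return sensitivity index, percent.
#' @examples
#' sensitivity_index(2.87, 1.43)   # 100.7
#' @export
sensitivity_index <- function(fr_s, fr_c) {
  if (any(fr_c <= 0)) stop("control firing rate must be > 0", call. = FALSE)
  abs(fr_s - fr_c) / fr_c * 100
}

#' Steady firing rate of a recorded run
#'
#' Spike count over the final measurement window divided by its duration.
#'
#' @param sim an \code{lc_sim}.
#' @param window_ms window length before the end of the recording, ms.
#' @return rate in Hz.
#' @export
steady_rate <- function(sim, window_ms = 2000) {
  spk <- detect_spikes(sim$V, sim$time)
  tend <- max(sim$time)
  sum(spk >= tend - window_ms & spk <= tend) / (window_ms / 1000)
}

#' Empirical spiking-onset scan
#'
#' Bisects a parameter (extracellular pH, intracellular pH, or applied
#' current) to the boundary between sustained spiking and quiescence.  The
#' sustained-spiking classifier is at least 5 spikes in the final 5 s of a
#' 10 s run (so pacemaker rates near 1 Hz count as spiking).  The scanned
#' parameter overrides the corresponding entry of the base condition.
#'
#' @param p an \code{lc_params}.
#' @param param one of \code{"pH_o"}, \code{"pH_i"}, \code{"I_app"}.
#' @param range two-element search interval.
#' @param cond base chemical condition.
#' @param resolution bisection resolution in the parameter's units.
#' @param sim_ms run length, ms.
#' @param record_dt sampling interval, ms.
#' @return list with \code{boundary} (NA when both ends classify alike),
#'   \code{spiking_at} (logical classification at the range ends).
#' @export
spiking_onset_scan <- function(p, param = c("pH_o", "pH_i", "I_app"), range,
                               cond = "N", resolution = 1e-3,
                               sim_ms = 10000, record_dt = 0.1) {
  param <- match.arg(param)
  base <- lc_condition(cond)
  classify <- function(x) {
    cnd <- base
    ia <- 0
    if (param == "I_app") ia <- x else cnd[[param]] <- x
    sim <- run_protocol(protocol_constant(cnd, ia, sim_ms,
                                          record_dt = record_dt), p)
    spk <- detect_spikes(sim$V, sim$time)
    sum(spk >= sim_ms - 5000) >= 5
  }
  lo <- range[1]; hi <- range[2]
  s_lo <- classify(lo); s_hi <- classify(hi)
  if (s_lo == s_hi)
    return(list(boundary = NA_real_, spiking_at = c(s_lo, s_hi)))
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (classify(mid) == s_lo) lo <- mid else hi <- mid
  }
  list(boundary = (lo + hi) / 2, spiking_at = c(s_lo, s_hi))
}

#' Postinhibitory rebound and post-stimulation recovery
#'
#' Inspects a recorded run for the two firing-pattern signatures that follow
#' electrical (but not purely chemical) stimulation.  Postinhibitory rebound
#' (PIR): a burst of at least two spikes within 500 ms of the release from
#' the inhibitory segment, at an instantaneous rate exceeding the
#' pre-inhibition rate.  Post-stimulation recovery: a quiescent gap after the
#' excitatory segment ends (longer than 1.5 baseline inter-spike intervals)
#' followed by resumed tonic spiking.  An inhibitory segment is one with
#' hyperpolarizing applied current, or - for purely chemical protocols - one
#' during which spiking stops; the excitatory segment is the one following
#' it.
#'
#' @param sim an \code{lc_sim} recorded from \code{protocol}.
#' @param protocol the \code{lc_protocol} that produced \code{sim}.
#' @return list with logical \code{pir} and \code{recovery}, plus
#'   \code{pir_latency_ms} and \code{recovery_gap_ms} when present.
#' @export
detect_rebound_and_recovery <- function(sim, protocol) {
  stopifnot(inherits(sim, "lc_sim"), inherits(protocol, "lc_protocol"))
  segs <- protocol$segments
  bounds <- c(0, cumsum(vapply(segs, `[[`, 0, "duration")))
  if (abs(max(sim$time) - bounds[length(bounds)]) > 1)
    stop("simulation does not match the protocol's total duration", call. = FALSE)
  spk <- detect_spikes(sim$V, sim$time)
  seg_rate <- function(i) {
    n <- sum(spk >= bounds[i] & spk < bounds[i + 1])
    n / (segs[[i]]$duration / 1000)
  }
  ia <- vapply(segs, `[[`, 0, "I_app")
  inhib <- which(ia < 0)
  if (length(inhib) == 0) {
    rates <- vapply(seq_along(segs), seg_rate, numeric(1))
    inhib <- which(rates == 0 & seq_along(segs) > 1 & seq_along(segs) < length(segs))
  }
  out <- list(pir = FALSE, recovery = FALSE,
              pir_latency_ms = NA_real_, recovery_gap_ms = NA_real_)
  if (length(inhib) == 0) return(out)
  i <- inhib[1]
  release <- bounds[i + 1]
  pre <- spk[spk < bounds[i]]
  pre_rate <- if (length(pre) >= 2) 1000 / stats::median(diff(pre)) else 0
  burst <- spk[spk >= release & spk <= release + 500]
  if (length(burst) >= 2) {
    burst_rate <- 1000 / min(diff(burst))
    if (burst_rate > pre_rate) {
      out$pir <- TRUE
      out$pir_latency_ms <- burst[1] - release
    }
  }
  # recovery after the excitatory segment that follows
  if (i + 1 <= length(segs)) {
    stim_end <- bounds[i + 2]
    after <- spk[spk > stim_end]
    base_isi <- if (length(pre) >= 2) stats::median(diff(pre)) else Inf
    if (length(after) >= 3 && is.finite(base_isi)) {
      gap <- after[1] - stim_end
      if (gap > 1.5 * base_isi) {
        out$recovery <- TRUE
        out$recovery_gap_ms <- gap
      }
    }
  }
  out
}

#' Full spike-train feature set of a run
#'
#' @param sim an \code{lc_sim}.
#' @param peak_window,steady_window measurement windows, ms; defaults follow
#'   the package convention (peak = first 1 s of the recording, steady =
#'   last 2 s).
#' @param initial_rate unstimulated steady rate, Hz (optional).
#' @param dvdt_crit threshold slope criterion, mV/ms.
#' @return list combining spike times, morphology and rate statistics.
#' @export
spike_train_features <- function(sim, peak_window = NULL, steady_window = NULL,
                                 initial_rate = NA_real_, dvdt_crit = 10) {
  tend <- max(sim$time)
  t0 <- min(sim$time)
  if (is.null(peak_window)) peak_window <- c(t0, t0 + 1000)
  if (is.null(steady_window)) steady_window <- c(tend - 2000, tend)
  spk <- detect_spikes(sim$V, sim$time)
  morph <- if (length(spk) >= 2)
    ap_morphology(sim$V, sim$time, spk, dvdt_crit) else NULL
  rates <- rate_statistics(spk, peak_window, steady_window, initial_rate)
  c(list(spike_times = spk), morph, rates)
}
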