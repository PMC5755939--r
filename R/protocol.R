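#' Piecewise-constant stimulus protocol
#'
#' A protocol is an ordered list of segments, each holding constant applied
#' current and chemical condition for a given duration.  Condition changes
#' are instantaneous steps (no wash-in kinetics), matching the square
#' transitions of the experimental protocols being emulated.
#'
#' @param segments data.frame with columns \code{duration_ms},
#'   \code{i_app_nA} and \code{condition} (a preset name, or a list-column of
#'   \code{lc_condition} / (co2, pH_o, pH_i) triples).
#' @param record_dt sampling interval of the dense output, ms.
#' @return object of class \code{lc_protocol}.
#' @examples
#' stimulus_protocol(data.frame(duration_ms = c(5000, 5000, 5000),
#'                              i_app_nA = c(0, 0.1, 0),
#'                              condition = "N"))
#' @export
stimulus_protocol <- function(segments, record_dt = 0.05) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (any(!is.finite(segments$duration_ms)) || any(segments$duration_ms <= 0))
    stop("segment durations must be > 0", call. = FALSE)
  if (record_dt <= 0) stop("record_dt must be > 0", call. = FALSE)
  segs <- lapply(seq_len(nrow(segments)), function(i) {
    cnd <- if (is.list(segments$condition)) segments$condition[[i]]
           else segments$condition[i]
    list(duration = segments$duration_ms[i],
         I_app = segments$i_app_nA[i],
         condition = lc_condition(cnd))
  })
  structure(list(segments = segs, record_dt = record_dt),
            class = "lc_protocol")
}

#' Constant-stimulus protocol
#'
#' @param condition chemical condition (preset name or triple).
#' @param i_app applied current, nA (positive depolarizes).
#' @param duration_ms duration, ms.
#' @param record_dt sampling interval, ms.
#' @return an \code{lc_protocol} with a single segment.
#' @export
protocol_constant <- function(condition, i_app = 0, duration_ms = 10000,
                              record_dt = 0.05) {
  stimulus_protocol(data.frame(duration_ms = duration_ms, i_app_nA = i_app,
                               condition = I(list(lc_condition(condition)))),
                    record_dt = record_dt)
}

#' Canned experimental protocols
#'
#' Ships the stimulus protocols used throughout the model's characterization
#' as declarative YAML fixtures: \code{fig2} (0.1 nA depolarizing pulse under
#' normocapnia), \code{fig3} (CO2 step 5\% to 15\%), \code{fig4}
#' (hyperpolarizing then depolarizing current pulses), \code{fig5a}--
#' \code{fig5d} (constant chemical conditions from hypocapnic alkalosis to
#' hypercapnic acidosis), \code{fig6} (normocapnia / hypocapnic alkalosis /
#' hypercapnic acidosis sequence) and \code{fig8} (the four sensitivity
#' conditions in sequence).  Pulse durations are a free choice (they are not
#' part of the published protocols) and default to 5 s.
#'
#' @param name protocol name.
#' @param record_dt sampling interval, ms.
#' @return an \code{lc_protocol}.
#' @export
protocol_preset <- function(name, record_dt = 0.05) {
  path <- system.file("extdata", "protocols", paste0(name, ".yaml"),
                      package = "lcneuro")
  if (!nzchar(path))
    stop(sprintf("unknown protocol preset '%s'", name), call. = FALSE)
  read_protocol(path, record_dt = record_dt)
}

#' Read a protocol from a declarative YAML file
#'
#' Each segment lists \code{duration_ms}, \code{i_app_nA} and a
#' \code{condition} that is either a preset name or an explicit
#' \code{[co2_percent, pH_o, pH_i]} triple.
#'
#' @param path YAML file path.
#' @param record_dt sampling interval, ms.
#' @return an \code{lc_protocol}.
#' @export
read_protocol <- function(path, record_dt = 0.05) {
  doc <- yaml::read_yaml(path)
  segs <- lapply(doc$segments, function(s) {
    list(duration = s$duration_ms, I_app = s$i_app_nA,
         condition = lc_condition(s$condition))
  })
  df <- data.frame(duration_ms = vapply(segs, `[[`, 0, "duration"),
                   i_app_nA = vapply(segs, `[[`, 0, "I_app"))
  df$condition <- I(lapply(segs, `[[`, "condition"))
  stimulus_protocol(df, record_dt = doc$record_dt %||% record_dt)
}

#' Integrate the model through a protocol
#'
#' Runs the full ODE system segment by segment with a stiff variable-step
#' solver (lsoda, compiled right-hand side), carrying the state continuously
#' across segment boundaries.  A pre-equilibration phase (default 2 s of
#' simulated time, applied current zero, first segment's condition) precedes
#' the protocol so that every measurement window starts from the model's own
#' steady behavior; equilibration samples carry negative times and the
#' protocol proper starts at t = 0.
#'
#' @param protocol an \code{lc_protocol}.
#' @param p an \code{lc_params} object.
#' @param equil_ms pre-equilibration duration, ms (0 disables).
#' @param rtol,atol solver tolerances; \code{atol} is state-scaled
#'   internally (tighter on the calcium component, whose scale is ~1e-4 mM).
#' @param state optional starting state (defaults to
#'   \code{\link{initial_state}}).
#' @param keep_equil keep the equilibration samples in the output.
#' @return object of class \code{lc_sim}: a data.frame with columns
#'   \code{time}, \code{V}, all gates, \code{m_SK}, \code{Ca_in}, plus
#'   attributes \code{boundaries} (segment end times) and \code{protocol}.
#' @export
run_protocol <- function(protocol, p, equil_ms = 2000, rtol = 1e-6,
                         atol = 1e-9, state = NULL, keep_equil = FALSE) {
  stopifnot(inherits(protocol, "lc_protocol"))
  validate_params(p)
  dt <- protocol$record_dt
  y <- if (is.null(state)) initial_state(p) else state
  atol_vec <- rep(atol, 16)
  atol_vec[16] <- atol * 1e-3     # Ca_in lives around 1e-4 mM
  segs <- protocol$segments
  if (equil_ms > 0)
    segs <- c(list(list(duration = equil_ms, I_app = 0,
                        condition = segs[[1]]$condition, equil = TRUE)), segs)
  pieces <- vector("list", length(segs))
  t0 <- if (equil_ms > 0) -equil_ms else 0
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    times <- seq(0, sg$duration, by = dt)
    if (tail(times, 1) < sg$duration) times <- c(times, sg$duration)
    pv <- lc_build_parms(p, sg$condition, sg$I_app)
    sol <- deSolve::ode(y = y, times = times, func = "lc_derivs",
                        parms = pv, dllname = "lcneuro",
                        initfunc = "lc_initmod", method = "lsoda",
                        rtol = rtol, atol = atol_vec, maxsteps = 50000)
    di <- attr(sol, "istate")[1]
    if (!is.null(di) && di < 0)
      stop(sprintf("solver failure in segment %d (istate = %d) at V = %.2f mV",
                   i, di, y[1]), call. = FALSE)
    y <- sol[nrow(sol), -1]
    sol[, 1] <- sol[, 1] + t0
    t0 <- t0 + sg$duration
    pieces[[i]] <- if (i == 1) sol else sol[-1, , drop = FALSE]
  }
  keep <- if (keep_equil || equil_ms == 0) seq_along(segs)
          else seq_along(segs)[-1]
  if (!keep_equil && equil_ms > 0)
    pieces[[1]] <- pieces[[1]][nrow(pieces[[1]]), , drop = FALSE]
  out <- as.data.frame(do.call(rbind, pieces))
  names(out) <- c("time", lc_state_names())
  bounds <- cumsum(vapply(protocol$segments, `[[`, 0, "duration"))
  structure(out, class = c("lc_sim", "data.frame"),
            boundaries = bounds, record_dt = dt, protocol = protocol)
}

#' @export
print.lc_sim <- function(x, ...) {
  cat(sprintf("<lc_sim> %d samples, t = [%.1f, %.1f] ms, V range [%.1f, %.1f] mV\n",
              nrow(x), min(x$time), max(x$time), min(x$V), max(x$V)))
  invisible(x)
}

#' Locate and classify a resting state
#'
#' Searches for a fixed point of the full right-hand side at a given chemical
#' condition and applied current.  At a fixed point every gate sits at its
#' voltage steady state and the shell calcium balances influx against pump,
#' so the search reduces to a one-dimensional root in V (with a nested root
#' for calcium).  A located equilibrium is then classified by integrating
#' from a slightly perturbed start: if the trajectory spikes or fails to
#' return, the equilibrium is unstable and the model is \code{"oscillatory"}.
#'
#' @param p an \code{lc_params} object.
#' @param cond chemical condition.
#' @param I_app applied current, nA.
#' @param V_range search interval for the membrane potential, mV.
#' @return list with \code{status} (\code{"resting"}, \code{"oscillatory"}
#'   or \code{"indeterminate"}) and, when resting, the fixed-point
#'   \code{state}.
#' @export
steady_state_search <- function(p, cond, I_app = 0, V_range = c(-95, -25)) {
  cond <- lc_condition(cond)
  ca_star <- function(V) {
    st <- initial_state(p, V)
    st["Ca_in"] <- 0
    f <- function(Ca) {
      st["Ca_in"] <- Ca
      ICa <- with(lc_currents(st, cond, p), CaL + CaN)
      calcium_rhs(Ca, ICa, p$calcium)
    }
    hi <- 1
    if (f(0) <= 0) return(0)
    if (f(hi) > 0) return(NA_real_)      # influx exceeds maximal pump rate
    uniroot(f, c(0, hi), tol = 1e-12)$root
  }
  net <- function(V) {
    Ca <- ca_star(V)
    if (is.na(Ca)) return(NA_real_)
    st <- initial_state(p, V)
    st["Ca_in"] <- Ca
    st["m_SK"] <- sk_activation(Ca, p$calcium)
    sum(lc_currents(st, cond, p)) + I_app
  }
  grid <- seq(V_range[1], V_range[2], by = 0.5)
  fv <- vapply(grid, net, numeric(1))
  sgn <- sign(fv)
  flip <- which(diff(sgn[!is.na(sgn)]) != 0)
  ok <- which(!is.na(fv))
  if (length(flip) == 0) return(list(status = "indeterminate", state = NULL))
  i <- ok[flip[1]]
  Vfix <- uniroot(net, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  st <- initial_state(p, Vfix)
  st["Ca_in"] <- ca_star(Vfix)
  st["m_SK"] <- sk_activation(st[["Ca_in"]], p$calcium)
  pert <- st
  pert["V"] <- pert["V"] + 2
  sim <- run_protocol(protocol_constant(cond, I_app, 5000, record_dt = 0.1),
                      p, equil_ms = 0, state = pert)
  spk <- detect_spikes(sim$V, sim$time)
  back <- abs(sim$V[nrow(sim)] - Vfix) < 1
  status <- if (length(spk) == 0 && back) "resting" else "oscillatory"
  list(status = status, state = st, V = Vfix)
}
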