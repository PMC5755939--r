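# Shared fixtures: the default parameterization and memoized simulation runs
# (several tests interrogate the same trajectories; the model is
# deterministic so one integration per protocol suffices).

lc_test_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = lc_test_cache))
    assign(key, builder(), envir = lc_test_cache)
  get(key, envir = lc_test_cache)
}

default_params <- function() cached("params", lc_default_params)

# 10 s spontaneous run under normocapnia, fine sampling (morphology-grade)
sim_N <- function() cached("sim_N", function()
  run_protocol(protocol_constant("N", 0, 10000, record_dt = 0.05),
               default_params()))

# coarser constant runs for rate measurements
rate_run <- function(cond, i_app = 0, ms = 12000) {
  key <- paste0("rate_", paste(unlist(lc_condition(cond)), collapse = "_"),
                "_", i_app, "_", ms)
  cached(key, function()
    run_protocol(protocol_constant(cond, i_app, ms, record_dt = 0.1),
                 default_params()))
}

steady_rate_of <- function(cond, i_app = 0, ms = 12000)
  steady_rate(rate_run(cond, i_app, ms))

# mean-ISI rate over the last `win` ms (finer-grained than a windowed count)
isi_rate <- function(sim, win = 6000) {
  spk <- detect_spikes(sim$V, sim$time)
  spk <- spk[spk > max(sim$time) - win]
  if (length(spk) < 2) return(0)
  1000 / mean(diff(spk))
}

sfa_run <- function(name) {
  cached(paste0("sfa_", name), function()
    sfa_for_protocol_test(name, default_params()))
}

sfa_for_protocol_test <- function(name, p) {
  prot <- protocol_preset(name, record_dt = 0.05)
  sim <- run_protocol(prot, p)
  b <- attr(sim, "boundaries")
  spk <- detect_spikes(sim$V, sim$time)
  rate_statistics(spk, peak_window = c(b[1], b[1] + 1000),
                  steady_window = c(b[2] - 2000, b[2]))
}

# a channel parameter block by name
chan <- function(nm) default_params()$channels[[nm]]
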