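# Hill responses, the conductance scaling phi, and the condition presets.

test_that("hill_response has its midpoint, saturation and monotonicity", {
  expect_equal(hill_response(7.1, 7.1, 15), 0.5)
  expect_equal(hill_response(1e6, 5, 5), 1, tolerance = 1e-6)
  expect_lt(hill_response(1e-6, 5, 5), 1e-6)
  # frozen oracle: K_dr intracellular titration at control pH_i
  expect_equal(hill_response(7.25, 7.1, 15), 0.577763802622538, tolerance = 1e-12)
  s <- seq(0.5, 20, by = 0.1)
  expect_true(all(diff(hill_response(s, 5, 3)) > 0))
  expect_error(hill_response(-1, 5, 3), "> 0")
})

test_that("phi is 1 for non-chemosensitive channels and algebraic at midpoints", {
  for (cn in names(condition_presets())) {
    expect_identical(chemo_phi(cn, NULL), 1)
    expect_identical(chemo_phi(cn, chan("Na")$chemo), 1)   # Na: zero-weight row
  }
  # a single signal at its midpoint contributes w/2 in every evaluation form
  w <- list(w_pHi = 0.4, w_pHo = 0, w_CO2 = 0, pK_i = 7.25, pK_o = NA,
            co2_half = NA, h_i = 4, h_o = NA, h_c = NA)
  for (form in c("protonation", "printed", "ph_ratio"))
    expect_equal(chemo_phi("N", w, form), 1 - 0.4 / 2)
  # frozen oracle: K_A under normocapnia, as-printed evaluation form
  expect_equal(chemo_phi("N", chan("KA")$chemo, "printed"),
               0.469877551028116, tolerance = 1e-12)
})

test_that("phi deviations are additive across the three signals", {
  ka <- chan("KA")$chemo
  cl <- chan("CaL")$chemo
  for (w in list(ka, cl)) for (form in c("protonation", "printed")) {
    only <- function(keep) {
      out <- w
      for (f in setdiff(c("w_pHi", "w_pHo", "w_CO2"), keep)) out[[f]] <- 0
      out
    }
    cond <- condition_presets()$HA
    total <- chemo_phi(cond, w, form) - 1
    parts <- sum(vapply(c("w_pHi", "w_pHo", "w_CO2"), function(k)
      chemo_phi(cond, only(k), form) - 1, numeric(1)))
    expect_equal(total, parts, tolerance = 1e-12)
  }
})

test_that("phi is monotone in each signal with the weight's sign", {
  # acid-activated titration: phi falls as pH falls for positively weighted
  # channels (more inhibition with acid), in the default form
  ph <- seq(6.5, 8.0, by = 0.05)
  for (nm in c("Kdr", "KA", "TASK")) {
    w <- chan(nm)$chemo
    phis <- vapply(ph, function(x)
      chemo_phi(chemical_condition(5, x, x), w, "protonation"), numeric(1))
    expect_true(all(diff(phis) >= -1e-12), info = nm)
  }
  # CO2 saturation term: phi decreases with CO2 for CaL (positive weight)
  co2 <- seq(1, 25, by = 1)
  phis <- vapply(co2, function(x)
    chemo_phi(chemical_condition(x, 7.45, 7.25), chan("CaL")$chemo), numeric(1))
  expect_true(all(diff(phis) <= 1e-12))
})

test_that("condition presets are exactly the printed triples", {
  pr <- condition_presets()
  expect_equal(unlist(pr$N), c(co2_percent = 5, pH_o = 7.45, pH_i = 7.25))
  expect_equal(unlist(pr$IH), c(co2_percent = 15, pH_o = 7.45, pH_i = 7.25))
  expect_equal(unlist(pr$IA), c(co2_percent = 5, pH_o = 7.10, pH_i = 7.00))
  expect_equal(unlist(pr$HA), c(co2_percent = 15, pH_o = 7.10, pH_i = 7.00))
  # HA* differs from HA only in intracellular pH
  expect_equal(pr[["HA*"]]$co2_percent, pr$HA$co2_percent)
  expect_equal(pr[["HA*"]]$pH_o, pr$HA$pH_o)
  expect_equal(pr[["HA*"]]$pH_i, pr$N$pH_i)
  expect_equal(unlist(pr$HypoA), c(co2_percent = 2.5, pH_o = 7.55, pH_i = 7.30))
  expect_error(chemical_condition(0, 7.4, 7.2), "co2")
  expect_error(chemical_condition(5, 9.0, 7.2), "pH")
})

test_that("disabling the chemosensitive channels makes traces condition-invariant", {
  p <- lc_default_params(list(
    cell = list(g_task = 0),
    channels = list(Kdr = list(gbar = 0), KA = list(gbar = 0),
                    CaT = list(gbar = 0), CaL = list(gbar = 0),
                    BK = list(gbar = 0), Kir = list(gbar = 0))))
  s1 <- run_protocol(protocol_constant("N", 0.05, 3000, record_dt = 0.25), p,
                     equil_ms = 500)
  s2 <- run_protocol(protocol_constant("HA", 0.05, 3000, record_dt = 0.25), p,
                     equil_ms = 500)
  expect_identical(s1$V, s2$V)
  expect_identical(s1$Ca_in, s2$Ca_in)
})
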