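# Leak decomposition, the assembled right-hand side, and fixed points.

test_that("leak decomposition reproduces the closed-form conductances", {
  p <- default_params()
  lk <- p$leak
  # frozen arithmetic from R_in = 241.5 MOhm, V_r = -60, E_Cl = E_K = -93
  expect_equal(lk$g_total, 0.00414078674948240, tolerance = 1e-12)
  expect_equal(lk$g_K, 0.002)
  expect_equal(lk$g_Na, 0.000990188135745792, tolerance = 1e-12)
  expect_equal(lk$g_Cl, 0.00115059861373661, tolerance = 1e-12)
  # conservation holds with the TASK component removed
  lk0 <- leak_decomposition(modifyList(p$cell, list(g_task = 0)),
                            E_Na = 45, E_K = -93, E_Cl = -93)
  expect_equal(lk0$g_K + lk0$g_Na + lk0$g_Cl, lk0$g_total)
  # the three leaks rest at the conductance-weighted reversal mix = V_r
  mix <- (lk$g_K * -93 + lk$g_Na * 45 + lk$g_Cl * -93) / lk$g_total
  expect_equal(mix, p$cell$V_r, tolerance = 1e-10)
  bad <- modifyList(p$cell, list(g_task = 0.02))
  expect_error(leak_decomposition(bad, 45, -93, -93), "g_Cl")
})

test_that("a passive membrane settles at the leak reversal mix", {
  ov <- list(channels = list(
    Na = list(gbar = 0), Kdr = list(gbar = 0), KM = list(gbar = 0),
    KA = list(gbar = 0), CaT = list(gbar = 0), CaL = list(gbar = 0),
    CaN = list(gbar = 0), H = list(gbar = 0), Kir = list(gbar = 0),
    BK = list(gbar = 0), SK = list(gbar = 0),
    TASK = list(chemo = NULL)))
  p <- lc_default_params(ov)
  sim <- run_protocol(protocol_constant("N", 0, 2000, record_dt = 1), p,
                      equil_ms = 1000, state = initial_state(p, -75))
  lk <- p$leak
  mix <- (lk$g_K * -93 + lk$g_Na * 45 + lk$g_Cl * -93) / lk$g_total
  expect_equal(tail(sim$V, 1), mix, tolerance = 1e-6)
})

test_that("an inert membrane has a zero derivative everywhere", {
  ov <- list(cell = list(R_in = 1e12, g_task = 0), channels = list(
    Na = list(gbar = 0), Kdr = list(gbar = 0), KM = list(gbar = 0),
    KA = list(gbar = 0), CaT = list(gbar = 0), CaL = list(gbar = 0),
    CaN = list(gbar = 0), H = list(gbar = 0), Kir = list(gbar = 0),
    BK = list(gbar = 0), SK = list(gbar = 0)))
  p <- lc_default_params(ov)
  st <- initial_state(p)
  st["Ca_in"] <- 0
  st["m_SK"] <- sk_activation(0, p$calcium)
  dy <- membrane_rhs(st, 0, "N", p)
  expect_equal(unname(dy), rep(0, 16), tolerance = 1e-15)
})

test_that("the compiled RHS matches an independent term-by-term summation", {
  # The oracle below rebuilds the membrane equation from the parameter lists
  # with plain arithmetic (no package current/derivative functions).
  p <- default_params()
  cond <- condition_presets()$HA
  phi <- lc_phi_oracle(cond, p)
  set.seed(42)
  for (rep in 1:100) {
    st <- initial_state(p, runif(1, -90, -20))
    gates <- grep("\\.(m|h)$", names(st))
    st[gates] <- pmin(1, pmax(0, st[gates] + runif(length(gates), -0.2, 0.2)))
    st["m_SK"] <- runif(1)
    st["Ca_in"] <- 10^runif(1, -10, -6)
    dy <- membrane_rhs(st, 0.05, cond, p)
    ref <- rhs_oracle(st, 0.05, phi, p)
    expect_equal(unname(dy), unname(ref), tolerance = 1e-10)
  }
})

test_that("located resting fixed points satisfy the gate steady-state relations", {
  p <- default_params()
  ss <- steady_state_search(p, "N", I_app = -0.1)
  expect_identical(ss$status, "resting")
  st <- ss$state
  dy <- membrane_rhs(st, -0.1, "N", p)
  expect_equal(max(abs(dy)), 0, tolerance = 1e-6)
  for (nm in c("Na", "Kdr", "KA", "CaT")) {
    expect_equal(st[[paste0(nm, ".m")]],
                 gate_steady_state(st[["V"]], chan(nm)$activation),
                 tolerance = 1e-8)
  }
  # and the default model under normocapnia has no stable rest: it spikes
  expect_identical(steady_state_search(p, "N", 0)$status, "oscillatory")
})
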