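# Voltage-gating steady states, time constants and ohmic currents.
# Frozen reference values were computed with an independent high-precision
# scalar evaluator (30-digit arithmetic) before the implementation existed.

test_that("gating steady state is the logistic curve with printed parameters", {
  na <- chan("Na")$activation
  expect_equal(gate_steady_state(na$V_half, na), 0.5)
  expect_equal(gate_steady_state(-60, na), 0.0829550843780139, tolerance = 1e-12)
  # saturation
  expect_equal(gate_steady_state(200, na), 1, tolerance = 1e-6)
  expect_lt(gate_steady_state(-200, na), 1e-6)
  # inactivation curves (negative slope factor) decrease with V
  nah <- chan("Na")$inactivation
  expect_gt(gate_steady_state(-80, nah), gate_steady_state(-20, nah))
  expect_error(gate_steady_state(NaN, na), "non-finite")
  expect_error(gate_steady_state(-60, list(V_half = -30, k = 0)), "non-zero")
})

test_that("gating steady states are bounded in [0,1] over a wide voltage grid", {
  V <- seq(-150, 80, by = 0.5)
  for (nm in c("Na", "Kdr", "KM", "KA", "CaT", "CaL", "CaN", "H")) {
    for (side in c("activation", "inactivation")) {
      gp <- chan(nm)[[side]]
      if (is.null(gp)) next
      x <- gate_steady_state(V, gp)
      expect_true(all(x >= 0 & x <= 1), info = paste(nm, side))
      # strict monotonicity with the sign of k
      expect_true(all(sign(diff(x)) == sign(gp$k) | diff(x) == 0),
                  info = paste(nm, side))
    }
  }
})

test_that("time constants follow the gaussian / reciprocal-cosh kernels", {
  km <- chan("KM")$activation            # b = 0: constant tau
  expect_equal(gate_time_constant(c(-100, -60, 0), km), c(100, 100, 100))
  na <- chan("Na")$activation            # gaussian kernel
  expect_equal(gate_time_constant(-60, na), 0.0609060763951466, tolerance = 1e-12)
  kdr <- chan("Kdr")$activation          # cosh kernel
  expect_equal(gate_time_constant(-60, kdr), 1.02638775894500, tolerance = 1e-12)
  # both kernels peak at V_tau with value a + b, and never fall below a
  V <- seq(-150, 60, by = 1)
  for (gp in list(na, kdr)) {
    expect_equal(gate_time_constant(gp$V_tau, gp), gp$a + gp$b)
    expect_true(all(gate_time_constant(V, gp) >= gp$a))
  }
  # the two forms agree exactly at V = V_tau
  g1 <- modifyList(kdr, list(tau_form = "gaussian"))
  expect_equal(gate_time_constant(kdr$V_tau, kdr), gate_time_constant(g1$V_tau, g1))
  expect_error(gate_time_constant(-60, modifyList(kdr, list(k_tau = 0))),
               "k_tau")
})

test_that("channel current is ohmic, gated, and linear in phi and gbar", {
  na <- chan("Na")
  # V at reversal -> zero current for any gating state
  expect_equal(channel_current(na$E_rev, 0.3, 0.7, na, 1), 0)
  # closed gate
  expect_equal(channel_current(-60, 0, 0.5, na, 1), 0)
  # frozen arithmetic example: 0.594 * 0.5^3 * 0.5 * (45 - (-60))
  expect_equal(channel_current(-60, 0.5, 0.5, na, 1), 3.898125, tolerance = 1e-12)
  # linearity in phi and gbar
  i1 <- channel_current(-50, 0.4, 0.6, na, 0.3)
  expect_equal(channel_current(-50, 0.4, 0.6, na, 0.6), 2 * i1)
  na2 <- modifyList(na, list(gbar = 2 * na$gbar))
  expect_equal(channel_current(-50, 0.4, 0.6, na2, 0.3), 2 * i1)
  expect_error(channel_current(-60, 1.2, 0.5, na, 1), "outside")
  expect_error(channel_current(-60, 0.5, 0.5, na, -1), "phi")
  expect_error(channel_current(-60, 0.5, 0.5, chan("SK"), 1), "standard")
})

test_that("the inward rectifier follows its printed closed form", {
  # numerator zero at V = E_K + 36
  expect_equal(kir_current(-57, 0.1, -93), 0)
  # frozen oracle value at V = -60, E_K = -93, ZF/RT = 0.0394
  expect_equal(kir_current(-60, 1, -93, 0.0394), -0.00328403316443393,
               tolerance = 1e-12)
  # deep hyperpolarization limit: denominator -> 1
  V <- -400
  expect_equal(kir_current(V, 0.2, -93), 0.2 * (V + 93 - 36), tolerance = 2e-3)
  # rectification suppresses the depolarized branch
  expect_lt(abs(kir_current(-20, 1, -93)), 0.02)
})
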