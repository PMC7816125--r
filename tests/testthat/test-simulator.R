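test_that("integrator matches the closed-form cascade oracle in null mode", {
  tr <- simulate_circuit(circuit_params(), "null", t_end = 5)
  expect_lt(max(abs(tr$Ip - cascade_ip(tr$time))), 1e-6)
  expect_lt(max(abs(tr$Im - cascade_im(tr$time))), 1e-6)
  # and the exported closed form agrees with the hand-written one
  cf <- closed_form_cascade(c(0, 1, 5))
  expect_equal(cf$Im, cascade_im(c(0, 1, 5)), tolerance = 1e-12)
  expect_equal(cf$Ip, cascade_ip(c(0, 1, 5)), tolerance = 1e-12)
  expect_equal(closed_form_cascade(0)$Ip, 0)
  expect_equal(closed_form_cascade(1)$Im, 0.63212, tolerance = 1e-5)
  expect_equal(closed_form_cascade(1)$Ip, 0.26424, tolerance = 1e-5)
})

test_that("closed form handles distinct mRNA/protein decay rates", {
  p <- circuit_params(k4 = 2, k6 = 0.5)
  cf <- closed_form_cascade(c(0.3, 1, 4), p)
  # cross-check against direct integration (null mode never represses)
  tr <- simulate_circuit(p, "null", t_end = 4, extra_times = c(0.3, 1, 4))
  at <- traj_at(tr, c(0.3, 1, 4))
  expect_equal(at$Im, cf$Im, tolerance = 1e-7)
  expect_equal(at$Ip, cf$Ip, tolerance = 1e-7)
})

test_that("wildtype pre-activation phase equals the unrepressed cascade", {
  tr <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2)
  pre <- tr[tr$time < 0.39, ]
  expect_lt(max(abs(pre$Ip - cascade_ip(pre$time))), 1e-6)
})

test_that("switching events are localized at the analytic crossing times", {
  # pre-activation Ip(t) = 1-(1+t)e^-t, so Ip = k2 and Ip = k2 + A are
  # roots of (1+t)e^-t = 0.95 and 0.94
  t_i2 <- uniroot(function(t) (1 + t) * exp(-t) - 0.95, c(0.01, 2),
                  tol = 1e-12)$root
  t_chi <- uniroot(function(t) (1 + t) * exp(-t) - 0.94, c(0.01, 2),
                   tol = 1e-12)$root
  for (r in c(0.5, 5)) {
    ev <- locate_events(circuit_params(r = r), "wildtype", t_end = 5)
    expect_equal(ev$time[ev$name == "i2_onset"], t_i2, tolerance = 1e-3)
    expect_equal(ev$time[ev$name == "chi_activation"], t_chi,
                 tolerance = 1e-3)
  }
  expect_equal(nrow(locate_events(circuit_params(), "null", t_end = 5)), 0)
  # at the located event the triggering quantity sits on its threshold
  tr <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2)
  ev <- circuit_events(tr)
  at <- traj_at(tr, round(ev$time[ev$name == "i2_onset"], 9))
  expect_lt(abs(at$Ip - 0.05), 1e-8)
  at2 <- traj_at(tr, round(ev$time[ev$name == "chi_activation"], 9))
  expect_lt(abs(at2$I2 - 0.01), 1e-8)
})

test_that("trajectories start at rest, stay nonnegative, bounded, chi monotone", {
  for (r in c(0, 0.1, 5)) {
    tr <- simulate_circuit(circuit_params(r = r), "wildtype", t_end = 20,
                           grid_dt = 0.05)
    expect_equal(tr$Im[1], 0)
    expect_equal(tr$Ip[1], 0)
    expect_equal(tr$chi[1], 0)
    expect_true(all(tr$Im >= 0 & tr$Ip >= 0))
    expect_true(all(tr$Im <= 1 + 1e-9 & tr$Ip <= 1 + 1e-9))
    expect_true(all(tr$chi %in% c(0, 1)))
    if (r > 0) expect_true(all(diff(tr$chi) >= 0))  # latch never releases
    expect_true(all(diff(tr$time) > 0))
  }
})

test_that("long-run simulations settle at the cell-type steady states", {
  hap <- simulate_cell_type("haploid", t_end = 50, grid_dt = 0.1)
  dip <- simulate_cell_type("diploid", t_end = 50, grid_dt = 0.1)
  # oracle: brute-force bisection of the self-consistency map
  expect_equal(tail(hap$Ip, 1), bisect_fixed_point(5), tolerance = 1e-4)
  expect_equal(tail(dip$Ip, 1), bisect_fixed_point(0.1, lo = 0.06),
               tolerance = 1e-4)
  # without IRT2 both cell types fully activate IME1
  hap0 <- simulate_cell_type("haploid", mode = "null", t_end = 50,
                             grid_dt = 0.1)
  dip0 <- simulate_cell_type("diploid", mode = "null", t_end = 50,
                             grid_dt = 0.1)
  expect_equal(tail(hap0$Ip, 1), 1, tolerance = 1e-4)
  expect_equal(tail(dip0$Ip, 1), 1, tolerance = 1e-4)
  # r = 0: IRT1 never fires even with the latch set
  tr0 <- simulate_circuit(circuit_params(r = 0), "wildtype", t_end = 50,
                          grid_dt = 0.1)
  expect_true(all(tr0$I1 == 0))
  expect_equal(tail(tr0$Ip, 1), 1, tolerance = 1e-4)
})

test_that("adaptive result is stable under tolerance tightening and the
           fixed-step fallback converges to it", {
  a <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2)
  b <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2,
                        rtol = 1e-11, atol = 1e-13)
  expect_lt(abs(tail(a$Ip, 1) - tail(b$Ip, 1)), 1e-8)
  f1 <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2,
                         stepper = "rk4", dt = 2e-3)
  f2 <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2,
                         stepper = "rk4", dt = 1e-3)
  # fallback error is dominated by step-quantized latch switching: O(dt)
  e1 <- abs(tail(f1$Ip, 1) - tail(a$Ip, 1))
  e2 <- abs(tail(f2$Ip, 1) - tail(a$Ip, 1))
  expect_lt(e2, 1e-3)
  expect_lt(e2, e1 + 1e-12)
})

test_that("latch hysteresis: starvation step-down leaves chi set while r > 0", {
  sch <- data.frame(time = c(0, 3), level = c(1, 0))
  tr <- simulate_circuit(circuit_params(r = 5, s_schedule = sch),
                         "wildtype", t_end = 10)
  ev <- circuit_events(tr)
  t_act <- ev$time[ev$name == "chi_activation"]
  expect_length(t_act, 1)
  post <- tr[tr$time > t_act, ]
  expect_true(all(post$chi == 1))
  # late in the run Ip has decayed below k2, so I2 = 0 < A, yet chi = 1
  late <- tr[tr$time > 8, ]
  expect_true(all(late$I2 == 0))
  expect_true(all(late$chi == 1))
  expect_true(all(late$I1 == 1))          # I1 = r/(r + 0)
  expect_false("chi_deactivation" %in% ev$name)
})

test_that("latch releases once I2 < A when r = 0 (no I1 to hold it)", {
  sch <- data.frame(time = c(0, 3), level = c(1, 0))
  tr <- simulate_circuit(circuit_params(r = 0, s_schedule = sch),
                         "wildtype", t_end = 10)
  ev <- circuit_events(tr)
  expect_true("chi_deactivation" %in% ev$name)
  t_off <- ev$time[ev$name == "chi_deactivation"]
  expect_true(all(tr$chi[tr$time > t_off] == 0))
  # release happens where Ip decays through k2 + A
  at <- traj_at(tr, round(t_off, 9))
  expect_lt(abs(at$Ip - 0.06), 1e-6)
})

test_that("activating-only clamp latches at t = 0 and represses mildly", {
  tr <- simulate_circuit(circuit_params(r = 5), "activating_only",
                         t_end = 50, grid_dt = 0.1)
  ev <- circuit_events(tr)
  expect_equal(ev$time[ev$name == "chi_activation"], 0)
  expect_true(all(tr$I2[-1] == 0.01))
  # steady state: I1 = 5/5.05 fixed, Ip = 1/(1 + 10 * I1)
  expect_equal(tail(tr$Ip, 1), 1 / (1 + 10 * 5 / 5.05), tolerance = 1e-4)
})

test_that("simulate rejects invalid horizons and cell types", {
  expect_error(simulate_circuit(t_end = -1), "t_end")
  expect_error(simulate_circuit(t_end = 0), "t_end")
  expect_error(simulate_cell_type("triploid"), "arg")
})
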