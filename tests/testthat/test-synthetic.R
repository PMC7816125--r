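test_that("time-course generator is exact at zero noise and seed-stable", {
  tc0 <- generate_time_course(noise_sigma = 0, n_rep = 2, seed = 3,
                              times = c(0.5, 1, 2, 4))
  expect_identical(tc0$observed, tc0$true)
  # truth equals the simulated trajectory at the design times
  tr <- simulate_circuit(circuit_params(), "wildtype", t_end = 4,
                         extra_times = c(0.5, 1, 2, 4))
  at <- traj_at(tr, c(0.5, 1, 2, 4))
  expect_equal(unique(tc0$true[tc0$variable == "Ip"]), at$Ip)

  a <- generate_time_course(seed = 42, times = c(1, 2), n_rep = 2)
  b <- generate_time_course(seed = 42, times = c(1, 2), n_rep = 2)
  expect_identical(a$observed, b$observed)
  c <- generate_time_course(seed = 43, times = c(1, 2), n_rep = 2)
  expect_false(identical(a$observed, c$observed))
  # generation does not disturb the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_time_course(seed = 1, times = 1,
                                               n_rep = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("lognormal noise has the stated scale (CLT bound on log means)", {
  sigma <- 0.1; n_rep <- 200
  tc <- generate_time_course(noise_sigma = sigma, n_rep = n_rep,
                             times = c(1, 3), seed = 7)
  by_pt <- split(tc, interaction(tc$time, tc$variable, drop = TRUE))
  for (g in by_pt) {
    expect_lt(abs(mean(log(g$observed)) - log(g$true[1])),
              3 * sigma / sqrt(n_rep))
  }
})

test_that("generator rejects invalid designs", {
  expect_error(generate_time_course(times = c(2, 1)), "increasing")
  expect_error(generate_time_course(noise_sigma = -1), "noise_sigma")
  expect_error(generate_time_course(n_rep = 0), "n_rep")
})

test_that("cell populations match Poisson-tail oracles at the 30-copy cut", {
  # wildtype haploid: Im* ~ 0.0946, mean copies ~ 4.73 -> tail above 30
  # is negligible
  lam_wt <- 50 * fixed_point(circuit_params(r = 5))$Im_star
  expect_lt(pois_tail_gt(30, lam_wt), 1e-10)
  pop_wt <- generate_cell_population(2000, cell_r_sampler("point", r = 5),
                                     mode = "wildtype", seed = 1)
  expect_equal(fraction_high(pop_wt), 0)
  expect_equal(mean(pop_wt$copies), lam_wt, tolerance = 0.05)

  # no IRT2: Im* = 1, mean copies 50, nearly every cell is a high expresser
  tail_null <- pois_tail_gt(30, 50)
  expect_gt(tail_null, 0.95)
  pop_null <- generate_cell_population(2000, cell_r_sampler("point", r = 5),
                                       mode = "null", seed = 2)
  expect_gt(fraction_high(pop_null), 0.95)
  expect_equal(fraction_high(pop_null), tail_null, tolerance = 0.02)

  # the contrast the readout is built to expose
  expect_gt(fraction_high(pop_null), fraction_high(pop_wt))
})

test_that("cell population determinism, empty case and copy scaling", {
  a <- generate_cell_population(100, seed = 5)
  b <- generate_cell_population(100, seed = 5)
  expect_identical(a$copies, b$copies)

  e <- generate_cell_population(0)
  expect_equal(nrow(e), 0)
  expect_true(is.na(fraction_high(e)))

  # expectation scales linearly in copy_scale (Poisson mean)
  m <- vapply(c(20, 40, 80), function(cs) {
    mean(generate_cell_population(3000, cell_r_sampler("point", r = 5),
                                  mode = "null", copy_scale = cs,
                                  seed = 11)$copies)
  }, 1)
  expect_equal(m / c(20, 40, 80), rep(1, 3), tolerance = 0.03)
})

test_that("mixture and lognormal Rme1 samplers shape the population", {
  mix <- cell_r_sampler("mixture", weights = c(0.5, 0.5),
                        components = list(cell_r_sampler("point", r = 5),
                                          cell_r_sampler("point", r = 0.1)))
  pop <- generate_cell_population(2000, mix, mode = "wildtype",
                                  seed = 21)
  # half the cells sit at the repressed state, half near Im* ~ 0.79:
  # only the diploid-like half exceeds the threshold appreciably
  fh <- fraction_high(pop)
  oracle_dip <- pois_tail_gt(30, 50 * bisect_fixed_point(0.1, lo = 0.06))
  expect_equal(fh, 0.5 * oracle_dip, tolerance = 0.05)

  ln <- cell_r_sampler("lognormal", meanlog = log(0.1), sdlog = 0.3)
  pop2 <- generate_cell_population(500, ln, seed = 31)
  expect_gt(length(unique(pop2$r)), 400)   # genuine per-cell heterogeneity
  expect_true(all(pop2$copies >= 0))
})
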