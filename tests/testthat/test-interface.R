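test_that("trajectory TSV round-trips values and events", {
  tr <- simulate_circuit(circuit_params(r = 5), "wildtype", t_end = 2,
                         grid_dt = 0.1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  lines <- readLines(f)
  expect_equal(lines[1], paste(c("time", "s", "chi", "I1", "I2", "It",
                                 "Im", "Ip"), collapse = "\t"))
  expect_true(any(grepl("^# event i2_onset ", lines)))
  expect_true(any(grepl("^# event chi_activation ", lines)))

  back <- read_trajectory(f)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(circuit_events(back)$name, circuit_events(tr)$name)
  # serialize(read(serialize(x))) is byte-identical: the 9-significant-digit
  # representation is a fixed point of the write/read cycle
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(back, f2)
  expect_identical(readLines(f2), lines)
  expect_equal(back$Ip, tr$Ip, tolerance = 1e-8)
})

test_that("config files round-trip and default to the published table", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenario = "simulate"), f)
  cfg <- read_config(f)
  expect_equal(cfg$params$k1, 5)
  expect_equal(cfg$params$A, 0.01)
  expect_equal(cfg$mode, "wildtype")

  cfg$mode <- "null"; cfg$seed <- 7L
  f2 <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f2)
  cfg2 <- read_config(f2)
  expect_equal(cfg2$mode, "null")
  expect_equal(cfg2$seed, 7L)
  expect_equal(unclass(cfg2$params)[1:8], unclass(cfg$params)[1:8])
  expect_equal(cfg2$params$s_schedule, cfg$params$s_schedule)
})

test_that("invalid configs are rejected with the offending path", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenario = "simulate", typo_key = 1), f)
  expect_error(read_config(f), "typo_key")
  yaml::write_yaml(list(parameters = list(k4 = 0)), f)
  expect_error(read_config(f), "parameters")
  yaml::write_yaml(list(parameters = list(k9 = 1)), f)
  expect_error(read_config(f), "k9")
  yaml::write_yaml(list(scenario = "frobnicate"), f)
  expect_error(read_config(f), "scenario")
})

test_that("CLI simulate writes a trajectory whose tail matches the cascade", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "traj.tsv")
  status <- run_cli(c("simulate", "--mode", "null", "--t-end", "2",
                      "--out", out))
  expect_equal(status, 0L)
  expect_true(file.exists(out))
  tr <- read_trajectory(out)
  expect_equal(tail(tr$Ip, 1), 1 - 3 * exp(-2), tolerance = 1e-6)
  expect_true(file.exists(paste0(out, ".manifest.json")))
  man <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_equal(man$parameters$k1, 5)
  expect_equal(man$mode, "null")
})

test_that("CLI dose emits the exact half-max point", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "dose.tsv")
  status <- run_cli(c("dose", "--mode", "wildtype", "--out", out))
  expect_equal(status, 0L)
  d <- utils::read.delim(out)
  expect_equal(d$Ip_star[d$r == 0.25], 0.5, tolerance = 1e-9)
})

test_that("CLI rejects bad usage without writing output", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "nope.tsv")
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--t-end", "-1", "--out", out))), 2L)
  expect_false(file.exists(out))
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(character())), 2L)
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--mode", "bogus"))), 2L)
})

test_that("CLI synth + fit pipeline round-trips through files", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "tc.tsv")
  status <- run_cli(c("synth", "--what", "timecourse", "--sigma", "0",
                      "--n-rep", "1", "--seed", "3", "--out", out))
  expect_equal(status, 0L)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".meta.json")))
  fit_out <- file.path(dir, "fit.json")
  status <- run_cli(c("fit", "--data", out, "--free", "k1,k3",
                      "--out", fit_out))
  expect_equal(status, 0L)
  res <- jsonlite::read_json(fit_out)
  expect_equal(res$estimates$k1, 5, tolerance = 1e-2)
  expect_equal(res$estimates$k3, 10, tolerance = 1e-2)
})

test_that("CLI synth cells reports the derepression contrast", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cells.tsv")
  status <- suppressMessages(
    run_cli(c("synth", "--what", "cells", "--mode", "null",
              "--n-cells", "500", "--seed", "2", "--out", out)))
  expect_equal(status, 0L)
  meta <- jsonlite::read_json(paste0(out, ".meta.json"))
  expect_gt(meta$fraction_high, 0.95)
})
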