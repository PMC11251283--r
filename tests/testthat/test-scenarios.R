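test_that("the reference preset carries the documented values", {
  sc <- scenario_paper()
  p <- sc$parameters
  expect_identical(p[["alpha"]], 0.0514)
  expect_identical(p[["beta"]], 1.02e-9)
  expect_identical(p[["gamma"]], 0.1)
  expect_identical(p[["phi"]], 1e-7)
  expect_identical(p[["rho"]], 1e-8)
  expect_identical(p[["kappa"]], 0.02)
  expect_identical(p[["mu"]], 480)
  expect_identical(p[["omega"]], 0.24)
  expect_identical(p[["lam"]], 2e-7)
  expect_identical(p[["d"]], 3e-4)
  expect_identical(p[["psi"]], 3e-4)
  expect_identical(p[["a"]], 0.04)
  expect_identical(as.numeric(sc$initial), c(1.0, 0.8, 0.3, 0.4, 0.4, 0.3))
  expect_identical(sc$orders$xi, 0.95)
  expect_identical(sc$orders$eta, 0.95)
  expect_identical(sc$solver$dt, 0.05)
  expect_identical(sc$solver$t_end, 100)
})

test_that("random scenarios are reproducible, positive, and leave the RNG alone", {
  a <- scenario_random(123)
  b <- scenario_random(123)
  expect_identical(unclass(a$parameters), unclass(b$parameters))
  expect_identical(unclass(a$initial), unclass(b$initial))
  expect_false(identical(unclass(a$parameters),
                         unclass(scenario_random(124)$parameters)))
  for (seed in 1:20) {
    sc <- scenario_random(seed)
    expect_true(all(unclass(sc$parameters) > 0))
    expect_true(all(unclass(sc$initial) > 0))
  }
  # global RNG state is preserved
  set.seed(42)
  before <- .Random.seed
  invisible(scenario_random(7))
  expect_identical(.Random.seed, before)
})

test_that("forced-R0 scenarios land in [1.5, 5]", {
  for (seed in 1:25) {
    p <- scenario_random(seed, force_R0_above_1 = TRUE)$parameters
    R0 <- reproduction_number(p)
    expect_gte(R0, 1.5)
    expect_lte(R0, 5)
  }
})

test_that("YAML and JSON configs round-trip bit-exactly", {
  sc <- scenario_random(42)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_config(sc, f)
    sc2 <- read_config(f)
    expect_identical(unclass(sc$parameters), unclass(sc2$parameters),
                     info = ext)
    expect_identical(unclass(sc$initial), unclass(sc2$initial), info = ext)
    expect_identical(sc$orders$xi, sc2$orders$xi, info = ext)
    expect_identical(sc$orders$eta, sc2$orders$eta, info = ext)
    expect_identical(sc$solver$dt, sc2$solver$dt, info = ext)
    expect_identical(sc$solver$t_end, sc2$solver$t_end, info = ext)
    expect_identical(sc$name, sc2$name, info = ext)
    unlink(f)
  }
  expect_error(read_config(tempfile(fileext = ".yaml")), "not found")
})

test_that("a config missing keys is rejected with the missing names", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(alpha = 1, beta = 1), f)
  expect_error(read_config(f), "missing keys.*T0")
  unlink(f)
})

test_that("trajectory CSV round-trips exactly with the fixed column layout", {
  sc <- scenario_paper()
  traj <- simulate_ffm(sc$parameters, sc$initial, sc$orders,
                       solver_config(dt = 0.05, t_end = 5))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  header <- readLines(f, n = 1)
  expect_identical(header, "t,T,C,D,IL2,IL12,Z")
  back <- read_trajectory_csv(f, sc)
  expect_equal(back$times, traj$times, tolerance = 1e-15)
  expect_equal(back$states, traj$states, tolerance = 1e-15)
  unlink(f)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("t,T,C", "0,1,2"), f2)
  expect_error(read_trajectory_csv(f2), "columns")
  unlink(f2)
})

test_that("run_scenario dispatches between the two integrators", {
  sc <- scenario_paper()
  sc$solver <- solver_config(dt = 0.05, t_end = 2)
  t1 <- run_scenario(sc)
  expect_identical(t1$method, "ffm_newton")
  t2 <- run_scenario(sc, classical = TRUE)
  expect_identical(t2$method, "classical_lsoda")
})

test_that("CLI simulate writes a trajectory CSV and returns status 0", {
  out <- tempfile(fileext = ".csv")
  code <- suppressMessages(
    run_cli(c("simulate", "--preset", "paper", "--dt", "0.05",
              "--t-end", "2", "--out", out)))
  expect_identical(code, 0L)
  expect_true(file.exists(out))
  df <- utils::read.csv(out)
  expect_identical(colnames(df), c("t", "T", "C", "D", "IL2", "IL12", "Z"))
  expect_identical(nrow(df), 41L)
  unlink(out)
})

test_that("CLI subcommands produce valid JSON reports", {
  for (cmd in c("equilibria", "sensitivity", "stability")) {
    out <- tempfile(fileext = ".json")
    code <- suppressMessages(run_cli(c(cmd, "--out", out)))
    expect_identical(code, 0L, info = cmd)
    rep <- jsonlite::read_json(out)
    expect_true("R0" %in% names(rep) || "dfe_numeric" %in% names(rep),
                info = cmd)
    unlink(out)
  }
  out <- tempfile(fileext = ".json")
  code <- suppressMessages(
    run_cli(c("chaos-control", "--gains", "1,0.5038,3,4.0027,5.0027,6",
              "--out", out)))
  expect_identical(code, 0L)
  rep <- jsonlite::read_json(out)
  expect_identical(rep$controlled$verdict, "stable")
  unlink(out)
})

test_that("CLI check-wellposedness and convergence run end to end", {
  out <- tempfile(fileext = ".json")
  code <- suppressMessages(
    run_cli(c("check-wellposedness", "--dt", "0.05", "--t-end", "5",
              "--out", out)))
  expect_identical(code, 0L)
  rep <- jsonlite::read_json(out)
  expect_true(isTRUE(rep$positive))
  unlink(out)

  out2 <- tempfile(fileext = ".json")
  code <- suppressMessages(
    run_cli(c("convergence", "--xi", "1", "--eta", "1",
              "--base-dt", "0.1", "--out", out2)))
  expect_identical(code, 0L)
  rep2 <- jsonlite::read_json(out2)
  expect_true(isTRUE(rep2$monotone))
  unlink(out2)
})

test_that("CLI returns status 2 on validation failures", {
  expect_identical(suppressMessages(run_cli(character())), 2L)
  expect_identical(suppressMessages(run_cli("frobnicate")), 2L)
  expect_identical(
    suppressMessages(run_cli(c("simulate", "--preset", "nope",
                               "--out", tempfile()))), 2L)
  expect_identical(
    suppressMessages(run_cli(c("simulate", "--xi", "7",
                               "--out", tempfile()))), 2L)
  expect_identical(suppressMessages(run_cli(c("simulate", "--out"))), 2L)
  expect_identical(
    suppressMessages(run_cli(c("chaos-control", "--gains", "1,2",
                               "--out", tempfile()))), 2L)
  # simulate without --out is a validation error too
  expect_identical(suppressMessages(run_cli("simulate")), 2L)
})

test_that("CLI returns status 1 on integration blow-up", {
  f <- tempfile(fileext = ".yaml")
  blow <- scenario(
    name = "blowup",
    parameters = model_parameters(alpha = 100, beta = 1e-4, gamma = 0.1,
                                  phi = 0.1, rho = 0.1, kappa = 0.1,
                                  mu = 1, omega = 0.1, lam = 0.1,
                                  d = 0.1, psi = 0.1, a = 0.1),
    initial = state_vector(1, 1, 1, 1, 1, 1),
    orders = fractional_orders(1, 1),
    solver = solver_config(dt = 10, t_end = 1000))
  write_config(blow, f)
  code <- suppressMessages(
    run_cli(c("simulate", "--config", f, "--out", tempfile())))
  expect_identical(code, 1L)
  unlink(f)
})

test_that("the installed CLI wrapper script is present", {
  script <- system.file("cli", "ffmtumor.R", package = "ffmtumor")
  expect_true(nzchar(script))
  expect_true(any(grepl("run_cli", readLines(script))))
})
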