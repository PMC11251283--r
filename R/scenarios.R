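#' Scenario presets
#'
#' A scenario bundles parameters, initial state, operator orders and solver
#' configuration into a single runnable object.
#'
#' @param name Scenario name.
#' @param parameters [model_parameters()].
#' @param initial [state_vector()].
#' @param orders [fractional_orders()].
#' @param solver [solver_config()].
#' @return A list of class `ffm_scenario`.
#' @export
scenario <- function(name, parameters, initial, orders, solver) {
  structure(list(name = name,
                 parameters = as_parameters(parameters),
                 initial = as_state(initial),
                 orders = orders,
                 solver = solver),
            class = "ffm_scenario")
}

#' @export
print.ffm_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (xi = %g, eta = %g, dt = %g, t_end = %g)\n",
              x$name, x$orders$xi, x$orders$eta, x$solver$dt, x$solver$t_end))
  print(x$parameters)
  cat("initial state:\n")
  print(format(unclass(x$initial), digits = 10), quote = FALSE)
  invisible(x)
}

#' Reference simulation scenario
#'
#' The built-in reference scenario of the model: a weakly immunogenic
#' regime (tumor-CD8+ couplings of order 1e-7 and below, strong dendritic
#' source mu = 480) in which the reproduction number is far below one and
#' the dendritic compartment relaxes to its source/sink balance
#' \eqn{\mu/(\omega+\lambda) \approx 2000} while all other compartments
#' decay. Defaults: \eqn{\xi = \eta = 0.95}, \eqn{\Delta t = 0.05},
#' horizon 100 (time units are treated as days; no unit is asserted by the
#' model).
#'
#' @return An `ffm_scenario`.
#' @export
scenario_paper <- function() {
  scenario(
    name = "paper",
    parameters = model_parameters(
      alpha = 0.0514, beta = 0.00000000102, gamma = 0.1, phi = 0.0000001,
      rho = 0.00000001, kappa = 0.02, mu = 480, omega = 0.24,
      lam = 0.0000002, d = 0.0003, psi = 0.0003, a = 0.04),
    initial = state_vector(T = 1.0, C = 0.8, D = 0.3, IL2 = 0.4,
                           IL12 = 0.4, Z = 0.3),
    orders = fractional_orders(xi = 0.95, eta = 0.95),
    solver = solver_config(dt = 0.05, t_end = 100))
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  force(code)
}

#' Random well-posed scenario generator
#'
#' Draws a positive parameter set log-uniformly within two decades of the
#' reference scenario values (and an initial state within one decade of the
#' reference initial state), deterministically per seed. With
#' `force_R0_above_1` the CD8+-dendritic interaction rate `rho` is rescaled
#' so the reproduction number lands uniformly in 1.5 to 5, producing
#' endemic-branch test systems.
#'
#' @param seed Integer seed.
#' @param force_R0_above_1 Rescale `rho` to push \eqn{R_0} into the interval 1.5 to 5.
#' @return An `ffm_scenario`.
#' @export
scenario_random <- function(seed, force_R0_above_1 = FALSE) {
  ref <- scenario_paper()
  with_preserved_rng({
    set.seed(as.integer(seed))
    pref <- unclass(ref$parameters)
    draw <- pref * 10^stats::runif(12, -2, 2)
    names(draw) <- names(pref)
    if (force_R0_above_1) {
      target <- stats::runif(1, 1.5, 5)
      draw[["rho"]] <- target * draw[["kappa"]] *
        (draw[["lam"]] + draw[["omega"]]) / draw[["mu"]]
    }
    x0 <- unclass(ref$initial) * 10^stats::runif(6, -1, 1)
    scenario(
      name = sprintf("random-%d%s", as.integer(seed),
                     if (force_R0_above_1) "-endemic" else ""),
      parameters = do.call(model_parameters, as.list(draw)),
      initial = do.call(state_vector, as.list(x0)),
      orders = ref$orders,
      solver = ref$solver)
  })
}

.scenario_to_list <- function(sc) {
  p <- unclass(sc$parameters)
  x0 <- unclass(sc$initial)
  c(as.list(p),
    list(T0 = x0[["T"]], C0 = x0[["C"]], D0 = x0[["D"]],
         IL2_0 = x0[["IL2"]], IL12_0 = x0[["IL12"]], Z0 = x0[["Z"]],
         xi = sc$orders$xi, eta = sc$orders$eta,
         dt = sc$solver$dt, t_end = sc$solver$t_end,
         store_every = sc$solver$store_every,
         name = sc$name))
}

.scenario_from_list <- function(lst) {
  need <- c(.param_names, "T0", "C0", "D0", "IL2_0", "IL12_0", "Z0")
  missing <- setdiff(need, names(lst))
  if (length(missing)) {
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  }
  scenario(
    name = if (!is.null(lst$name)) lst$name else "config",
    parameters = do.call(model_parameters, lst[.param_names]),
    initial = state_vector(lst$T0, lst$C0, lst$D0, lst$IL2_0,
                           lst$IL12_0, lst$Z0),
    orders = fractional_orders(
      xi = if (!is.null(lst$xi)) lst$xi else 1,
      eta = if (!is.null(lst$eta)) lst$eta else 1),
    solver = solver_config(
      dt = if (!is.null(lst$dt)) lst$dt else 0.05,
      t_end = if (!is.null(lst$t_end)) lst$t_end else 100,
      store_every = if (!is.null(lst$store_every)) lst$store_every else 1L))
}

#' Read and write scenario configurations
#'
#' Scenario files are YAML or JSON (chosen by file extension) with the keys
#' `alpha, beta, gamma, phi, rho, kappa, mu, omega, lam, d, psi, a` for the
#' parameters, `T0, C0, D0, IL2_0, IL12_0, Z0` for the initial state, and
#' optional `xi, eta, dt, t_end, store_every, name`. Numbers are written at
#' full double precision so a load-save-load round trip is exact.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param sc Scenario to write.
#' @return `read_config` returns an `ffm_scenario`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .scenario_from_list(lst)
}

#' @rdname read_config
#' @export
write_config <- function(sc, path) {
  stopifnot(inherits(sc, "ffm_scenario"))
  lst <- .scenario_to_list(sc)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # I(17) = 17 *significant* digits, enough to round-trip any double
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17))
  } else {
    # full-precision numeric representation so round trips are lossless
    fmt <- lapply(lst, function(v) {
      if (is.numeric(v)) {
        s <- sprintf("%.17g", v)
        class(s) <- "verbatim"
        s
      } else v
    })
    yaml::write_yaml(fmt, path)
  }
  invisible(path)
}

#' Write and read trajectory CSV files
#'
#' Columns are exactly `t,T,C,D,IL2,IL12,Z` with a header row and full
#' double precision (17 significant digits) so downstream checks are
#' bit-stable.
#'
#' @param traj An `ffm_trajectory`.
#' @param path Output path.
#' @param sc Optional scenario supplying parameters/orders when reading
#'   (needed by the monitors).
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns an `ffm_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ffm_trajectory"))
  df <- as.data.frame(traj)
  mat <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                character(nrow(df)))
  mat <- rbind(colnames(df), mat)
  writeLines(apply(mat, 1, paste, collapse = ","), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, sc = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", .state_names)
  if (!identical(colnames(df), need)) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  }
  states <- as.matrix(df[, .state_names])
  p <- if (!is.null(sc)) sc$parameters else NULL
  orders <- if (!is.null(sc)) sc$orders else fractional_orders(1, 1)
  cfg <- if (!is.null(sc)) sc$solver else NULL
  .new_trajectory(df$t, states, orders, p, cfg, method = "from_csv")
}

#' Run a scenario
#'
#' Convenience wrapper dispatching on the operator orders: the classical
#' reference integrator when `xi = eta = 1` and `classical = TRUE`,
#' otherwise the fractal-fractional scheme.
#'
#' @param sc An `ffm_scenario`.
#' @param classical Use the adaptive classical integrator (ignores the
#'   fractional orders).
#' @return An `ffm_trajectory`.
#' @export
run_scenario <- function(sc, classical = FALSE) {
  stopifnot(inherits(sc, "ffm_scenario"))
  if (classical) {
    simulate_classical(sc$parameters, sc$initial, sc$solver)
  } else {
    simulate_ffm(sc$parameters, sc$initial, sc$orders, sc$solver)
  }
}
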