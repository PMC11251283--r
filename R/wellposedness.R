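#' Sup-norm envelopes
#'
#' Componentwise sup norms \eqn{\|\cdot\|_\infty} of the six compartments,
#' plus a bound `n_prime` on \eqn{\|n'\|_\infty}, the derivative of the
#' clock function of the global (Riemann-Stieltjes) derivative. The default
#' `n_prime = 1` corresponds to the classical clock \eqn{n(t) = t}; for the
#' fractal clock \eqn{n(t) = t^\eta} supply the sup of
#' \eqn{\eta t^{\eta-1}} over the run.
#'
#' @param sup_T,sup_C,sup_D,sup_IL2,sup_IL12,sup_Z Nonnegative bounds.
#' @param n_prime Positive bound on \eqn{\|n'\|_\infty}.
#' @return A list of class `ffm_supnorms`.
#' @export
supnorms <- function(sup_T, sup_C, sup_D, sup_IL2, sup_IL12, sup_Z,
                     n_prime = 1) {
  s <- c(sup_T = sup_T, sup_C = sup_C, sup_D = sup_D, sup_IL2 = sup_IL2,
         sup_IL12 = sup_IL12, sup_Z = sup_Z)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("sup norms must be nonnegative and finite")
  }
  if (!is.numeric(n_prime) || length(n_prime) != 1L || !is.finite(n_prime) ||
      n_prime <= 0) {
    stop("n_prime must be positive (the clock derivative never vanishes)")
  }
  structure(c(as.list(s), list(n_prime = n_prime)), class = "ffm_supnorms")
}

#' Empirical sup norms from a trajectory
#'
#' Componentwise maximum of the absolute state over the stored grid, with
#' `n_prime = 1`. Idempotent by construction.
#'
#' @param traj An `ffm_trajectory`.
#' @return An `ffm_supnorms` object.
#' @export
supnorms_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "ffm_trajectory"))
  if (length(traj$times) == 0L) stop("trajectory is empty")
  m <- apply(abs(traj$states), 2, max)
  supnorms(m[["T"]], m[["C"]], m[["D"]], m[["IL2"]], m[["IL12"]], m[["Z"]])
}

#' Linear-growth and Lipschitz constants with the uniqueness condition
#'
#' Evaluates the six linear-growth constants \eqn{K_1..K_6}, the six
#' Lipschitz constants \eqn{\bar K_1..\bar K_6} of the clocked vector
#' field, and the six growth-condition ratios whose maximum below one
#' certifies a unique solution:
#' \deqn{K_1 = 2\|n'\|^2\|T\|^2\alpha^2,\quad
#'       K_2 = 2\|n'\|^2\kappa^2\|C\|^2,\quad
#'       K_3 = 2\|n'\|^2\mu^2,}
#' \deqn{K_4 = 2\|n'\|^2\|D\|^2\lambda^2,\quad
#'       K_5 = 2\|n'\|^2 d^2\|IL_2\|^2,\quad
#'       K_6 = 4\|n'\|^2\psi^2\|IL_{12}\|^2,}
#' \deqn{\bar K_1 = 2\|n'\|^2\left(2(\alpha^2+\alpha^2\beta^2\|T\|^2) +
#'       3(\alpha^2\beta^2\|T\|^2+\phi^2\|C\|^2+\gamma^2)\right),}
#' \deqn{\bar K_2 = 3\|n'\|^2(\phi^2\|T\|^2+\rho^2\|D\|^2+\kappa^2),\quad
#'       \bar K_3 = 3\|n'\|^2(\rho^2\|C\|^2+\lambda^2+\omega^2),}
#' \deqn{\bar K_4 = \|n'\|^2 d^2,\quad \bar K_5 = \|n'\|^2\psi^2,\quad
#'       \bar K_6 = \|n'\|^2 a^2.}
#' The two sup norms appearing in the composite \eqn{\bar K_1} are both
#' taken as the single trajectory sup (they are never distinguished
#' operationally). Ratios with zero denominator are reported as `Inf`
#' (condition fails), not as an error.
#'
#' @param p Parameters.
#' @param s An `ffm_supnorms` object.
#' @return A list of class `ffm_growth_report` with `K` (K1..K6), `Kbar`
#'   (Kbar1..Kbar6), `ratios` (the six condition ratios), `uniqueness_max`,
#'   `unique` (logical: maximum ratio < 1).
#' @export
growth_and_lipschitz <- function(p, s) {
  p <- as_parameters(p)
  stopifnot(inherits(s, "ffm_supnorms"))
  n2 <- s$n_prime^2
  sT <- s$sup_T; sC <- s$sup_C; sD <- s$sup_D
  s2 <- s$sup_IL2; s12 <- s$sup_IL12
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; gamma <- p[["gamma"]]
  phi <- p[["phi"]]; rho <- p[["rho"]]; kappa <- p[["kappa"]]
  mu <- p[["mu"]]; omega <- p[["omega"]]; lam <- p[["lam"]]
  d <- p[["d"]]; psi <- p[["psi"]]; a <- p[["a"]]

  K <- c(K1 = 2 * n2 * sT^2 * alpha^2,
         K2 = 2 * n2 * kappa^2 * sC^2,
         K3 = 2 * n2 * mu^2,
         K4 = 2 * n2 * sD^2 * lam^2,
         K5 = 2 * n2 * d^2 * s2^2,
         K6 = 4 * n2 * psi^2 * s12^2)
  Kbar <- c(Kbar1 = 2 * n2 * (2 * (alpha^2 + alpha^2 * beta^2 * sT^2) +
                              3 * (alpha^2 * beta^2 * sT^2 +
                                   phi^2 * sC^2 + gamma^2)),
            Kbar2 = n2 * 3 * (phi^2 * sT^2 + rho^2 * sD^2 + kappa^2),
            Kbar3 = n2 * 3 * (rho^2 * sC^2 + lam^2 + omega^2),
            Kbar4 = n2 * d^2,
            Kbar5 = n2 * psi^2,
            Kbar6 = n2 * a^2)
  rat <- function(num, den) if (den == 0) Inf else num / den
  ratios <- c(
    r1 = rat(3 * (alpha^2 * beta^2 * sT^2 + gamma^2 + phi^2 * sC^2),
             alpha^2 * sT^2),
    r2 = rat(2 * (phi^2 * sT^2 + rho^2 * sD^2), kappa^2 * sC^2),
    r3 = rat(3 * (rho^2 * sC^2 + omega^2 + lam^2), mu^2),
    r4 = rat(d^2, lam^2 * sD^2),
    r5 = rat(psi^2, d^2 * s2^2),
    r6 = rat(a^2, psi^2 * s12^2))
  umax <- max(ratios)
  structure(list(K = K, Kbar = Kbar, ratios = ratios,
                 uniqueness_max = umax, unique = umax < 1),
            class = "ffm_growth_report")
}

#' @export
print.ffm_growth_report <- function(x, ...) {
  cat("Linear-growth constants K1..K6:\n")
  print(format(x$K, digits = 6), quote = FALSE)
  cat("Lipschitz constants Kbar1..Kbar6:\n")
  print(format(x$Kbar, digits = 6), quote = FALSE)
  cat("Condition ratios:\n")
  print(format(x$ratios, digits = 6), quote = FALSE)
  cat(sprintf("max ratio = %.6g -> %s solution\n", x$uniqueness_max,
              if (x$unique) "unique" else "uniqueness not certified"))
  invisible(x)
}

#' Uniqueness condition
#'
#' Maximum of the six growth-condition ratios of [growth_and_lipschitz()];
#' a unique solution is certified when it is below one.
#'
#' @param p Parameters.
#' @param s An `ffm_supnorms` object.
#' @return A list with `uniqueness_max` and `unique`.
#' @export
uniqueness_condition <- function(p, s) {
  g <- growth_and_lipschitz(p, s)
  list(uniqueness_max = g$uniqueness_max, unique = g$unique)
}

#' Positivity and boundedness monitor
#'
#' Scans a trajectory for negative excursions below `-1e-9` (positivity)
#' and for unbounded growth: any component whose magnitude exceeds ten
#' times its natural scale \eqn{\max(x_0, \mu/(\omega+\lambda))}.
#'
#' @param traj An `ffm_trajectory`.
#' @return A list with `violations` (data frame `time`, `compartment`,
#'   `value` for every positivity breach), `bound_exceeded` (same layout
#'   for boundedness breaches), and logical flags `positive`, `bounded`.
#' @export
monitor_trajectory <- function(traj) {
  stopifnot(inherits(traj, "ffm_trajectory"))
  if (length(traj$times) == 0L) stop("trajectory is empty")
  st <- traj$states
  p <- traj$parameters
  x0 <- st[1L, ]
  scale <- pmax(abs(x0), p[["mu"]] / (p[["omega"]] + p[["lam"]])) * 10

  neg <- which(st < -1e-9, arr.ind = TRUE)
  violations <- data.frame(
    time = traj$times[neg[, 1L]],
    compartment = .state_names[neg[, 2L]],
    value = st[neg])
  big <- which(abs(st) > matrix(scale, nrow(st), 6L, byrow = TRUE),
               arr.ind = TRUE)
  bound_exceeded <- data.frame(
    time = traj$times[big[, 1L]],
    compartment = .state_names[big[, 2L]],
    value = st[big])
  list(violations = violations,
       bound_exceeded = bound_exceeded,
       positive = nrow(violations) == 0L,
       bounded = nrow(bound_exceeded) == 0L)
}
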