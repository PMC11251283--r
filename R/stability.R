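#' Feedback control gains
#'
#' Nonnegative gains \eqn{\omega_1, \dots, \omega_6} of the linear feedback
#' law that subtracts \eqn{\omega_i (x_i - x_i^*)} from each equation,
#' shifting the Jacobian diagonal by \eqn{-\omega_i}. Zero gains reproduce
#' the uncontrolled system.
#'
#' @param w1,w2,w3,w4,w5,w6 Nonnegative gains.
#' @return Named numeric vector of class `ffm_gains`.
#' @export
control_gains <- function(w1 = 0, w2 = 0, w3 = 0, w4 = 0, w5 = 0, w6 = 0) {
  g <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5, w6 = w6)
  if (!is.numeric(g) || length(g) != 6L || any(!is.finite(g)) || any(g < 0)) {
    stop("gains must be six nonnegative finite numbers")
  }
  structure(g, class = "ffm_gains")
}

.spectrum_report <- function(ev) {
  stopifnot(length(ev) == 6L)
  ev <- ev[order(Re(ev))]
  max_real <- max(Re(ev))
  verdict <- if (max_real < -1e-12) "stable"
             else if (abs(max_real) <= 1e-12) "marginal"
             else "unstable"
  structure(list(eigenvalues = ev, max_real = max_real, verdict = verdict),
            class = "ffm_spectrum")
}

#' @export
print.ffm_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum (%s), max real part %.6g\n", x$verdict, x$max_real))
  print(format(x$eigenvalues, digits = 8), quote = FALSE)
  invisible(x)
}

#' Closed-form spectrum at the disease-free equilibrium
#'
#' The Jacobian at the disease-free point is lower triangular up to an
#' uncoupled block, and its six eigenvalues have closed forms:
#' \eqn{-a}, \eqn{-d}, \eqn{\alpha - \gamma}, \eqn{-\psi},
#' \eqn{-\lambda - \omega}, and
#' \eqn{(\mu\rho - \kappa(\lambda+\omega)) / (\lambda+\omega)}.
#' The disease-free state is locally asymptotically stable iff both
#' sign-indefinite entries are negative, i.e. \eqn{R_0 < 1} and
#' \eqn{\alpha < \gamma}.
#'
#' @param p Parameters.
#' @return An `ffm_spectrum` report (eigenvalues sorted by real part;
#'   verdict `stable` iff max real part < -1e-12, `marginal` within
#'   +/-1e-12).
#' @export
dfe_spectrum_closed_form <- function(p) {
  p <- as_parameters(p)
  s <- p[["lam"]] + p[["omega"]]
  ev <- c(-p[["a"]], -p[["d"]], p[["alpha"]] - p[["gamma"]], -p[["psi"]],
          -s, (-p[["kappa"]] * p[["lam"]] + p[["mu"]] * p[["rho"]] -
               p[["kappa"]] * p[["omega"]]) / s)
  .spectrum_report(as.complex(ev))
}

#' Numeric spectrum at an equilibrium
#'
#' Dense eigendecomposition of the Jacobian evaluated at the equilibrium
#' state.
#'
#' @param eq An `ffm_equilibrium` (from [equilibria()]) or a state vector.
#' @param p Parameters.
#' @return An `ffm_spectrum` report.
#' @export
spectrum_at <- function(eq, p) {
  x <- if (inherits(eq, "ffm_equilibrium")) eq$state else as_state(eq)
  ev <- eigen(model_jacobian(x, p), only.values = TRUE)$values
  .spectrum_report(as.complex(ev))
}

#' Spectrum of the feedback-controlled system
#'
#' Eigenvalues of \eqn{J(x^*) - \mathrm{diag}(\omega_1, \dots, \omega_6)}.
#' At the disease-free equilibrium the matrix is lower triangular, so the
#' eigenvalues equal the shifted diagonal entries exactly
#' (\eqn{\alpha-\gamma-\omega_1}, \eqn{\mu\rho/(\lambda+\omega)-\kappa-
#' \omega_2}, \eqn{-\lambda-\omega-\omega_3}, \eqn{-d-\omega_4},
#' \eqn{-\psi-\omega_5}, \eqn{-a-\omega_6}); at interior points they are
#' computed numerically. Because the subdiagonal couplings are weak
#' relative to the diagonal gaps, each eigenvector is dominated by a single
#' compartment; `axis` records that association.
#'
#' @param eq Equilibrium (as in [spectrum_at()]).
#' @param p Parameters.
#' @param gains [control_gains()].
#' @return An `ffm_spectrum` report with an extra element `axis`: for each
#'   eigenvalue, the compartment carrying the largest eigenvector component.
#' @export
controlled_spectrum <- function(eq, p, gains = control_gains()) {
  stopifnot(inherits(gains, "ffm_gains"))
  x <- if (inherits(eq, "ffm_equilibrium")) eq$state else as_state(eq)
  J <- model_jacobian(x, p) - diag(as.numeric(gains))
  es <- eigen(J)
  ord <- order(Re(es$values))
  ev <- es$values[ord]
  vec <- es$vectors[, ord, drop = FALSE]
  axis <- .state_names[apply(abs(vec), 2, which.max)]
  rep <- .spectrum_report(as.complex(ev))
  # .spectrum_report re-sorts identically (stable order by real part)
  rep$axis <- axis
  rep
}

#' Lyapunov function and its decomposition at a state
#'
#' The Volterra-type Lyapunov function
#' \deqn{L = \sum_i \left( x_i - x_i^* - x_i^* \log(x_i/x_i^*) \right)}
#' is nonnegative and vanishes exactly at the reference equilibrium. Its
#' derivative along trajectories splits as \eqn{\dot L = \Sigma - \Omega}
#' into a collecting aggregate \eqn{\Sigma} and a dissipating aggregate
#' \eqn{\Omega}; the terms of both are implemented verbatim from their
#' reference decomposition (including the sign-ambiguous
#' \eqn{+\psi IL_{12} - \psi IL_{12}^*} pair inside \eqn{\Sigma}), because
#' the decision rule being tested is "\eqn{\Sigma < \Omega} implies
#' \eqn{\dot L < 0}", not a cleaned-up derivation.
#'
#' @param x Strictly positive state.
#' @param eq Strictly positive reference equilibrium.
#' @param p Parameters.
#' @return A list of class `ffm_lyapunov` with `L`, `Sigma`, `Omega`,
#'   `dL_sign` (sign of `Sigma - Omega`).
#' @export
lyapunov_terms <- function(x, eq, p) {
  p <- as_parameters(p)
  x <- as_state(x)
  xs <- if (inherits(eq, "ffm_equilibrium")) eq$state else as_state(eq)
  if (any(x <= 0)) stop("state must be componentwise positive")
  if (any(xs <= 0)) stop("reference equilibrium must be componentwise positive")

  L <- sum(x - xs - xs * log(x / xs))

  T <- x[["T"]]; C <- x[["C"]]; D <- x[["D"]]
  IL2 <- x[["IL2"]]; IL12 <- x[["IL12"]]; Z <- x[["Z"]]
  Ts <- xs[["T"]]; Cs <- xs[["C"]]; Ds <- xs[["D"]]
  I2s <- xs[["IL2"]]; I12s <- xs[["IL12"]]; Zs <- xs[["Z"]]
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; gamma <- p[["gamma"]]
  phi <- p[["phi"]]; rho <- p[["rho"]]; kappa <- p[["kappa"]]
  mu <- p[["mu"]]; omega <- p[["omega"]]; lam <- p[["lam"]]
  d <- p[["d"]]; psi <- p[["psi"]]; a <- p[["a"]]

  Sigma <- alpha * (T - Ts)^2 / T +
    phi * Cs * (T - Ts)^2 / T +
    phi * T * (C - Cs)^2 / C +
    rho * D * (C - Cs)^2 / C +
    mu +
    rho * Cs * (D - Ds)^2 / D +
    lam * D +
    lam * Ds * I2s / IL2 +
    d * IL2 +
    d * I2s * I12s / IL12 +
    psi * IL12 - psi * I12s +
    psi * I12s * Zs / Z

  Omega <- alpha * beta * (T - Ts)^3 / T +
    gamma * (T - Ts)^2 / T +
    phi * C * (T - Ts)^2 / T +
    phi * Ts * (C - Cs)^2 / C +
    rho * Ds * (C - Cs)^2 / C +
    kappa * (C - Cs)^2 / C +
    mu * Ds / D +
    rho * C * (D - Ds)^2 / D +
    omega * (D - Ds)^2 / D +
    lam * (D - Ds)^2 / D +
    lam * D * I2s / IL2 +
    lam * Ds +
    d * (IL2 - I2s)^2 / IL2 +
    d * I2s +
    d * IL2 * I12s / IL12 +
    psi * (IL12 - I12s)^2 / IL12 +
    psi * IL12 * Zs / Z +
    a * (Z - Zs)^2 / Z

  structure(list(L = L, Sigma = Sigma, Omega = Omega,
                 dL_sign = sign(Sigma - Omega)),
            class = "ffm_lyapunov")
}

#' Lyapunov global-stability scan along a trajectory
#'
#' Evaluates [lyapunov_terms()] at every stored trajectory point against a
#' reference equilibrium, reports the fraction of steps at which
#' \eqn{\Sigma < \Omega}, and checks whether the Lyapunov value is
#' non-increasing (finite differences along the grid) wherever the
#' \eqn{\Sigma < \Omega} certificate holds. Steps with a nonpositive
#' component are skipped and counted.
#'
#' @param traj An `ffm_trajectory`.
#' @param eq Strictly positive reference equilibrium.
#' @param p Parameters.
#' @param tol Nonpositive slack for the "non-increasing" finite-difference
#'   check (absorbs discretisation noise).
#' @return A list with `records` (data frame: `t`, `L`, `Sigma`, `Omega`,
#'   `certified`), `frac_certified`, `frac_L_decreasing_where_certified`,
#'   `n_skipped`.
#' @export
global_stability_scan <- function(traj, eq, p, tol = 1e-10) {
  stopifnot(inherits(traj, "ffm_trajectory"))
  n <- length(traj$times)
  L <- Sg <- Om <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    xi <- traj$states[i, ]
    if (any(xi <= 0)) { skipped <- skipped + 1L; next }
    rec <- lyapunov_terms(xi, eq, p)
    L[i] <- rec$L; Sg[i] <- rec$Sigma; Om[i] <- rec$Omega
  }
  certified <- !is.na(Sg) & (Sg < Om)
  dL <- diff(L)
  cert_step <- certified[-n] & certified[-1] & !is.na(dL)
  frac_dec <- if (any(cert_step)) {
    scale <- pmax(abs(L[-n]), 1)
    mean(dL[cert_step] <= tol * scale[cert_step])
  } else NA_real_
  list(records = data.frame(t = traj$times, L = L, Sigma = Sg, Omega = Om,
                            certified = certified),
       frac_certified = mean(certified, na.rm = FALSE),
       frac_L_decreasing_where_certified = frac_dec,
       n_skipped = skipped)
}
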