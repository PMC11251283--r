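#' Right-hand side of the tumor-immune model
#'
#' Evaluates the six time derivatives of the TCD-IL2-IL12-Z system:
#' \deqn{T' = \alpha T(1-\beta T) - \gamma T - \phi C T}
#' \deqn{C' = \phi C T + \rho C D - \kappa C}
#' \deqn{D' = \mu - \rho C D - \omega D - \lambda D}
#' \deqn{IL_2' = \lambda D - d\, IL_2}
#' \deqn{IL_{12}' = d\, IL_2 - \psi IL_{12}}
#' \deqn{Z' = \psi IL_{12} - a Z}
#'
#' The system is autonomous; `t` is accepted for solver compatibility only.
#'
#' @param t Time (ignored by the vector field).
#' @param x State (coercible via [state_vector()]).
#' @param p Parameters (coercible via [model_parameters()]).
#' @return Named numeric vector of the six derivatives.
#' @export
model_rhs <- function(t, x, p) {
  p <- as_parameters(p)
  xv <- unlist(x)
  if (is.null(names(xv)) && length(xv) == 6L) names(xv) <- .state_names
  bad <- !is.finite(xv)
  if (any(bad)) {
    stop("non-finite state component: ",
         paste(names(xv)[bad], collapse = ", "))
  }
  T <- xv[["T"]]; C <- xv[["C"]]; D <- xv[["D"]]
  IL2 <- xv[["IL2"]]; IL12 <- xv[["IL12"]]; Z <- xv[["Z"]]
  c(T    = p[["alpha"]] * T * (1 - p[["beta"]] * T) - p[["gamma"]] * T -
           p[["phi"]] * C * T,
    C    = p[["phi"]] * C * T + p[["rho"]] * C * D - p[["kappa"]] * C,
    D    = p[["mu"]] - p[["rho"]] * C * D - p[["omega"]] * D - p[["lam"]] * D,
    IL2  = p[["lam"]] * D - p[["d"]] * IL2,
    IL12 = p[["d"]] * IL2 - p[["psi"]] * IL12,
    Z    = p[["psi"]] * IL12 - p[["a"]] * Z)
}

#' Jacobian matrix of the vector field
#'
#' Analytic 6x6 Jacobian of [model_rhs()] derived from the governing
#' equations. Note the inhibitor row couples only to IL-12 and itself
#' (\eqn{\partial Z'/\partial IL_2 = 0}).
#'
#' @param x State.
#' @param p Parameters.
#' @return 6x6 numeric matrix with row/column names of the compartments.
#' @export
model_jacobian <- function(x, p) {
  p <- as_parameters(p)
  x <- as_state(x)
  T <- x[["T"]]; C <- x[["C"]]; D <- x[["D"]]
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  J[1, 1] <- p[["alpha"]] - 2 * p[["alpha"]] * p[["beta"]] * T -
             p[["gamma"]] - p[["phi"]] * C
  J[1, 2] <- -p[["phi"]] * T
  J[2, 1] <- p[["phi"]] * C
  J[2, 2] <- p[["phi"]] * T + p[["rho"]] * D - p[["kappa"]]
  J[2, 3] <- p[["rho"]] * C
  J[3, 2] <- -p[["rho"]] * D
  J[3, 3] <- -(p[["rho"]] * C + p[["omega"]] + p[["lam"]])
  J[4, 3] <- p[["lam"]]
  J[4, 4] <- -p[["d"]]
  J[5, 4] <- p[["d"]]
  J[5, 5] <- -p[["psi"]]
  J[6, 5] <- p[["psi"]]
  J[6, 6] <- -p[["a"]]
  J
}

#' Equilibrium points of the model
#'
#' Computes all fixed points of the vector field in closed form:
#' \itemize{
#'   \item the disease-free point \eqn{(0, 0, \mu/(\omega+\lambda),
#'     \mu\lambda/(d(\omega+\lambda)), \mu\lambda/(\psi(\omega+\lambda)),
#'     \mu\lambda/(a(\omega+\lambda)))}, always returned;
#'   \item the interior (endemic) branches, roots of the fixed-point
#'     quadratic via the discriminant
#'     \eqn{\mathbb{A} = \sqrt{4\beta\alpha\mu\rho^2\phi^2 +
#'     (\rho\alpha(\phi-\beta\kappa)+\phi(-\rho\gamma+\phi(\omega+\lambda)))^2}};
#'     both \eqn{\pm\mathbb{A}} sign branches are evaluated and a branch is
#'     returned iff all six components are strictly positive;
#'   \item the tumor-free boundary branch with \eqn{T = 0},
#'     \eqn{D = \kappa/\rho}, \eqn{C} from the dendritic balance, returned
#'     when positive (it exists iff the reproduction number exceeds one).
#' }
#'
#' Every returned point is checked against the residual invariant
#' \eqn{\|F(x^*)\|_\infty < 10^{-8}(1+\max|x^*|)}.
#'
#' @param p Parameters.
#' @return A list of `ffm_equilibrium` objects, each with elements `state`,
#'   `kind` (`"disease_free"`, `"endemic_interior"` or `"boundary"`),
#'   `residual`, and `discriminant_A` (interior branches only, else `NA`).
#' @export
equilibria <- function(p) {
  p <- as_parameters(p)
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; gamma <- p[["gamma"]]
  phi <- p[["phi"]]; rho <- p[["rho"]]; kappa <- p[["kappa"]]
  mu <- p[["mu"]]; omega <- p[["omega"]]; lam <- p[["lam"]]
  d <- p[["d"]]; psi <- p[["psi"]]; a <- p[["a"]]

  out <- list()
  # Newton refinement of a closed-form seed: the closed forms are exact in
  # exact arithmetic, but for extreme parameter magnitudes their evaluation
  # cancels catastrophically in doubles. A polished root is accepted only
  # if it stays finite, keeps the seed's sign pattern, moves by at most a
  # small relative distance, and improves the residual.
  polish <- function(state) {
    x0 <- as.numeric(state)
    x <- x0
    for (it in 1:40) {
      f <- model_rhs(0, x, p)
      if (max(abs(f)) == 0) break
      step <- tryCatch(solve(model_jacobian(x, p), f),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      xn <- x - step
      if (any(!is.finite(xn))) break
      x <- xn
      if (max(abs(step) / (1 + abs(x))) < 1e-15) break
    }
    ok <- all(is.finite(x)) &&
      all(sign(x) == sign(x0) | x0 == 0) &&
      max(abs(x - x0) / (1 + abs(x0))) <= 0.1 &&
      max(abs(model_rhs(0, x, p))) <= max(abs(model_rhs(0, x0, p)))
    do.call(state_vector, as.list(if (ok) x else x0))
  }
  mk <- function(state, kind, A = NA_real_) {
    res <- max(abs(model_rhs(0, state, p)))
    eq <- structure(list(state = state, kind = kind, residual = res,
                         discriminant_A = A), class = "ffm_equilibrium")
    if (res >= 1e-8 * (1 + max(abs(state)))) {
      stop("closed-form equilibrium failed its residual check (", kind, ")")
    }
    eq
  }

  Ddfe <- mu / (omega + lam)
  dfe <- state_vector(0, 0, Ddfe, lam * Ddfe / d, lam * Ddfe / psi,
                      lam * Ddfe / a)
  out[[1]] <- mk(dfe, "disease_free")

  # interior branches: T from the quadratic, remaining components chained
  A <- sqrt(4 * beta * alpha * mu * rho^2 * phi^2 +
            (rho * alpha * (phi - beta * kappa) +
             phi * (-rho * gamma + phi * (omega + lam)))^2)
  P <- kappa * rho * beta * alpha + phi * rho * alpha - phi * rho * gamma +
       phi^2 * lam + omega * phi^2
  for (s in c(1, -1)) {
    Ts <- (P - s * A) / (2 * rho * beta * alpha * phi)
    Cs <- -(kappa * rho * beta * alpha - phi * rho * alpha +
            phi * rho * gamma + phi^2 * lam + omega * phi^2 - s * A) /
          (2 * phi^2 * rho)
    Ds <- (kappa * rho * beta * alpha - phi * rho * alpha +
           phi * rho * gamma - phi^2 * lam - omega * phi^2 + s * A) /
          (2 * beta * rho^2 * alpha)
    comp <- c(Ts, Cs, Ds, lam * Ds / d, lam * Ds / psi, lam * Ds / a)
    if (all(is.finite(comp)) && all(comp > 0)) {
      st <- polish(do.call(state_vector, as.list(comp)))
      out[[length(out) + 1L]] <- mk(st, "endemic_interior", A)
    }
  }

  # tumor-free boundary branch: rho*D = kappa, C from the dendritic balance
  Db <- kappa / rho
  Cb <- (mu - (omega + lam) * Db) / (rho * Db)
  comp <- c(0, Cb, Db, lam * Db / d, lam * Db / psi, lam * Db / a)
  if (all(is.finite(comp)) && Cb > 0) {
    st <- polish(do.call(state_vector, as.list(comp)))
    out[[length(out) + 1L]] <- mk(st, "boundary")
  }
  out
}

#' @export
print.ffm_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (%s), residual %.3e\n", x$kind, x$residual))
  print(format(unclass(x$state), digits = 10), quote = FALSE)
  if (is.finite(x$discriminant_A)) {
    cat(sprintf("discriminant A = %.10g\n", x$discriminant_A))
  }
  invisible(x)
}

#' Basic reproduction number
#'
#' Closed form \eqn{R_0 = \mu\rho / (\kappa(\lambda+\omega))}: the expected
#' number of secondary CD8+ activations produced near the disease-free state,
#' thresholding CD8+ T-cell persistence.
#'
#' @param p Parameters.
#' @return Scalar \eqn{R_0}.
#' @export
reproduction_number <- function(p) {
  p <- as_parameters(p)
  den <- p[["kappa"]] * (p[["lam"]] + p[["omega"]])
  if (den <= 0) stop("kappa * (lam + omega) must be positive")
  p[["mu"]] * p[["rho"]] / den
}

#' Reproduction number via the next-generation matrix
#'
#' Independent construction with infected set {C}: the new-activation term
#' \eqn{\rho C D} linearised at the disease-free state gives
#' \eqn{F = \rho\mu/(\lambda+\omega)} and the transition \eqn{V = \kappa};
#' the spectral radius of \eqn{F V^{-1}} must equal the closed form.
#'
#' @param p Parameters.
#' @return Scalar spectral radius of the next-generation matrix.
#' @export
reproduction_number_ngm <- function(p) {
  p <- as_parameters(p)
  Fm <- matrix(p[["rho"]] * p[["mu"]] / (p[["lam"]] + p[["omega"]]), 1, 1)
  Vm <- matrix(p[["kappa"]], 1, 1)
  max(abs(eigen(Fm %*% solve(Vm), only.values = TRUE)$values))
}

#' Sensitivity of the reproduction number
#'
#' Analytic partial derivatives of \eqn{R_0 = \mu\rho/(\kappa(\lambda+\omega))}
#' with respect to the five parameters it contains, plus normalised
#' elasticities \eqn{(p/R_0)\,\partial R_0/\partial p}. Signs follow the
#' algebra: increasing the dendritic source `mu` or the interaction rate
#' `rho` raises \eqn{R_0}, while `kappa`, `lam` and `omega` lower it. (Note:
#' a transcription elsewhere lists the `mu` derivative as negative although
#' its own formula \eqn{\rho/(\kappa(\lambda+\omega))} is positive; the
#' formula is used.)
#'
#' @param p Parameters.
#' @return A data frame of class `ffm_sensitivity` with columns `parameter`,
#'   `derivative`, `sign`, `elasticity`.
#' @export
sensitivity_indices <- function(p) {
  p <- as_parameters(p)
  mu <- p[["mu"]]; rho <- p[["rho"]]; kappa <- p[["kappa"]]
  lam <- p[["lam"]]; omega <- p[["omega"]]
  s <- lam + omega
  R0 <- mu * rho / (kappa * s)
  der <- c(mu    = rho / (kappa * s),
           rho   = mu / (kappa * s),
           kappa = -mu * rho / (kappa^2 * s),
           lam   = -mu * rho / (kappa * s^2),
           omega = -mu * rho / (kappa * s^2))
  tab <- data.frame(parameter = names(der),
                    derivative = unname(der),
                    sign = ifelse(der > 0, "+", "-"),
                    elasticity = unname(der * p[names(der)] / R0),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("ffm_sensitivity", "data.frame"))
}

#' @export
print.ffm_sensitivity <- function(x, ...) {
  cat("Sensitivity of R0 (analytic; note: the mu derivative is positive",
      "by its formula)\n")
  NextMethod()
  invisible(x)
}
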