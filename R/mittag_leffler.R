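#' One-parameter Mittag-Leffler function
#'
#' Evaluates \eqn{E_\xi(z) = \sum_{k\ge0} z^k / \Gamma(\xi k + 1)} on the
#' real line for \eqn{\xi \in (0, 1]}. Three regimes are used, switching on
#' accuracy rather than convenience:
#' \itemize{
#'   \item \eqn{z \ge 0} and small negative arguments (\eqn{z \ge -1}): the
#'     defining power series with adaptive truncation (summation stops once
#'     the term falls below `tol` relative to the partial sum, hard cap
#'     `max_terms`). For alternating sums further left the series cancels
#'     catastrophically in double precision, hence:
#'   \item \eqn{\xi = 1}, \eqn{z < -1}: the exact reciprocal identity
#'     \eqn{e^z = 1/e^{-z}} applied to the stable positive-term series.
#'   \item \eqn{\xi < 1}, \eqn{z < -1}: the complete-monotonicity
#'     (spectral) representation
#'     \deqn{E_\xi(-x) = \int_0^\infty e^{-r x^{1/\xi}}
#'       \frac{1}{\pi}\frac{r^{\xi-1}\sin(\xi\pi)}
#'       {r^{2\xi} + 2 r^\xi \cos(\xi\pi) + 1}\, dr,}
#'     evaluated by adaptive quadrature.
#' }
#' Arguments are restricted to \eqn{|z| \le 10^4}; evaluation is
#' deterministic (repeated calls are bit-identical).
#'
#' @param xi Order in (0, 1].
#' @param z Real argument, \eqn{|z| \le 10^4} (vectorised).
#' @param tol Series term-size cutoff, in (0, 1e-6].
#' @param max_terms Series cap (>= 50).
#' @return Numeric vector of \eqn{E_\xi(z)}.
#' @export
#' @examples
#' ml(1, -1)        # exp(-1)
#' ml(0.5, -1)      # exp(1) * erfc(1)
ml <- function(xi, z, tol = 1e-14, max_terms = 10000L) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) ||
      xi <= 0 || xi > 1) {
    stop("xi must lie in (0, 1]")
  }
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-6) {
    stop("tol must lie in (0, 1e-6]")
  }
  max_terms <- as.integer(max_terms)
  if (is.na(max_terms) || max_terms < 50L) stop("max_terms must be >= 50")
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(abs(z) > 1e4)) stop("|z| must not exceed 1e4")
  vapply(z, function(zi) {
    if (zi >= -1) return(.ml_series(xi, zi, tol, max_terms))
    if (xi == 1) return(1 / .ml_series(1, -zi, tol, max_terms))
    .ml_spectral(xi, -zi)
  }, numeric(1))
}

.ml_series <- function(xi, zi, tol, max_terms) {
  if (zi == 0) return(1)
  ln_abs_z <- log(abs(zi))
  sgn <- if (zi < 0) -1 else 1
  total <- 1
  k <- 0L
  repeat {
    k <- k + 1L
    # z^k / Gamma(xi*k + 1) in log space to avoid intermediate overflow
    term <- sgn^k * exp(k * ln_abs_z - lgamma(xi * k + 1))
    total <- total + term
    if (abs(term) < tol * max(abs(total), 1) && abs(term) < tol) {
      return(total)
    }
    if (k >= max_terms) {
      stop(sprintf(paste0("Mittag-Leffler series did not converge within ",
                          "%d terms (partial sum %.6g)"), max_terms, total))
    }
  }
}

# spectral-density quadrature for E_xi(-x), 0 < xi < 1, x > 1.
# Starting from E_xi(-x) = int_0^inf exp(-r x^(1/xi)) K_xi(r) dr with
# K_xi(r) = (1/pi) r^(xi-1) sin(xi pi) / (r^(2xi) + 2 r^xi cos(xi pi) + 1),
# the substitutions r = v^(1/xi), w = v x remove the r^(xi-1) endpoint
# singularity and give the smooth O(1)-scale integrand below.
.ml_spectral <- function(xi, x) {
  cospi_xi <- cospi(xi)
  sinpi_xi <- sinpi(xi)
  f <- function(w) {
    q <- w / x
    exp(-w^(1 / xi)) / (q^2 + 2 * q * cospi_xi + 1)
  }
  val <- stats::integrate(f, 0, Inf, rel.tol = 1e-13, abs.tol = 0,
                          subdivisions = 2000L)$value
  sinpi_xi * val / (pi * xi * x)
}

#' Atangana-Baleanu normalization constant
#'
#' \eqn{AB(\xi) = 1 - \xi + \xi / \Gamma(\xi)}; equals 1 at both
#' \eqn{\xi = 1} and the \eqn{\xi \to 0^+} limit.
#'
#' @param xi Fractional order in (0, 1].
#' @return Scalar normalization constant.
#' @export
ab_normalization <- function(xi) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) ||
      xi <= 0 || xi > 1) {
    stop("xi must lie in (0, 1]")
  }
  1 - xi + xi / gamma(xi)
}

# per-compartment decay-rate coefficient entering the positivity bounds;
# built from sup-norm envelopes of the coupled compartments
.positivity_rate <- function(compartment, p, supnorms) {
  switch(compartment,
    T    = p[["alpha"]] * p[["beta"]] * supnorms$sup_T + p[["gamma"]] +
           p[["phi"]] * supnorms$sup_C,
    C    = -p[["rho"]] * supnorms$sup_D + p[["kappa"]] -
           p[["phi"]] * supnorms$sup_T,
    D    = p[["lam"]] + p[["omega"]] + p[["rho"]] * supnorms$sup_C,
    IL2  = p[["d"]],
    IL12 = p[["psi"]],
    Z    = p[["a"]],
    stop("unknown compartment: ", compartment))
}

#' Mittag-Leffler positivity lower bound for one compartment
#'
#' Each compartment started at a nonnegative value stays above a
#' Mittag-Leffler decay envelope: for tumor cells, for instance,
#' \deqn{T(t) \ge T(0)\, E_\xi\!\left[\frac{-b^{1-\eta}\,\xi\,
#'   (\alpha\beta\|T\|_\infty + \gamma + \phi\|C\|_\infty)\, t^\xi}
#'   {AB(\xi) - (1-\xi)(\alpha\beta\|T\|_\infty + \gamma +
#'   \phi\|C\|_\infty)}\right],}
#' with analogous envelopes for the other compartments (rates `d`, `psi`,
#' `a` for the cytokine chain and inhibitor). The constant `b` is the
#' "time component" multiplying the fractal correction \eqn{b^{1-\eta}};
#' it is caller-supplied with default 1 (the envelope source never assigns
#' it). When the denominator \eqn{AB(\xi) - (1-\xi)(\cdot)} is not positive
#' the bound is undefined and a domain error is raised.
#'
#' @param compartment One of `"T"`, `"C"`, `"D"`, `"IL2"`, `"IL12"`, `"Z"`.
#' @param t Time (>= 0, vectorised).
#' @param x0 Initial state.
#' @param p Parameters.
#' @param orders [fractional_orders()].
#' @param supnorms Sup-norm envelopes, see [supnorms_from_trajectory()].
#' @param b Positive time-component constant (default 1).
#' @return A list of class `ffm_positivity_bound` with elements
#'   `compartment`, `time`, `bound`, `decay_rate_argument`, `supnorm_inputs`,
#'   `b`, `ab_norm`.
#' @export
positivity_bound <- function(compartment, t, x0, p, orders,
                             supnorms, b = 1) {
  compartment <- match.arg(compartment, .state_names)
  p <- as_parameters(p)
  x0 <- as_state(x0)
  stopifnot(inherits(orders, "ffm_orders"))
  if (any(t < 0)) stop("t must be nonnegative")
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop("b must be a positive scalar")
  }
  sn <- unlist(supnorms[c("sup_T", "sup_C", "sup_D",
                          "sup_IL2", "sup_IL12", "sup_Z")])
  if (any(!is.finite(sn)) || any(sn < 0)) {
    stop("sup norms must be nonnegative and finite")
  }
  xi <- orders$xi; eta <- orders$eta
  ab <- ab_normalization(xi)
  r <- .positivity_rate(compartment, p, supnorms)
  den <- ab - (1 - xi) * r
  if (den <= 0) {
    stop(sprintf(paste0("positivity bound undefined: AB(xi) - (1-xi)*rate",
                        " = %.6g <= 0 for compartment %s"),
                 den, compartment))
  }
  arg <- -b^(1 - eta) * xi * r * t^xi / den
  structure(list(compartment = compartment,
                 time = t,
                 bound = x0[[compartment]] * ml(xi, arg),
                 decay_rate_argument = arg,
                 supnorm_inputs = sn,
                 b = b,
                 ab_norm = ab),
            class = "ffm_positivity_bound")
}
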