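#' Model parameters for the tumor-immune system
#'
#' Bundles the twelve positive rate constants of the TCD-IL2-IL12-Z model:
#' tumor cells (T) grow logistically and are killed by dendritic and CD8+
#' T cells; CD8+ T cells are stimulated by tumor and dendritic contact and
#' die naturally; dendritic cells are produced at a constant source and
#' drained by CD8+ contact, natural death and IL-2 recruitment; the cytokine
#' chain IL-2 -> IL-12 -> anti-PD-L1 inhibitor is a linear cascade.
#'
#' @param alpha Tumor logistic growth rate (1/time).
#' @param beta Inverse tumor carrying capacity (1/cells).
#' @param gamma Dendritic kill rate of tumor cells (1/time).
#' @param phi CD8+ elimination rate of tumor cells (1/(cells*time)).
#' @param rho CD8+-dendritic interaction rate (1/(cells*time)).
#' @param kappa CD8+ natural death rate (1/time).
#' @param mu Dendritic source (cells/time).
#' @param omega Dendritic natural death rate (1/time).
#' @param lam IL-2 source rate from dendritic cells (1/time).
#' @param d IL-2 to IL-12 conversion rate (1/time).
#' @param psi IL-12 to inhibitor conversion rate (1/time).
#' @param a Anti-PD-L1 inhibitor natural death rate (1/time).
#'
#' @return An object of class `ffm_parameters`, a named numeric vector.
#' @export
#' @examples
#' p <- model_parameters(alpha = 0.5, beta = 0.01, gamma = 0.1, phi = 0.01,
#'                       rho = 0.01, kappa = 0.1, mu = 1, omega = 0.1,
#'                       lam = 0.1, d = 0.1, psi = 0.1, a = 0.1)
#' reproduction_number(p)
model_parameters <- function(alpha, beta, gamma, phi, rho, kappa,
                             mu, omega, lam, d, psi, a) {
  p <- c(alpha = alpha, beta = beta, gamma = gamma, phi = phi, rho = rho,
         kappa = kappa, mu = mu, omega = omega, lam = lam, d = d,
         psi = psi, a = a)
  if (!is.numeric(p) || length(p) != 12L) {
    stop("all twelve parameters must be single numeric values")
  }
  bad <- !is.finite(p) | p <= 0
  if (any(bad)) {
    stop("parameters must be strictly positive and finite; offending: ",
         paste(names(p)[bad], collapse = ", "))
  }
  storage.mode(p) <- "double"   # config files may deliver integers
  structure(p, class = "ffm_parameters")
}

#' @export
print.ffm_parameters <- function(x, ...) {
  cat("Tumor-immune model parameters:\n")
  print(format(unclass(x), digits = 10), quote = FALSE)
  invisible(x)
}

.param_names <- c("alpha", "beta", "gamma", "phi", "rho", "kappa",
                  "mu", "omega", "lam", "d", "psi", "a")

as_parameters <- function(p) {
  if (inherits(p, "ffm_parameters")) return(p)
  p <- unlist(p)
  missing <- setdiff(.param_names, names(p))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  do.call(model_parameters, as.list(p[.param_names]))
}

#' State of the six model compartments
#'
#' @param T Tumor cells.
#' @param C CD8+ T cells.
#' @param D Dendritic cells.
#' @param IL2 Cytokine IL-2.
#' @param IL12 Cytokine IL-12.
#' @param Z Anti-PD-L1 inhibitor.
#'
#' @details Components must be finite but may be negative: the solver has to
#' be able to represent positivity violations so that the well-posedness
#' monitor can report them.
#'
#' @return A named numeric vector of class `ffm_state`.
#' @export
state_vector <- function(T, C, D, IL2, IL12, Z) {
  x <- c(T = T, C = C, D = D, IL2 = IL2, IL12 = IL12, Z = Z)
  if (!is.numeric(x) || length(x) != 6L) {
    stop("all six components must be single numeric values")
  }
  bad <- !is.finite(x)
  if (any(bad)) {
    stop("state components must be finite; offending: ",
         paste(names(x)[bad], collapse = ", "))
  }
  storage.mode(x) <- "double"
  structure(x, class = "ffm_state")
}

.state_names <- c("T", "C", "D", "IL2", "IL12", "Z")

as_state <- function(x) {
  if (inherits(x, "ffm_state")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 6L) names(x) <- .state_names
  missing <- setdiff(.state_names, names(x))
  if (length(missing)) stop("missing state components: ",
                            paste(missing, collapse = ", "))
  do.call(state_vector, as.list(x[.state_names]))
}

#' Fractional order and fractal dimension of the FFM operator
#'
#' The operator carries two indices: the fractional order `xi` of the
#' Mittag-Leffler (Atangana-Baleanu) kernel and the fractal dimension `eta`
#' (the operator's second index; named `eta` here to avoid clashing with the
#' IL-2 source rate `lam`). Both lie in (0, 1]; `xi = eta = 1` recovers the
#' classical derivative.
#'
#' @param xi Fractional order in (0, 1].
#' @param eta Fractal dimension in (0, 1].
#' @return An object of class `ffm_orders`.
#' @export
fractional_orders <- function(xi = 1, eta = 1) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) ||
      xi <= 0 || xi > 1) {
    stop("xi must lie in (0, 1]")
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta <= 0 || eta > 1) {
    stop("eta must lie in (0, 1]")
  }
  structure(list(xi = as.numeric(xi), eta = as.numeric(eta)),
            class = "ffm_orders")
}

#' @export
print.ffm_orders <- function(x, ...) {
  cat(sprintf("FFM operator orders: xi = %g (fractional), eta = %g (fractal)\n",
              x$xi, x$eta))
  invisible(x)
}

#' Solver configuration for the fractal-fractional integrator
#'
#' @param dt Time step (> 0).
#' @param t_end Integration horizon; must be an integer multiple of `dt` and
#'   at least `3 * dt` (the Newton-polynomial scheme needs three seed points).
#' @param bootstrap Seeding rule for the first two steps; only
#'   `"fractional_euler"` is implemented.
#' @param store_every Positive integer thinning factor for the stored output
#'   grid (computation always runs on the full grid).
#' @return An object of class `ffm_solver_config`.
#' @export
solver_config <- function(dt, t_end, bootstrap = "fractional_euler",
                          store_every = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive number")
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end)) {
    stop("t_end must be a finite number")
  }
  if (t_end < 3 * dt) stop("t_end must be at least 3 * dt")
  n <- t_end / dt
  if (abs(n - round(n)) > 1e-8 * max(1, n)) {
    stop("t_end must be an integer multiple of dt")
  }
  bootstrap <- match.arg(bootstrap, "fractional_euler")
  store_every <- as.integer(store_every)
  if (is.na(store_every) || store_every < 1L) {
    stop("store_every must be a positive integer")
  }
  structure(list(dt = as.numeric(dt), t_end = as.numeric(t_end),
                 n_steps = as.integer(round(n)),
                 bootstrap = bootstrap, store_every = store_every),
            class = "ffm_solver_config")
}
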