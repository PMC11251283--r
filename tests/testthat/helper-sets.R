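# Shared fixtures for the test suite.

# O(1)-magnitude parameter set with alpha > gamma whose interior (endemic)
# branch is componentwise positive; used wherever a strictly positive
# reference equilibrium is needed.
endemic_parameters <- function() {
  model_parameters(alpha = 0.8, beta = 0.5, gamma = 0.1, phi = 0.4,
                   rho = 0.3, kappa = 0.5, mu = 1.0, omega = 0.3,
                   lam = 0.2, d = 0.3, psi = 0.25, a = 0.35)
}

# The gains that place the controlled disease-free spectrum at the
# documented worked-example eigenvalues.
worked_example_gains <- function() {
  control_gains(1, 0.5038, 3, 4.0027, 5.0027, 6)
}

# Central finite difference of f at x. The step is capped at |x|/2 so that
# strictly positive quantities stay positive, but never shrinks below the
# roundoff-safe scale for tiny |x| unless positivity forces it.
central_diff <- function(f, x, h = NULL) {
  if (is.null(h)) h <- min(1e-6 * max(1, abs(x)), abs(x) / 2)
  (f(x + h) - f(x - h)) / (2 * h)
}
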