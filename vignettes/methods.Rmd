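---
title: "Methods: the fractal-fractional tumor-immune toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fractal-fractional tumor-immune toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffmtumor)
```

# The model

`ffmtumor` simulates and analyses a six-compartment tumor-immune
interaction system: tumor cells $T$, CD8+ T cells $C$, dendritic cells
$D$, the cytokines IL-2 and IL-12, and an anti-PD-L1 checkpoint-blockade
inhibitor $Z$:

$$
\begin{aligned}
T' &= \alpha T(1-\beta T) - \gamma T - \phi C T, &
C' &= \phi C T + \rho C D - \kappa C, \\
D' &= \mu - \rho C D - \omega D - \lambda D, &
IL_2' &= \lambda D - d\, IL_2, \\
IL_{12}' &= d\, IL_2 - \psi\, IL_{12}, &
Z' &= \psi\, IL_{12} - a Z .
\end{aligned}
$$

Tumor cells grow logistically and are killed by dendritic contact
($\gamma$) and CD8+ contact ($\phi$); CD8+ cells are stimulated by tumor
and dendritic contact and die at rate $\kappa$; dendritic cells have a
constant source $\mu$; the cytokine chain
$D \to IL_2 \to IL_{12} \to Z$ is a linear cascade. The built-in
reference scenario (`scenario_paper()`) is a weakly immunogenic regime:
couplings of order $10^{-7}$ and below, $\mu = 480$, so the dendritic
compartment relaxes to $\mu/(\omega+\lambda) \approx 2000$ while every
other compartment decays.

```{r}
sc <- scenario_paper()
reproduction_number(sc$parameters)
```

# Equilibria, $R_0$, sensitivity

`equilibria()` returns every fixed point in closed form: the
disease-free point (always), the interior branches of the fixed-point
quadratic in $T$ via its discriminant (both sign branches are evaluated
and kept only when componentwise positive), and the tumor-free boundary
branch (exists iff $R_0 > 1$). Two implementation points deserve note:

* **Residual gate.** Every returned point must satisfy
  $\|F(x^*)\|_\infty < 10^{-8}(1 + \max_i |x^*_i|)$; a violation is an
  error, never a silent result.
* **Newton polish.** The closed forms are exact algebraically, but for
  extreme parameter magnitudes their floating-point evaluation cancels.
  Interior and boundary seeds are therefore refined by full-system
  Newton iteration; the polished root is accepted only if it stays
  finite, preserves the seed's sign pattern, moves at most 10%
  relative, and does not worsen the residual.

The basic reproduction number has the closed form
$R_0 = \mu\rho/(\kappa(\lambda+\omega))$ and is cross-checked against an
independent next-generation-matrix construction with infected set
$\{C\}$: $F = \rho\mu/(\lambda+\omega)$, $V = \kappa$, $R_0 = \rho(FV^{-1})$.
`sensitivity_indices()` gives the five analytic partial derivatives of
$R_0$ and their elasticities. The derivative with respect to $\mu$ is
positive by its own formula $\rho/(\kappa(\lambda+\omega))$; the
implementation follows the formula (a negative sign sometimes quoted for
it is a transcription slip).

# The Mittag-Leffler function

The kernel of the Atangana-Baleanu operator is the one-parameter
Mittag-Leffler function $E_\xi(z)=\sum_{k\ge0} z^k/\Gamma(\xi k+1)$.
`ml()` evaluates it on the real line with three regimes, chosen for
accuracy:

1. **Series** for $z \ge -1$ (any $\xi$): the defining power series with
   adaptive truncation, summed in log space. On this range the largest
   term has magnitude at most 1, so no cancellation occurs.
2. **Reciprocal identity** for $\xi = 1$, $z < -1$: $e^z = 1/e^{-z}$
   applied to the positive-term series. The alternating series itself
   loses all significant digits near $z = -20$ (observed relative error
   of order $10^2$), which is why a pure-series implementation was
   rejected.
3. **Spectral integral** for $\xi < 1$, $z < -1$: complete monotonicity
   gives
   $E_\xi(-x) = \int_0^\infty e^{-r x^{1/\xi}} K_\xi(r)\,dr$ with
   $K_\xi(r) = \frac{1}{\pi}\frac{r^{\xi-1}\sin(\xi\pi)}
   {r^{2\xi}+2r^\xi\cos(\xi\pi)+1}$. The substitutions $r = v^{1/\xi}$,
   $w = vx$ collapse this to
   $$E_\xi(-x) = \frac{\sin(\xi\pi)}{\pi\xi x}\int_0^\infty
   \frac{e^{-w^{1/\xi}}}{(w/x)^2 + 2(w/x)\cos(\xi\pi)+1}\,dw,$$
   a smooth, singularity-free integrand of $O(1)$ scale handled by
   adaptive quadrature at `rel.tol = 1e-13`.

Verified properties: agreement with `exp` to $4\times10^{-15}$ relative
on $|z|\le 20$; agreement with the scaled complementary error function
$E_{1/2}(-x) = e^{x^2}\mathrm{erfc}(x)$ to $\sim 10^{-13}$; the two-term
large-$x$ asymptotics; and complete monotonicity on the negative axis.

```{r}
ml(1, -1) - exp(-1)
ml(0.5, -1) # = exp(1) * erfc(1)
```

# The fractal-fractional integrator

`simulate_ffm()` advances the system under the fractal-fractional
operator with Mittag-Leffler kernel, fractional order $\xi$ and fractal
dimension $\eta$ (both in $(0,1]$; $\xi=\eta=1$ recovers the classical
derivative). The equivalent Volterra form of the problem is discretised
with the three-point Newton-polynomial quadrature: writing
$g_k = t_k^{\eta-1}F(t_k,X^k)$ for the fractal-weighted vector field,

$$
X^{\varrho+1} = X^0 + \frac{\eta(1-\xi)}{AB(\xi)}\, g_\varrho
 + \frac{\xi\eta\,\Delta t^\xi}{AB(\xi)}\left[
   \frac{S_1}{\Gamma(\xi+1)} + \frac{S_2}{\Gamma(\xi+2)} +
   \frac{S_3}{2\,\Gamma(\xi+3)}\right],
$$

where $S_1, S_2, S_3$ are the history sums over the bracket weights
returned by `kernel_weights()` (zeroth/first/second differences of the
$g$ history). The first weight sequence telescopes to
$(\varrho-1)^\xi$, and at $\xi = 1$ the three brackets combine to the
classical three-step Adams-Bashforth coefficients $(23,-16,5)/12$ — both
facts are tested.

Three fidelity choices are deliberate and worth recording:

* **Initial-condition term.** The Volterra form requires the explicit
  $X^0$; the update is a quadrature of the whole integral from 0, not a
  one-step recursion.
* **Head correction.** The history sums start at $\varpi = 2$ and
  therefore omit the integral over the first two grid cells $[0, t_2]$.
  That missing mass does not vanish with $\Delta t$ (for the reference
  scenario it biases the dendritic compartment by roughly 10 units);
  it is restored by a first-order rectangle rule over nodes 0 and 1
  with the telescoping weights. With the correction the classical-limit
  error against an adaptive reference drops to $\sim 10^{-3}$ relative.
* **$t = 0$ regularisation.** For $\eta < 1$ the fractal weight
  $t^{\eta-1}$ is singular at the initial node; the node value is taken
  at $\Delta t$ (the underlying integrand is integrable, so this is a
  consistent one-node choice).

Steps 1 and 2 are seeded by the same rectangle (fractional-Euler) rule.
History sums are recomputed each step from the stored history: $O(N^2)$
work, no fast-convolution approximation, which keeps the scheme exactly
as analysed. Non-finite states raise a typed `ffm_integration_error`
carrying the last valid state.

`simulate_classical()` (deSolve lsoda at tolerances $10^{-10}$) is the
reference oracle for the $\xi=\eta=1$ limit, and `convergence_order()`
estimates the empirical order from step halving against a
$\Delta t/8$ self-reference.

# Stability and chaos control

At the disease-free point the Jacobian is effectively triangular, so its
spectrum has closed forms ($\alpha-\gamma$, $(\mu\rho-\kappa(\lambda+\omega))/(\lambda+\omega)$,
$-(\lambda+\omega)$, $-d$, $-\psi$, $-a$); `dfe_spectrum_closed_form()`
and the dense `spectrum_at()` must agree, and the stability verdict is
equivalent to $R_0 < 1$ together with $\alpha < \gamma$.

Chaos control subtracts linear feedback $\omega_i(x_i - x_i^*)$ from
each equation, shifting the Jacobian diagonal. `controlled_spectrum()`
also reports, for each eigenvalue, the compartment carrying the largest
eigenvector component (`axis`), which is how eigenvalues are associated
with compartments in reports.

```{r}
p <- scenario_paper()$parameters
dfe <- equilibria(p)[[1]]
controlled_spectrum(dfe, p, control_gains(1, 0.5038, 3, 4.0027, 5.0027, 6))
```

The Volterra-type Lyapunov function
$L=\sum_i (x_i - x_i^* - x_i^*\log(x_i/x_i^*))$ and its
$\Sigma/\Omega$ decomposition are implemented verbatim in
`lyapunov_terms()`. The decomposition is a regrouping, not an exact
split of $\dot L$; the invariant the package (and its tests) rely on is
the decision rule — wherever $\Sigma < \Omega$, the chain-rule
derivative $\dot L = \sum_i (1 - x_i^*/x_i) f_i(x)$ is negative.
`global_stability_scan()` applies the rule along a trajectory.

# Well-posedness

`growth_and_lipschitz()` evaluates the six linear-growth constants
$K_1..K_6$, the six Lipschitz constants $\bar K_1..\bar K_6$ of the
clocked vector field, and the six growth-condition ratios whose maximum
below one certifies a unique solution. The certificate is sufficient,
not necessary: on the reference scenario the cytokine-chain ratios are
far above one and the checker reports `unique = FALSE` faithfully.

`positivity_bound()` provides per-compartment Mittag-Leffler decay
envelopes built from sup-norm inputs. For $T$, $D$, $IL_2$, $IL_{12}$,
$Z$ the envelope rate over-counts the losses, so the envelope is a true
lower bound (exactly $x_0 e^{-\text{rate}\,t}$ in the classical limit);
the $C$ envelope follows its defining form, whose rate subtracts the
gain terms, and is therefore reported but not certified. The
complementary empirical check is `monitor_trajectory()`: negative
excursions below $-10^{-9}$ and magnitudes beyond ten times the natural
scale $\max(|x_0|,\mu/(\omega+\lambda))$ are reported as violations.

# Scenario generation and I/O

`scenario_random(seed)` draws parameters log-uniformly within two
decades of the reference values (initial states within one decade),
deterministically per seed and without disturbing the caller's RNG
state. With `force_R0_above_1` the rate $\rho$ is rescaled so $R_0$
lands between 1.5 and 5, producing endemic-branch systems for testing
the interior equilibria. The two-decade envelope is a deliberate
stress-test width: it exercises the closed forms across ten orders of
magnitude of state scale while staying in the positive, well-posed
regime.

Configs round-trip losslessly through YAML or JSON (17 significant
digits); trajectories are CSV with columns exactly
`t,T,C,D,IL2,IL12,Z`. `run_cli()` exposes the workflows as subcommands
(`simulate`, `equilibria`, `sensitivity`, `stability`, `chaos-control`,
`check-wellposedness`, `convergence`) with exit status 0 on success, 2
on validation errors, and 1 on integration failure; a thin wrapper
script ships in `inst/cli/`.

# Problem sizes and limitations

Default test and example sizes are our own choices, scaled to keep the
full check suite under a few minutes: reference runs use
$\Delta t = 0.05$ over a horizon of 100; convergence studies use a
coarsest step of 0.1 over a short horizon; randomized property checks
use 100 seeds.

Known limitations:

* The $O(N^2)$ history recomputation makes very long fractional runs
  expensive; no memory-truncation or fast-kernel approximation is
  offered.
* `ml()` is restricted to real arguments with $|z| \le 10^4$, which
  covers every use in the package; complex arguments and the
  two-parameter generalisation are out of scope.
* The uniqueness certificate and the $C$ positivity envelope implement
  their stated sufficient conditions verbatim; both can fail to certify
  systems that are in fact well behaved, and the package reports that
  honestly rather than tightening the theory.
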