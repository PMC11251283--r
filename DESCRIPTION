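Package: ffmtumor
Title: Fractal-Fractional Tumor-Immune Dynamics with a Mittag-Leffler Kernel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a six-compartment tumor-immune
    model coupling tumor cells, CD8+ T cells, dendritic cells, the cytokines
    IL-2 and IL-12, and an anti-PD-L1 checkpoint inhibitor. Provides a
    fractal-fractional integrator with Atangana-Baleanu (Mittag-Leffler)
    kernel based on a three-point Newton-polynomial quadrature, closed-form
    equilibria, the basic reproduction number with next-generation cross-check
    and sensitivity indices, local spectra and linear-feedback chaos control,
    Lyapunov-based global-stability scans, and well-posedness diagnostics
    (positivity bounds, linear-growth and Lipschitz constants, uniqueness
    condition, runtime monitors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
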