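Package: nichefate
Title: Competition Dynamics of Normal and Leukaemic Stem Cells in the Bone-Marrow Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of haematopoietic (HSC) and
    leukaemia (LSC) stem-cell lineages competing for a shared bone-marrow niche,
    together with the tools used to analyse them: numerical integration to a
    finite-time pseudo-steady state with blow-up detection, classification of
    trajectories into dynamical regimes (HSC win, LSC win, coexistence,
    unbounded), qualitative approximate Bayesian computation (rejection and
    sequential Monte Carlo) that conditions on declared behaviour such as
    "healthy species persist, leukaemic species vanish" instead of data, and
    principal-component analysis of the resulting weighted posterior to locate
    stiff (tightly constrained) parameter combinations.  Includes two niche
    models (a hard-carrying-capacity Lotka-Volterra-type model and a soft-niche
    model with explicit stem-cell fate rates and exponential feedback), a
    two-species pedagogical competition model, Latin-hypercube samplers,
    analytically tractable toy problems for validating the inference machinery,
    and named analysis recipes with full run provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
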