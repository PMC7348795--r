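Package: gradlab
Title: Ligand Gradient Simulation and Chemotaxis Quantification for
    Microfluidic and Transwell Migration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the development of growth-factor concentration gradients
    in two-reservoir microfluidic devices and transwell (Boyden chamber)
    assays by the one-dimensional convective-diffusion equation with
    well-mixed reservoir compartments, estimates protein diffusivities from
    the Stokes-Einstein relation, quantifies cell migration from sampled
    trajectories (path length, net displacement, motile fraction) and from
    per-device transwell counts, computes relative gene expression by the
    delta-delta-CT method, and applies a normality-gated group comparison
    procedure (one-way ANOVA with Tukey post-hoc, or Kruskal-Wallis with
    Dunn post-hoc under Holm correction). Includes a seeded synthetic-data
    generator (biased random walks with closed-form Rice path-length
    moments, CT tables, device counts) for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
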