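Package: kroghslice
Title: Krogh Coefficient Estimation from Oxygen Tension Profiles in Perfused Tissue Slices
Version: 0.1.0
Authors@R:
    person("Slice", "Metabolism Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to determine the tissue Krogh coefficient (oxygen
    permeability, the product of oxygen diffusivity and solubility) from
    microelectrode pO2-versus-depth soundings through thin perfused tissue
    slices. Implements the closed-form steady-state diffusion-consumption
    tension profiles for a slab with piecewise-linear oxygen uptake
    (parabolic, mixed parabolic/hyperbolic-cosine and pure cosh cases,
    including the numerical determination of the critical depth), curve
    fitting of measured profiles, detection of stationary fluid boundary
    layers and flux-conservation estimation of the tissue:fluid Krogh
    ratio, temperature- and composition-dependent fluid physics for
    artificial cerebrospinal fluid (diffusivity, Bunsen/Henry solubility,
    salting-out and glucose corrections), conversions between the
    compound Krogh-coefficient unit systems in common use, variance
    decomposition of paired repeat measurements into experimental and
    biological components, and a seeded synthetic-profile generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
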