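Package: sipflux
Title: Isotope-Labelled Function Assignment and Electron-Flow Balance for
    Denitrifying Sulfur-Oxidizing Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for DNA stable-isotope probing (DNA-SIP) studies of
    coupled carbon, nitrogen and sulfur cycling in anoxic sediments. Provides
    isopycnic CsCl gradient fraction analytics (refractive-index to buoyant-density
    conversion, per-fraction gene-abundance normalisation, heavy/light demarcation,
    labelling-shift detection), community-isotope-corrected assignment of carbon,
    nitrogen and sulfur functions to taxa from treatment-by-label comparisons of
    heavy-fraction relative abundances, stoichiometric electron-flow statistics for
    denitrification (completion extent, sulfide and organic-matter electron shares,
    N2O emission fractions), a standard-state Gibbs free-energy engine with a bundled
    formation-energy library, and a synthetic microcosm generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
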