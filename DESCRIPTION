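Package: minimet
Title: Symmetry-Guided Miniaturization and Validation of Tetrathiolate Metalloproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating miniature metal-binding proteins
    built around a tetrahedral M(Cys)4 center. Implements the symmetry-guided
    miniaturization workflow (template fragment dissection, pseudo-C2 dimer
    generation, gap-limited loop-closure fragment search, beta-turn typing and
    loop grafting), structure-validation analytics (rigid-body superposition,
    first- and second-coordination-sphere geometry, NH...S hydrogen bonds,
    crystal-symmetry contacts), and the accompanying solution biophysics:
    S = 5/2 zero-field-splitting effective-g rhombograms and rhombicity
    estimation, Randles-Sevcik diffusion analysis of cyclic voltammograms,
    exact 1:1 binding isotherms, extinction-coefficient and Beer-Lambert
    bookkeeping, and Kirkwood bead-model translational diffusion. Deterministic
    synthetic-fixture generators make every step testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
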