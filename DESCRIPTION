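Package: ampchem
Title: Physicochemical Characterization of Cationic Amino-Acid Surfactants
    and Their Phospholipid Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cationic amino-acid surfactants and their
    DPPC (dipalmitoylphosphatidylcholine) vesicle formulations. Implements
    small-angle X-ray scattering (SAXS) forward models and nonlinear
    least-squares fitting for core-shell cylinder micelles and Gaussian
    electron-density bilayers, Tanford hydrocarbon-chain geometry and derived
    micellar quantities, critical micelle concentration estimation from
    conductivity breakpoints and pyrene I1/I3 fluorescence sigmoids, apparent
    pKa extraction from potentiometric titrations, HSAB reactivity-descriptor
    algebra on frontier-orbital energies, censoring-aware MIC/MBC and
    hemolysis summaries, and seeded synthetic-data generators that emulate
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
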