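Package: fretlines
Title: FRET-Lines for Single-Molecule FRET Burst Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference FRET-lines relating the intensity-based FRET
    efficiency to the intensity-weighted donor fluorescence lifetime in
    single-molecule FRET experiments. Provides generators for static,
    two-state and three-state dynamic, donor-mixture, linker-broadened,
    polymer (Gaussian chain, worm-like chain) and order-disorder reference
    curves, the moment-difference representation that linearizes kinetic
    mixing, a photon-level burst simulator with continuous-time Markov
    state switching, and per-burst estimators including burst variance
    analysis (BVA) with its shot-noise reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
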