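Package: fdsim
Title: Stochastic Simulation of Transcription-Factor Facilitated Diffusion
    with System-Size Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven kinetic Monte Carlo simulation of the facilitated
    diffusion mechanism by which transcription factors locate their genomic
    target sites: molecules associate to a DNA lattice, perform a
    one-dimensional random walk with sequence-dependent waiting times derived
    from a position weight matrix energy landscape, exclude one another by
    molecular footprint, and dissociate back to a well-mixed free pool.
    Includes two principled methods for reducing a genome-scale system to a
    small subsystem while preserving its statistics (copy-number scaling and
    association-rate scaling), synthetic genome generation with prescribed
    base composition, and the observables used to compare systems: occupancy
    bias profiles and their correlation, normalized affinity/occupancy ratios,
    first-passage time to the target, target-occupancy probability, and
    one-dimensional random-walk statistics (residence time, sliding length,
    bound-time fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
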