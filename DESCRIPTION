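Package: mapkinfo
Title: Information Transmission and Energetic Cost of a MAPK Signalling Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the budding-yeast pheromone (mating) MAPK pathway as a
    two-step phosphorylation cascade with inducible positive (STE2, FUS3) and
    negative (SST2, MSG5) transcriptional feedbacks, across heterogeneous cell
    populations with log-normal extrinsic noise. Quantifies information
    transmission of the dose-response channel by Fisher information and local
    (sliding-window) mutual information, tracks the GTP/ATP futile-cycle energy
    dissipated by signalling, and computes information-per-energy efficiency
    over sweeps of feedback-promoter affinities. Includes a synthetic
    single-cell assay generator (microscopy-style reporter data with
    autofluorescence and channel bleed-through) and tools to simulate and
    analyse serial-dilution growth-competition experiments that link futile
    cycling to a growth-fitness defect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
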