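Package: riboshift
Title: Ribosome Traffic Simulation and Elongation Analysis Under Acute
    Glucose Starvation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for translation elongation dynamics in budding
    yeast during acute glucose starvation and recovery. Implements per-gene
    ribosome polarity scores, start-codon-aligned metagene densities,
    ribosome-occupancy (RPF/mRNA) classification, Schleif-plot estimation of
    translation elongation rates from inducible luciferase reporter kinetics,
    and spike-in-normalized delta-delta-Ct quantification across polysome
    fraction pools. All stages are exercisable without external data through a
    stochastic exclusion-process (TASEP) ribosome-traffic simulator with
    time-dependent initiation and elongation schedules, an mRNA induction
    model, multinomial sequencing sampling, and a luciferase reporter curve
    generator with transcription delay and PEST decay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
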