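Package: tchur
Title: DNA Data Storage Sequence Design with the TC-HUR Hybrid Metaheuristic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs synthesizable nucleotide sequences for DNA data storage
    from arbitrary digital payloads encoded at 2 bits per nucleotide. Implements
    the TC-HUR tri-phase hybrid optimizer (Cauchy-assisted Hunger Games Search
    exploration, Runge-Kutta-style elite refinement, adaptive targeted mutation)
    against a biophysical penalty model covering GC content, homopolymer runs,
    nearest-neighbour stacking free energy, melting temperature, Hamming
    distance to an archive, and reverse-complement self-similarity. Ships
    canonical PSO, GWO, HGS and RUN baselines, a substitution/insertion/deletion
    error-channel simulator with homopolymer-aware boosting and normalized
    edit-distance scoring, and a multi-run benchmark harness with Friedman and
    Wilcoxon comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
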