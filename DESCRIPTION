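Package: paretarget
Title: Degradome-Guided Prediction of Plant Small RNA Targets
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: High-throughput prediction of plant small RNA (sRNA) targets from
    degradome/PARE sequencing data. Implements 2-bit integer encoding of
    nucleotide sequences with inverse codes for sRNA and mRNA, exact-match
    degradome-to-transcript alignment by binary search over sorted encoded
    read lists, CleaveLand-style cleavage-peak categories with an
    abundance-one modification, 7-mer seed-region prefiltering against lazily
    computed valid-alignment matrix rows, a configurable cleavage-anchored
    duplex aligner supporting G:U wobbles and gaps (Allen et al. and
    Fahlgren-Carrington presets), and optional minimum-free-energy-ratio and
    per-transcript binomial p-value confidence filters. A deterministic
    synthetic-data generator plants known sRNA-target-degradome triples for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: Rcpp, Biostrings, rtracklayer, jsonlite, methods, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
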