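Package: utrscan
Title: Sliding-Window Thermodynamic Scanning for Structured Elements in
    mRNA 5' UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates candidate cis-regulatory secondary structure in mRNA
    untranslated regions by sliding-window RNA folding. Windows are folded
    for minimum free energy and ensemble (partition-function) free energy,
    and each window is scored against dinucleotide-preserving shuffled
    nulls with a segment z-score, so that stability in excess of base
    composition can be separated from composition-driven stability.
    Includes a self-contained Zuker-style minimum-free-energy and McCaskill
    partition-function engine over a simplified nearest-neighbour model, an
    adapter to the ViennaRNA RNAfold program for Turner-parameter energies,
    centroid base-pair-probability profiling, mutant delta-delta-G
    comparison, Eulerian-walk dinucleotide shuffling, pairwise-alignment
    conservation summaries, and generators for dinucleotide-matched
    synthetic benchmarks with planted hairpins. Ships the oligonucleotide
    set from which the 167-nucleotide proximal TGF-beta1 5' UTR insert and
    its adenine-substitution mutants can be reconstructed offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (RNAfold on the PATH) for the optional
    thermodynamic backend
Config/testthat/edition: 3
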