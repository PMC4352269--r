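Package: annolift
Title: Cross-Species Gene Annotation Transfer by Stage-Wise Shortest-Path Exon Chaining
Version: 0.1.0
Authors@R:
    person("Annolift", "Developers", email = "annolift@example.org", role = c("aut", "cre"))
Description: Transfers structural gene annotations from an annotated source
    genome onto an un-annotated target genome of a similar species. Exon
    sequences of each source transcript are pre-aligned to the target genome
    with a local aligner (12-column tabular output); for every transcript the
    package selects the optimal combination of exon alignments with a
    stage-wise shortest-path model solved by backward Bellman recursion, using
    a one-step cost that combines chromosome and strand feasibility, alignment
    quality (aligned-length fraction scaled by exp(-E-value)) and the ratio of
    inter-exon distances between the two genomes, with a fixed penalty for
    skipping an exon. Candidate annotations are quality-controlled for
    canonical GT-AG splice sites (with a bounded two-side shift rescue),
    score-filtered, and written as a UCSC-style genePred table plus transcript
    FASTA. A seeded fixture generator builds fully synthetic source/target
    worlds and simulated alignment tables so the whole pipeline runs
    hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
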