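---
title: "annolift: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{annolift: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annolift)
```

# The model

`annolift` transfers transcript structures from an annotated source
genome to an un-annotated target genome of a similar species. The input
evidence is a table of local alignments of every source exon sequence
against the target genome. For a transcript with `N` exons, the
alignments of exon `i` form decision stage `i`; each stage carries one
extra synthetic state, *skip*. A solution chooses one state per stage,
and the chosen alignments, read in stage order, must form a plausible
transcript: one chromosome, one strand, exon order preserved, and
inter-exon spacing comparable to the source.

Each stage contributes exactly one cost term, attributed to the state
chosen at that stage:

* **skip**: the constant `K = 0.95`;
* **alignment followed by another retained alignment**: infinite if the
  two hits disagree on chromosome or strand, otherwise
  `1 − Align · Rela` where `Align = (Align_Length / Exon_Length) ·
  exp(−E)` is the alignment quality of the *current* hit and `Rela` is
  the min/max ratio of the absolute source and target inter-exon
  distances;
* **last retained alignment**: `1 − Align` (terminal rule, below).

The total is minimized exactly by backward Bellman recursion and
normalized to `Score = (1 − f*/N) · 100`, so a perfect transfer scores
100 and every feasible path scores in `[0, 100]`.

## Why multiply Align and Rela

A sum would let a strong alignment excuse an absurd genomic placement
(quality 0.2 with perfect spacing would average to a passable 0.6). The
product demands both: quality 0.2 × spacing 1 is still a poor 0.2, and
the step cost `1 − 0.2 = 0.8` approaches the skip penalty, which is the
intended behaviour — an exon whose best evidence is that weak is nearly
worth skipping.

## Decisions where the model needed completing

The cost recursion leaves several corners open; these are this package's
choices, each tested:

* **Terminal cost.** The recursion needs a transition from the last
  retained alignment to the End point. We charge `1 − Align(hit)`,
  i.e. the `Rela` factor is taken as 1 at the terminus. This keeps "one
  cost term per stage", which is what makes `Score = (1 − f*/N) · 100`
  span `[0, 100]`; it also reconciles the `N`-term normalization with the
  `N − 1` inter-exon transitions of the objective.
* **Single-exon transcripts** (`N = 1`) are scored by the terminal rule
  alone: a full-length, significant hit scores 100, a fragmentary one is
  filterable, and a hopeless one loses to the (infeasible) all-skip
  assignment and is dropped. This avoids vacuously perfect scores for
  junk single-exon matches.
* **Skip bridging** (`skip_rela_policy = "bridge"`, the default). When
  stage `i` is skipped, the next retained hit's `Rela` compares the
  target gap against the source genomic span from the last retained
  exon's end to the next retained exon's start — the sum of the skipped
  introns and exons — keeping the two distances commensurable. The
  `"unit"` policy (`Rela := 1` across skips) is available for sensitivity
  checks. Each skipped stage always charges its own `K`.
* **Degenerate distance ratios.** Both distances 0 → `Rela = 1` (exons
  adjacent in both genomes); exactly one 0 → `Rela = 0`. These are the
  limits of min/max as either distance shrinks.
* **Overlaps and order.** The target gap between consecutive retained
  hits enters as an absolute value, so mild overlaps (alignment slop at
  exon edges) are tolerated; overlaps exceeding `max_overlap_frac`
  (default 0.5) of either hit are vetoed with an infinite cost, which
  also blocks grossly out-of-order chains through self-overlapping
  repeats. Residual small overlaps are trimmed on the downstream block at
  assembly so output blocks are disjoint.
* **Chain direction and strand.** Stages are traversed in ascending
  genomic order of the source exons; for a minus-strand source transcript
  the start/end roles simply reverse, which is cost-neutral because every
  term is symmetric in the pair. Exon query sequences are extracted
  transcript-oriented (minus-strand exons reverse-complemented), so a
  hit's subject orientation already composes the source strand with the
  target orientation: the annotation strand *is* the hit strand, and
  consecutive stages ascend in target coordinates exactly when hit strand
  equals source strand (collinear transfer) and descend otherwise
  (inverted transfer).
* **All-skip paths** cost `N · K` and compete in the minimization, but a
  winner with no retained alignment carries no coordinates and is
  declared infeasible outright; the transcript is dropped and logged
  rather than left to the score filter.
* **Skip selection is emergent, not thresholded.** Skip wins a stage
  whenever every alternative continuation costs more than `K`; no
  separate "alignment close to useless" cutoff exists, the `K = 0.95`
  penalty subsumes it.
* **Tie-breaking** (unspecified by the model): fewest skips, then
  lexicographically smallest sequence of target start coordinates, then
  input order. Costs within `1e-9` are treated as tied. This makes
  results deterministic and reproducible across worker counts.

# Quality control

Introns of a candidate annotation must read `GT...AG` on the annotation
strand (`CT...AC` on the genomic forward strand for minus annotations);
only the canonical class is checked — GC-AG and AT-AC junctions are out
of scope. A non-canonical junction triggers a bounded rescue: the donor
and acceptor boundaries may shift independently by up to
`max_splice_shift` (default 10 bp), candidates explored in order of
increasing total displacement with a fixed secondary order, first
canonical pair wins. A rescue moves the adjoining exon edges by the same
displacement, so exon + intron length across the boundary is conserved;
candidates that would empty an exon or shrink the intron below 4 bp are
discarded. If any junction stays non-canonical the annotation is kept and
flagged `N` — downstream users can decide, and the flag is the last
column of the output table. The rescue deliberately does **not** change
the score: the score is a property of the alignment path, QC is a
post-hoc coordinate refinement.

The final filter keeps annotations with score strictly greater than 80
("more than 80"); a transcript scoring exactly 80 is removed.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `K` | 0.95 | cost | skip penalty; `< 1` keeps skipping preferable to an infeasible stage, never to a good alignment |
| `min_score` | 80 | score points | strict retention threshold |
| `max_splice_shift` | 10 | bp | rescue radius per intron boundary |
| `max_hits_per_exon` | 500 | hits | stage-width cap, best E-values kept; bounds the DP, which is quadratic in stage width |
| `max_evalue` | Inf | — | admission ceiling; default accepts every table row |
| `max_overlap_frac` | 0.5 | fraction | consecutive-hit overlap veto |
| `skip_rela_policy` | "bridge" | — | distance handling across skips |
| `clamp_align` | TRUE | — | cap `Align` at 1 when gapped alignments exceed the exon length |

The aligned-length term uses the full HSP span as reported in column 4 of
the tabular format (matched-bases-only is not recoverable from that
format), clamped by `clamp_align`.

# The synthetic data generator

The fixtures module states a small but structured world: by default 10
multi-exon genes (3–6 exons of 80–200 bp, introns 200–800 bp) planted on
two 50 kb chromosomes, every intron canonical by construction. The
derived target applies per-base substitutions at 2.5% — the nucleotide
divergence regime of closely related mammalian genomes — sparse 1–3 bp
indels, optional whole-exon deletions (forcing skip states), and
segmental duplications that append whole-gene copies at the end of the
chromosome, generating decoy hits. The simulated alignment table emits
one hit at each surviving exon's true mapped location (E ≈ 1e-50,
full-length), one slightly degraded hit per duplication copy (E ≈ 1e-20,
97% length), and optional random noise hits, using the
`transcriptID|exonIndex|exonLength` query-id convention so exon identity
and length travel through the aligner format.

Deliberate idealizations, and hence what a green test does *not*
establish:

* **Splice dinucleotides are never mutated.** Real splice sites are under
  strong purifying selection, but real data still contains diverged
  junctions; the generator's conservation means QC rescue is exercised by
  the dedicated mis-assembly scenario rather than by background mutation.
* **E-values are synthesized, not computed** from a scoring model; only
  their ordering and rough magnitude matter to the cost, which consumes
  them as given.
* **Alignment geometry is exact**: hits sit precisely at the truth
  interval, so boundary errors of a real aligner (clipped exon edges,
  split HSPs, chimeric hits) are not represented.
* No rearrangements other than whole-gene duplication, no gene
  conversion, no N-runs or assembly gaps.

The mis-assembly preset reproduces the 2 bp-shift phenomenon seen when a
target assembly has lost bases at an intron/exon boundary: the source
intron is planted to end `...CCTT AG` with the downstream exon beginning
`AG`, and the target deletes the intron's terminal `AG`. The annotated
junction is then non-canonical at displacement 0 and ±1, and the rescue
finds GT-AG exactly at an acceptor shift of +2, conserving exon + intron
length — the mechanism, isolated from any particular genome.

Generator outputs are byte-deterministic in the seed (sub-seeds `seed`,
`seed + 1`, `seed + 2`, `seed + 7` partition the source build, target
mutation, alignment simulation and duplication spacers).

# Numerical and testing notes

The solver and the exhaustive-enumeration oracle share one canonical
cost fold (suffix-first addition, skipped runs added as `count × K`) and
one tie comparator, so their optimal costs and paths agree bitwise on
every instance within the enumeration guard — the property suite asserts
`identical()`, not approximate equality. The regression property for the
default mutation regime (≥ 95% of retained exon coordinates exactly equal
to the truth map over seeds 1–10) is a repository-fixed threshold
characterizing the stated world, not an external claim.

# Limitations

* No coding-region inference: `cdsStart = cdsEnd = txEnd` in the output.
* One candidate annotation per source transcript; no novel isoforms, no
  k-best paths.
* Only GT-AG junctions are recognized as canonical.
* The aligner is an upstream black box: alignment artefacts propagate
  into stages, mitigated but not eliminated by the E-value cap, stage cap
  and overlap veto.
* Exon boundaries are taken from alignment endpoints (plus QC shifts);
  there is no base-level spliced re-alignment.
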