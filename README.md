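# annolift

Cross-species structural genome annotation transfer by stage-wise
shortest-path exon chaining.

## The problem

When a eukaryotic genome is newly assembled, its structural annotation
(genes, transcripts, exons, splice junctions) usually lags years behind,
because conventional pipelines need species-specific ESTs, proteins or
RNA-Seq and substantial curation. When a closely related, well-annotated
species exists (e.g. ~97.5% nucleotide identity between human and rhesus
macaque), a much cheaper route is available: align every exon of every
annotated transcript of the *source* genome to the *target* genome with a
local aligner, then pick, per transcript, the combination of exon
alignments that best reconstitutes the transcript structure. Because
eukaryotic genomes are repeat rich, a single exon can align to thousands
of target loci, so picking that combination is a real optimization
problem, not a lookup.

`annolift` consumes (1) source annotations (genePred or GTF), (2) the
pre-computed exon-vs-target alignment table in the standard 12-column
tabular format, and (3) the target genome FASTA, and emits a genePred-like
annotation table plus transcript FASTA for the target genome. A seeded
fixture generator synthesizes all three inputs so the whole pipeline is
testable hermetically.

## The model

For a transcript with exons `1..N`, the candidate alignments of exon `i`
form decision stage `A_i`; each stage also carries a synthetic **skip**
state. A path chooses one state per stage, and the optimal exon
combination minimizes the summed one-step costs

```
d(A_i, A_{i+1}) = Chr_dist + Strand + Align_Rela        (alignment state)
d(A_i, A_{i+1}) = K = 0.95                              (skip state)
```

where `Chr_dist` and `Strand` are 0 when consecutive chosen alignments
share the target chromosome and strand and infinite otherwise, and

```
Align_Rela = 1 − Align(A_i) · Rela(A_i, A_{i+1})
Align(A_i) = (Align_Length / Exon_Length) · exp(−E-value)   ∈ [0, 1]
Rela       = min(|d_source|, |d_target|) / max(|d_source|, |d_target|)
```

compares the source intron length with the target gap between the chosen
alignments. The minimization is solved exactly by backward Bellman
recursion `f*(A_i) = min_{s} ( f*(A_{i+1,s}) + d(·,·) )` with
`f*(End) = 0`, and the optimum is normalized to

```
Score = (1 − f*/N) × 100        (100 = perfect transfer)
```

Candidate annotations then pass quality control: every intron must carry
the canonical `GT`-`AG` splice dinucleotides on the annotation strand;
non-canonical junctions are rescued by shifting either boundary by up to
10 bp (exon + intron length conserved), and transcripts that still fail
are flagged `N` in the last output column. Finally only annotations with
`Score > 80` are kept.

## Worked example

Everything below runs from a synthetic world: 10 multi-exon genes on two
50 kb chromosomes, mutated into a target at 2.5% substitutions with small
indels, two segmental-duplication decoy loci, and a 5% exon-deletion
rate.

```r
library(annolift)
fx <- generate_fixture_files(fixture_preset("default", seed = 1), "demo/fixtures")
cfg <- run_config(annotations = fx$annotations, alignments = fx$alignments,
                  target_genome = fx$target_genome, out_dir = "demo/out")
str(annotate_genome(cfg))
#> List of 6
#>  $ attempted : int 10
#>  $ feasible  : int 10
#>  $ infeasible: int 0
#>  $ low_score : int 1
#>  $ flagged_N : int 0
#>  $ retained  : int 9
```

Ten transcripts were attempted; all ten admitted a feasible exon chain;
one lost an exon to a target deletion, took the 0.95 skip penalty, fell
to a score below 80 and was filtered; nine were written, none needed the
`N` flag. The annotation table is genePred plus two columns (score,
canonical flag):

```
#name  chrom  strand  txStart  txEnd  cdsStart  cdsEnd  exonCount  exonStarts           exonEnds             score  flag
t001   chr1   +       464      2540   2540      2540    4          464,1264,1724,2369,  582,1372,1907,2540,  100
t003   chr1   -       2892     4643   4643      4643    3          2892,3636,4534,      3009,3801,4643,      100
```

and `log.tsv` records every transcript's outcome with its score:

```
transcript_id  status    score
t001           retained  100.000000
t002           retained  99.897119
```

The same run is available from the shell:

```sh
Rscript inst/cli/annolift.R fixtures --out demo/fixtures --seed 1 --preset default
Rscript inst/cli/annolift.R annotate \
    --annotations demo/fixtures/source.gp \
    --alignments demo/fixtures/alignments.tsv \
    --target-genome demo/fixtures/target_genome.fa \
    --out demo/out
```

## Scope notes

The package annotates transcript *structure* only: no CDS/ORF inference
(`cdsStart = cdsEnd = txEnd` in the output), no isoform discovery beyond
the source transcript set, and the exon-vs-target alignment itself is an
external pre-process whose tabular output is consumed as input. See
`vignettes/annolift-methods.Rmd` for the model details, parameter
rationale and limitations.
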