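#' Cost-model parameters
#'
#' @param K skip penalty in (0, 1], the fixed one-step cost charged when a
#'   stage takes its "skip" state (default 0.95). Because every finite
#'   alignment-to-alignment cost lies in `[0, 1]`, K just below 1 makes
#'   skipping always preferable to an infeasible stage but never
#'   preferable to a reasonably good alignment.
#' @param skip_rela_policy how the distance-ratio term is computed across
#'   skipped stages. `"bridge"` (default): the source distance is the
#'   genomic span from the last retained exon's end to the next retained
#'   exon's start (skipped introns and exons included), kept commensurable
#'   with the target gap. `"unit"`: the ratio is taken as 1 across any
#'   skip (sensitivity-check variant).
#' @param clamp_align clamp the alignment-quality term at 1 when gapped
#'   alignments make the aligned length exceed the exon length.
#' @param max_overlap_frac consecutive retained hits overlapping by more
#'   than this fraction of either hit's length are vetoed with `Inf`
#'   (guards against chaining self-overlapping repeats).
#' @return object of class `cost_params`.
#' @export
cost_params <- function(K = 0.95, skip_rela_policy = c("bridge", "unit"),
                        clamp_align = TRUE, max_overlap_frac = 0.5) {
  skip_rela_policy <- match.arg(skip_rela_policy)
  if (!(K > 0 && K <= 1)) stop("K must be in (0, 1]")
  structure(list(K = K, skip_rela_policy = skip_rela_policy,
                 clamp_align = clamp_align,
                 max_overlap_frac = max_overlap_frac),
            class = "cost_params")
}

#' Chromosome feasibility term
#'
#' 0 if two candidate alignments lie on a common target chromosome,
#' `Inf` otherwise.
#'
#' @param a,b alignment hits (one-row data.frames or lists with
#'   `target_chrom`).
#' @return 0 or `Inf`.
#' @export
chr_dist <- function(a, b) {
  if (identical(a$target_chrom, b$target_chrom)) 0 else Inf
}

#' Strand feasibility term
#'
#' 0 if two candidate alignments share the target strand, `Inf` otherwise.
#'
#' @param a,b alignment hits with `strand`.
#' @return 0 or `Inf`.
#' @export
strand_cost <- function(a, b) {
  if (identical(a$strand, b$strand)) 0 else Inf
}

#' Alignment quality of one hit
#'
#' `(align_length / exon_length) * exp(-evalue)`, the fraction of the
#' source exon covered by the alignment, discounted by the alignment's
#' statistical significance. 1 means a full-length, maximally significant
#' alignment.
#'
#' @param a an alignment hit with `align_length`, `exon_length`, `evalue`.
#' @param params a [cost_params()] object.
#' @return numeric in `[0, 1]` (clamped at 1 when `clamp_align`).
#' @export
align_quality <- function(a, params = cost_params()) {
  if (a$exon_length < 1) stop("exon_length must be >= 1")
  q <- (a$align_length / a$exon_length) * exp(-a$evalue)
  if (params$clamp_align) q <- min(q, 1)
  q
}

#' Inter-exon distance ratio
#'
#' `min(|d_s|, |d_t|) / max(|d_s|, |d_t|)` comparing the source intron
#' length with the target gap between consecutive retained hits; 1 means
#' perfectly comparable spacing. Degenerate cases: both distances 0 -> 1
#' (adjacent in both genomes); exactly one 0 -> 0.
#'
#' @param dist_source,dist_target absolute distances in bp (non-negative).
#' @return numeric in `[0, 1]`.
#' @export
rela <- function(dist_source, dist_target) {
  if (dist_source < 0 || dist_target < 0) {
    stop("rela() takes absolute distances; apply abs() first")
  }
  if (dist_source == 0 && dist_target == 0) return(1)
  if (dist_source == 0 || dist_target == 0) return(0)
  min(dist_source, dist_target) / max(dist_source, dist_target)
}

#' Target-genome gap between two consecutive retained hits
#'
#' Consecutive stages run in ascending target coordinates when the hit
#' strand equals the source transcript strand (collinear transfer) and
#' descending otherwise (inverted transfer); the gap is measured from the
#' end of the earlier hit in chain order to the start of the later one and
#' may be negative when the hits overlap.
#'
#' @param a,b alignment hits, `a` from the lower stage.
#' @param source_strand strand of the source transcript.
#' @return signed gap in bp.
#' @export
target_gap <- function(a, b, source_strand) {
  ascending <- identical(a$strand, source_strand)
  if (ascending) b$target_start - a$target_end else a$target_start - b$target_end
}

#' Combined alignment-and-relationship cost term
#'
#' `1 - align_quality(a) * rela(|d_source|, |d_target|)`; 0 means a
#' perfect alignment with ideally comparable inter-exon spacing. Hits
#' overlapping on the target by more than `max_overlap_frac` of either
#' hit's length give `Inf`.
#'
#' @param a,b consecutive alignment hits (`a` supplies the quality term).
#' @param dist_source source-genome distance in bp (absolute value taken).
#' @param params a [cost_params()] object.
#' @param source_strand source transcript strand (chain direction).
#' @return numeric in `[0, 1]` or `Inf`.
#' @export
align_rela <- function(a, b, dist_source, params = cost_params(),
                       source_strand = "+") {
  gap <- target_gap(a, b, source_strand)
  if (gap < 0) {
    ov <- -gap
    la <- a$target_end - a$target_start
    lb <- b$target_end - b$target_start
    if (ov > params$max_overlap_frac * la || ov > params$max_overlap_frac * lb) {
      return(Inf)
    }
  }
  1 - align_quality(a, params) * rela(abs(dist_source), abs(gap))
}

#' One-step cost between states of consecutive decision stages
#'
#' The transition cost charged to the state chosen at stage `stage_a`:
#' \itemize{
#'   \item skip state (`hit_a = NULL`): the fixed penalty `K`;
#'   \item alignment followed by an alignment at the next retained stage
#'     `stage_b`: chromosome feasibility + strand feasibility + the
#'     alignment/relationship term, with the source distance spanning any
#'     skipped stages in between (per `skip_rela_policy`); the `K` charges
#'     of skipped intermediate stages are accounted separately, one per
#'     skipped stage;
#'   \item alignment followed by the End point (`hit_b = NULL`,
#'     `stage_b = N + 1`): `1 - align_quality(hit_a)` (terminal rule: the
#'     distance-ratio factor is taken as 1 at the terminus, so every
#'     retained exon contributes exactly one cost term and the normalized
#'     score spans `[0, 100]`).
#' }
#' Infeasibility (different chromosome/strand, gross overlap) is encoded
#' as `Inf`, never as an error.
#'
#' @param hit_a alignment hit at `stage_a`, or `NULL` for the skip state.
#' @param hit_b alignment hit at `stage_b`, or `NULL` for the End point.
#' @param stage_a,stage_b 1-based stage ordinals; `stage_b` may exceed
#'   `stage_a + 1` when intermediate stages are skipped, and equals
#'   `N + 1` for the End point.
#' @param transcript the `source_transcript` (supplies inter-exon
#'   distances and chain direction).
#' @param params a [cost_params()] object.
#' @return non-negative numeric, possibly `Inf`.
#' @export
one_step_cost <- function(hit_a, hit_b, stage_a, stage_b, transcript,
                          params = cost_params()) {
  if (is.null(hit_a)) return(params$K)
  if (is.null(hit_b)) return(1 - align_quality(hit_a, params))
  feas <- chr_dist(hit_a, hit_b) + strand_cost(hit_a, hit_b)
  if (is.infinite(feas)) return(Inf)
  if (params$skip_rela_policy == "unit" && stage_b > stage_a + 1) {
    return(1 - align_quality(hit_a, params))
  }
  d_src <- transcript$exons$start[stage_b] - transcript$exons$end[stage_a]
  align_rela(hit_a, hit_b, d_src, params, source_strand = transcript$strand)
}
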