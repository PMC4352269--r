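#' Construct a splice junction
#'
#' The intron between two consecutive exon blocks: `[donor_pos,
#' acceptor_pos)` in 0-based genomic coordinates. On the "+" strand the
#' donor is the intron's left edge; on the "-" strand the genomic roles
#' reverse (the transcript-sense donor is the right edge), which is why
#' the canonical motif check reads CT...AC on the genomic forward strand.
#'
#' @param chrom chromosome name.
#' @param donor_pos,acceptor_pos intron boundaries, `acceptor_pos -
#'   donor_pos >= 4` (room for both dinucleotide motifs).
#' @param strand annotation strand.
#' @return object of class `junction`.
#' @export
junction <- function(chrom, donor_pos, acceptor_pos, strand) {
  if (acceptor_pos - donor_pos < 4) stop("intron length must be >= 4")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom),
                 donor_pos = as.integer(donor_pos),
                 acceptor_pos = as.integer(acceptor_pos),
                 strand = strand),
            class = "junction")
}

#' Test a junction for the canonical GT-AG motif
#'
#' TRUE iff, read on the annotation strand, the intron begins with "GT"
#' and ends with "AG" (genomic forward-strand reading "CT"..."AC" for a
#' minus-strand junction). About 98.7% of eukaryotic splice junctions are
#' canonical GT-AG; non-canonical classes (GC-AG, AT-AC) are deliberately
#' not recognized.
#'
#' @param genome target genome object.
#' @param j a [junction()].
#' @return logical.
#' @export
is_canonical <- function(genome, j) {
  first2 <- genome_slice(genome, j$chrom, j$donor_pos, j$donor_pos + 2L)
  last2 <- genome_slice(genome, j$chrom, j$acceptor_pos - 2L, j$acceptor_pos)
  if (j$strand == "+") {
    first2 == "GT" && last2 == "AG"
  } else {
    first2 == "CT" && last2 == "AC"
  }
}

#' Rescue a non-canonical junction by bounded boundary shifts
#'
#' Searches displacements of the two intron boundaries independently,
#' each by `delta` in `[-max_shift, +max_shift]`, for a canonical GT-AG
#' pair. Candidates are explored in order of increasing total displacement
#' `|delta_donor| + |delta_acceptor|` (then smaller `|delta_donor|`, then
#' ascending `delta_donor`, then ascending `delta_acceptor`), and the
#' first canonical candidate wins, so an already-canonical junction is
#' returned unchanged with shift 0. Shifted candidates whose intron drops
#' below 4 bp, or whose moved boundary would empty an adjoining exon
#' (`donor_min` / `acceptor_max`), are discarded.
#'
#' @param genome target genome object.
#' @param j a [junction()].
#' @param max_shift maximal displacement per side in bp (default 10).
#' @param donor_min exclusive lower bound for the shifted donor position
#'   (start of the upstream exon block).
#' @param acceptor_max exclusive upper bound for the shifted acceptor
#'   position (end of the downstream exon block).
#' @return list with `junction` (shifted), `shift_donor`,
#'   `shift_acceptor`, `shift_used` (= `|shift_donor| +
#'   |shift_acceptor|`), or `NULL` if no canonical pair exists in range.
#' @export
rescue_junction <- function(genome, j, max_shift = 10L, donor_min = -Inf,
                            acceptor_max = Inf) {
  stopifnot(max_shift >= 0)
  deltas <- seq.int(-max_shift, max_shift)
  grid <- expand.grid(dd = deltas, da = deltas, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(abs(grid$dd) + abs(grid$da), abs(grid$dd),
                     grid$dd, grid$da), , drop = FALSE]
  chrom_len <- genome_lengths(genome)[[j$chrom]]
  # one slice per side instead of one per candidate
  dw0 <- max(0L, j$donor_pos - max_shift)
  dw1 <- min(chrom_len, j$donor_pos + max_shift + 2L)
  aw0 <- max(0L, j$acceptor_pos - max_shift - 2L)
  aw1 <- min(chrom_len, j$acceptor_pos + max_shift)
  donor_win <- genome_slice(genome, j$chrom, dw0, dw1)
  acc_win <- genome_slice(genome, j$chrom, aw0, aw1)
  want_d <- if (j$strand == "+") "GT" else "CT"
  want_a <- if (j$strand == "+") "AG" else "AC"
  for (r in seq_len(nrow(grid))) {
    dd <- grid$dd[r]
    da <- grid$da[r]
    donor <- j$donor_pos + dd
    acceptor <- j$acceptor_pos + da
    if (acceptor - donor < 4) next
    if (donor <= donor_min || acceptor >= acceptor_max) next
    if (donor < 0 || donor + 2L > chrom_len) next
    if (acceptor - 2L < 0 || acceptor > chrom_len) next
    if (substr(donor_win, donor - dw0 + 1L, donor - dw0 + 2L) != want_d) next
    if (substr(acc_win, acceptor - 2L - aw0 + 1L, acceptor - aw0) != want_a) next
    return(list(junction = junction(j$chrom, donor, acceptor, j$strand),
                shift_donor = dd, shift_acceptor = da,
                shift_used = abs(dd) + abs(da)))
  }
  NULL
}

#' Quality-control a candidate annotation's splice junctions
#'
#' Every internal junction is checked for the canonical GT-AG motif; a
#' non-canonical junction triggers the bounded shift rescue, and a
#' successful rescue moves the adjoining exon boundaries by the same
#' displacement, conserving the summed exon + intron length across the
#' shifted boundary. If any junction remains non-canonical the annotation
#' is retained but flagged "N". The path score is left untouched: it is
#' defined on the alignment path, and QC is post-hoc. The operation is
#' idempotent.
#'
#' @param genome target genome object.
#' @param annotation a `candidate_annotation`.
#' @param max_shift maximal rescue displacement per side (default 10).
#' @return the adjusted `candidate_annotation`.
#' @export
apply_quality_control <- function(genome, annotation, max_shift = 10L) {
  blocks <- annotation$blocks
  flag <- "canonical"
  if (nrow(blocks) > 1) {
    for (k in seq_len(nrow(blocks) - 1)) {
      if (blocks$start[k + 1] - blocks$end[k] < 4) {
        flag <- "N"
        next
      }
      j <- junction(annotation$chrom, blocks$end[k], blocks$start[k + 1],
                    annotation$strand)
      res <- rescue_junction(genome, j, max_shift = max_shift,
                             donor_min = blocks$start[k],
                             acceptor_max = blocks$end[k + 1])
      if (is.null(res)) {
        flag <- "N"
      } else {
        blocks$end[k] <- res$junction$donor_pos
        blocks$start[k + 1] <- res$junction$acceptor_pos
      }
    }
  }
  candidate_annotation(
    transcript_id = annotation$transcript_id,
    source_transcript_id = annotation$source_transcript_id,
    chrom = annotation$chrom, strand = annotation$strand,
    blocks = blocks, score = annotation$score,
    canonical_flag = flag, skipped_exons = annotation$skipped_exons)
}

#' Filter annotations by normalized path score
#'
#' Keeps exactly the annotations whose score is strictly greater than
#' `min_score` (default 80), preserving order.
#'
#' @param annotations list of `candidate_annotation`.
#' @param min_score strict lower bound (default 80).
#' @return filtered list.
#' @export
filter_by_score <- function(annotations, min_score = 80) {
  Filter(function(a) a$score > min_score, annotations)
}
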