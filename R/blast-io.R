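#' Parse a 12-column tabular alignment table
#'
#' Reads the standard tab-separated tabular output of a pairwise local
#' aligner (qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore). The query id must encode exon
#' identity as `transcriptID|exonIndex|exonLength`, the convention used
#' when the exon FASTA fed to the aligner is produced by this package.
#' Subject coordinates are converted from 1-based inclusive to 0-based
#' half-open; `sstart > send` marks a minus-strand hit and coordinates are
#' normalized so `target_start < target_end`.
#'
#' @param path path to the alignment table.
#' @return data.frame of alignment hits with columns `transcript_id`,
#'   `exon_index`, `exon_length`, `target_chrom`, `target_start`,
#'   `target_end`, `strand`, `evalue`, `align_length`, `pident`,
#'   `bitscore`, `input_order`.
#' @export
parse_alignment_table <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lnos <- seq_along(keep)[keep]
  n <- length(lines)
  if (n == 0) return(empty_hits())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols != 12)) {
    bad <- which(ncols != 12)[1]
    stop(sprintf("alignment parse error at line %d: expected 12 columns, got %d",
                 lnos[bad], ncols[bad]))
  }
  m <- matrix(unlist(f), nrow = 12)
  q <- strsplit(m[1, ], "|", fixed = TRUE)
  if (any(lengths(q) != 3)) {
    bad <- which(lengths(q) != 3)[1]
    stop(sprintf("alignment parse error at line %d: qseqid '%s' is not 'transcriptID|exonIndex|exonLength'",
                 lnos[bad], m[1, bad]))
  }
  qm <- matrix(unlist(q), nrow = 3)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("alignment parse error at line %d: unparseable %s '%s'",
                   lnos[bad], what, col[bad]))
    }
    v
  }
  exon_index <- as.integer(num(qm[2, ], "exon index"))
  exon_length <- as.integer(num(qm[3, ], "exon length"))
  sstart <- as.integer(num(m[9, ], "sstart"))
  send <- as.integer(num(m[10, ], "send"))
  evalue <- num(m[11, ], "E-value")
  align_length <- as.integer(num(m[4, ], "alignment length"))
  strand <- ifelse(sstart <= send, "+", "-")
  lo <- pmin(sstart, send)
  hi <- pmax(sstart, send)
  hits <- data.frame(
    transcript_id = qm[1, ],
    exon_index = exon_index,
    exon_length = exon_length,
    target_chrom = m[2, ],
    target_start = lo - 1L,
    target_end = hi,
    strand = strand,
    evalue = evalue,
    align_length = align_length,
    pident = num(m[3, ], "percent identity"),
    bitscore = num(m[12, ], "bitscore"),
    input_order = seq_len(n),
    stringsAsFactors = FALSE)
  bad <- hits$evalue < 0 | hits$align_length < 1 | hits$target_start >= hits$target_end
  if (any(bad)) {
    stop(sprintf("alignment parse error at line %d: invalid hit (E-value < 0, align length < 1 or empty interval)",
                 lnos[which(bad)[1]]))
  }
  hits
}

empty_hits <- function() {
  data.frame(transcript_id = character(0), exon_index = integer(0),
             exon_length = integer(0), target_chrom = character(0),
             target_start = integer(0), target_end = integer(0),
             strand = character(0), evalue = numeric(0),
             align_length = integer(0), pident = numeric(0),
             bitscore = numeric(0), input_order = integer(0),
             stringsAsFactors = FALSE)
}

#' Assemble per-exon decision stages for one transcript
#'
#' Stage `i` gathers the candidate alignments of source exon `i` in the
#' target genome; an implicit "skip" state is always available to the
#' solver, so an exon with no hits yields an empty (skip-only) stage.
#' Within a stage hits are sorted by ascending E-value, then ascending
#' target start, then input order, and capped at `max_hits_per_exon`
#' (best E-values first) to bound the width of the dynamic program.
#'
#' @param transcript a `source_transcript`.
#' @param hits data.frame from [parse_alignment_table()].
#' @param max_hits_per_exon cap per stage (default 500).
#' @param max_evalue optional admission ceiling on E-value (default `Inf`:
#'   accept every row present in the table).
#' @return object of class `alignment_stages`: list of `N` hit
#'   data.frames, with attributes `transcript_id` and `N`.
#' @export
build_stages <- function(transcript, hits, max_hits_per_exon = 500L,
                         max_evalue = Inf) {
  hits <- hits[hits$transcript_id == transcript$transcript_id, , drop = FALSE]
  if (nrow(hits) && (any(hits$exon_index < 1) || any(hits$exon_index > transcript$N))) {
    stop(sprintf("hit with exon index outside 1..%d for transcript %s",
                 transcript$N, transcript$transcript_id))
  }
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  stages <- lapply(seq_len(transcript$N), function(i) {
    s <- hits[hits$exon_index == i, , drop = FALSE]
    s <- s[order(s$evalue, s$target_start, s$input_order), , drop = FALSE]
    if (nrow(s) > max_hits_per_exon) s <- s[seq_len(max_hits_per_exon), , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  structure(stages, class = "alignment_stages",
            transcript_id = transcript$transcript_id, N = transcript$N)
}

#' @export
print.alignment_stages <- function(x, ...) {
  cat(sprintf("<alignment_stages %s: %s hit(s) per stage>\n",
              attr(x, "transcript_id"),
              paste(vapply(x, nrow, 0L), collapse = ",")))
  invisible(x)
}
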