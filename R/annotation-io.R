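#' Construct a source transcript
#'
#' A source transcript is an annotated transcript of the source species:
#' an ordered set of exons on one chromosome and strand. Exons are stored
#' in ascending genomic order regardless of strand; transcription order is
#' derived where needed. Coordinates are 0-based half-open.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with integer columns `start`, `end`.
#' @return an object of class `source_transcript` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (sorted) and `N`.
#' @export
source_transcript <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) < 1) stop("transcript must have at least one exon")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end)) {
    stop(sprintf("transcript %s: exon with start >= end", transcript_id))
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop(sprintf("transcript %s: overlapping exons", transcript_id))
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 strand = strand,
                 exons = exons,
                 N = nrow(exons)),
            class = "source_transcript")
}

#' @export
print.source_transcript <- function(x, ...) {
  cat(sprintf("<source_transcript %s (%s) %s:%s %d exon(s)>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, x$N))
  invisible(x)
}

#' Exon lengths of a transcript (bp)
#' @param transcript a `source_transcript`.
#' @return integer vector of `end - start` per exon, genomic order.
#' @export
exon_lengths <- function(transcript) {
  transcript$exons$end - transcript$exons$start
}

#' Source inter-exon (intron) distances
#'
#' Distance between consecutive exons `i` and `i+1` in genomic order,
#' `start[i+1] - end[i]`; the intron length used by the distance-ratio
#' term of the cost model.
#'
#' @param transcript a `source_transcript`.
#' @return integer vector of length `N - 1` (length 0 for single-exon).
#' @export
intron_lengths <- function(transcript) {
  ex <- transcript$exons
  if (nrow(ex) < 2) return(integer(0))
  ex$start[-1] - ex$end[-nrow(ex)]
}

# -- reading ------------------------------------------------------------

#' Read source annotations
#'
#' Parses a genePred table (UCSC 10+ column format, 0-based half-open,
#' comma-terminated exon block lists; `#`-prefixed lines skipped) or a GTF
#' stream (only `exon` features consumed; 1-based inclusive coordinates
#' converted to 0-based half-open). Transcripts with zero exons are dropped
#' with a warning; malformed lines raise an error naming the line number.
#'
#' @param path path to the annotation file.
#' @param format "genepred" or "gtf".
#' @return list of [source_transcript()] objects.
#' @export
read_source_annotations <- function(path, format = c("genepred", "gtf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "genepred") read_genepred_lines(lines) else read_gtf_lines(lines)
}

read_genepred_lines <- function(lines) {
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) {
      stop(sprintf("genePred parse error at line %d: expected >= 10 columns, got %d",
                   ln, length(f)))
    }
    n_exon <- suppressWarnings(as.integer(f[8]))
    if (is.na(n_exon)) {
      stop(sprintf("genePred parse error at line %d: bad exonCount '%s'", ln, f[8]))
    }
    if (n_exon == 0) {
      warning(sprintf("line %d: transcript '%s' has zero exons; dropped", ln, f[1]))
      next
    }
    split_blocks <- function(x) {
      v <- strsplit(x, ",", fixed = TRUE)[[1]]
      suppressWarnings(as.integer(v[nzchar(v)]))
    }
    starts <- split_blocks(f[9])
    ends <- split_blocks(f[10])
    if (anyNA(starts) || anyNA(ends) ||
        length(starts) != n_exon || length(ends) != n_exon) {
      stop(sprintf("genePred parse error at line %d: inconsistent exon blocks", ln))
    }
    if (!f[3] %in% c("+", "-")) {
      stop(sprintf("genePred parse error at line %d: bad strand '%s'", ln, f[3]))
    }
    out[[length(out) + 1L]] <- source_transcript(
      transcript_id = f[1], gene_id = f[1], chrom = f[2], strand = f[3],
      exons = data.frame(start = starts, end = ends))
  }
  out
}

read_gtf_lines <- function(lines) {
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop(sprintf("GTF parse error at line %d: expected 9 columns, got %d",
                   ln, length(f)))
    }
    if (f[3] != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      stop(sprintf("GTF parse error at line %d: bad coordinates", ln))
    }
    tid <- gtf_attr(f[9], "transcript_id")
    gid <- gtf_attr(f[9], "gene_id")
    if (is.na(tid)) {
      stop(sprintf("GTF parse error at line %d: missing transcript_id", ln))
    }
    if (is.na(gid)) gid <- tid
    recs[[length(recs) + 1L]] <- list(tid = tid, gid = gid, chrom = f[1],
                                      strand = f[7],
                                      start = start - 1L, end = end)
  }
  if (!length(recs)) return(list())
  tids <- vapply(recs, `[[`, "", "tid")
  lapply(unique(tids), function(tid) {
    rr <- recs[tids == tid]
    chrom <- unique(vapply(rr, `[[`, "", "chrom"))
    strand <- unique(vapply(rr, `[[`, "", "strand"))
    if (length(chrom) != 1 || length(strand) != 1) {
      stop(sprintf("GTF: transcript '%s' spans multiple chromosomes or strands", tid))
    }
    source_transcript(
      transcript_id = tid, gene_id = rr[[1]]$gid, chrom = chrom, strand = strand,
      exons = data.frame(start = vapply(rr, `[[`, 0L, "start"),
                         end = vapply(rr, `[[`, 0L, "end")))
  })
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}

#' Extract exon sequences of a transcript
#'
#' One nucleotide string per exon, in genomic order of the exons. For a
#' minus-strand transcript each exon sequence is reverse-complemented
#' individually, so every returned sequence reads in transcript sense.
#'
#' @param genome a genome object.
#' @param transcript a `source_transcript` within chromosome bounds.
#' @return character vector of length `N`.
#' @export
extract_exon_sequences <- function(genome, transcript) {
  seqs <- vapply(seq_len(transcript$N), function(i) {
    genome_slice(genome, transcript$chrom,
                 transcript$exons$start[i], transcript$exons$end[i])
  }, character(1))
  if (transcript$strand == "-") seqs <- vapply(seqs, revcomp, character(1))
  unname(seqs)
}

# -- candidate annotations ---------------------------------------------

#' Construct a candidate annotation
#'
#' The assembled target-genome transcript model: the exon blocks chosen by
#' the shortest-path solver, the normalized path score, and the canonical
#' splice flag set by quality control ("N" marks a transcript with at least
#' one junction where no GT-AG could be found or rescued).
#'
#' @param transcript_id,source_transcript_id identifiers.
#' @param chrom,strand target chromosome and strand.
#' @param blocks data.frame with `start`, `end` (0-based half-open, sorted,
#'   non-overlapping).
#' @param score numeric in `[0, 100]`.
#' @param canonical_flag "canonical" or "N".
#' @param skipped_exons integer vector of skipped source exon ordinals.
#' @return object of class `candidate_annotation`.
#' @export
candidate_annotation <- function(transcript_id, source_transcript_id, chrom,
                                 strand, blocks, score,
                                 canonical_flag = "canonical",
                                 skipped_exons = integer(0)) {
  blocks <- blocks[order(blocks$start), c("start", "end"), drop = FALSE]
  blocks$start <- as.integer(blocks$start)
  blocks$end <- as.integer(blocks$end)
  rownames(blocks) <- NULL
  if (any(blocks$start >= blocks$end)) stop("annotation block with start >= end")
  if (nrow(blocks) > 1 && any(blocks$start[-1] < blocks$end[-nrow(blocks)])) {
    stop("overlapping annotation blocks")
  }
  if (score < 0 || score > 100) stop("score must be in [0, 100]")
  if (!canonical_flag %in% c("canonical", "N")) stop("bad canonical_flag")
  structure(list(transcript_id = as.character(transcript_id),
                 source_transcript_id = as.character(source_transcript_id),
                 chrom = as.character(chrom), strand = strand,
                 blocks = blocks, score = score,
                 canonical_flag = canonical_flag,
                 skipped_exons = as.integer(skipped_exons)),
            class = "candidate_annotation")
}

#' @export
print.candidate_annotation <- function(x, ...) {
  cat(sprintf("<candidate_annotation %s %s:%s %d block(s) score %.2f%s>\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$blocks), x$score,
              if (x$canonical_flag == "N") " [N]" else ""))
  invisible(x)
}

# -- writing ------------------------------------------------------------

#' Write candidate annotations as a genePred-plus table
#'
#' Tab-separated UCSC genePred column order (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) with two
#' trailing columns: the normalized path score and the canonical flag ("N"
#' for a non-canonical transcript, empty otherwise). No coding region is
#' inferred, so cdsStart = cdsEnd = txEnd. Rows sorted by (chrom, txStart,
#' name).
#'
#' @param annotations list of `candidate_annotation`.
#' @param path output file path.
#' @param header write a `#`-prefixed header line (default TRUE; with
#'   `header = FALSE` an empty annotation set yields an empty file).
#' @return number of rows written, invisibly.
#' @export
write_annotation_table <- function(annotations, path, header = TRUE) {
  hdr <- paste0("#", paste(c("name", "chrom", "strand", "txStart", "txEnd",
                             "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                             "exonEnds", "score", "flag"), collapse = "\t"))
  rows <- lapply(annotations, function(a) {
    tx_start <- min(a$blocks$start)
    tx_end <- max(a$blocks$end)
    c(a$transcript_id, a$chrom, a$strand, tx_start, tx_end,
      tx_end, tx_end, nrow(a$blocks),
      paste0(paste(a$blocks$start, collapse = ","), ","),
      paste0(paste(a$blocks$end, collapse = ","), ","),
      format(a$score, digits = 15),
      if (a$canonical_flag == "N") "N" else "")
  })
  if (length(rows)) {
    key <- order(vapply(rows, `[`, "", 2),
                 as.integer(vapply(rows, `[`, "", 4)),
                 vapply(rows, `[`, "", 1))
    rows <- rows[key]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(hdr, con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  invisible(length(rows))
}

#' Write transcript sequences of candidate annotations as FASTA
#'
#' Each record is the concatenation of the annotation's exon-block slices
#' from the target genome, reverse-complemented as a whole for minus-strand
#' annotations so the sequence reads in transcript sense. The header carries
#' the transcript id, source transcript id, score and canonical flag.
#'
#' @param genome target genome object.
#' @param annotations list of `candidate_annotation` (written in the same
#'   deterministic (chrom, txStart, name) order as the annotation table).
#' @param path output FASTA path.
#' @return number of records written, invisibly.
#' @export
write_transcript_fasta <- function(genome, annotations, path) {
  if (length(annotations)) {
    key <- order(vapply(annotations, `[[`, "", "chrom"),
                 vapply(annotations, function(a) min(a$blocks$start), 0L),
                 vapply(annotations, `[[`, "", "transcript_id"))
    annotations <- annotations[key]
  }
  seqs <- vapply(annotations, function(a) {
    s <- paste(vapply(seq_len(nrow(a$blocks)), function(i) {
      genome_slice(genome, a$chrom, a$blocks$start[i], a$blocks$end[i])
    }, character(1)), collapse = "")
    if (a$strand == "-") revcomp(s) else s
  }, character(1))
  names(seqs) <- vapply(annotations, function(a) {
    sprintf("%s source=%s score=%s flag=%s", a$transcript_id,
            a$source_transcript_id, format(a$score, digits = 15),
            if (a$canonical_flag == "N") "N" else "canonical")
  }, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(length(seqs))
}

#' Write source transcripts as a plain genePred table
#'
#' Companion writer used by the fixture generator; cdsStart = cdsEnd =
#' txEnd (no CDS inference).
#'
#' @param transcripts list of `source_transcript`.
#' @param path output path.
#' @return number of rows written, invisibly.
#' @export
write_genepred <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in transcripts) {
    writeLines(paste(c(
      tr$transcript_id, tr$chrom, tr$strand,
      min(tr$exons$start), max(tr$exons$end),
      max(tr$exons$end), max(tr$exons$end), tr$N,
      paste0(paste(tr$exons$start, collapse = ","), ","),
      paste0(paste(tr$exons$end, collapse = ","), ",")), collapse = "\t"), con)
  }
  invisible(length(transcripts))
}
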