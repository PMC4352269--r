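# Shared in-code fixtures: hand-built hits, stages and tiny worlds.

make_hit <- function(exon_index, target_start, target_end,
                     transcript_id = "t1", target_chrom = "chr1",
                     strand = "+", evalue = 0, exon_length = NULL,
                     align_length = NULL, input_order = 1L) {
  if (is.null(exon_length)) exon_length <- target_end - target_start
  if (is.null(align_length)) align_length <- exon_length
  data.frame(transcript_id = transcript_id, exon_index = as.integer(exon_index),
             exon_length = as.integer(exon_length),
             target_chrom = target_chrom,
             target_start = as.integer(target_start),
             target_end = as.integer(target_end),
             strand = strand, evalue = evalue,
             align_length = as.integer(align_length),
             pident = 100, bitscore = 2 * align_length,
             input_order = as.integer(input_order),
             stringsAsFactors = FALSE)
}

bind_hits <- function(...) {
  h <- do.call(rbind, list(...))
  h$input_order <- seq_len(nrow(h))
  h
}

# A 3-exon "+" transcript; perfect self-hits reproduce its coordinates.
tiny_transcript <- function(strand = "+", starts = c(100L, 400L, 900L),
                            ends = c(200L, 500L, 1000L), id = "t1") {
  source_transcript(id, id, "chr1", strand,
                    data.frame(start = starts, end = ends))
}

perfect_hits <- function(tr) {
  do.call(bind_hits, lapply(seq_len(tr$N), function(i) {
    make_hit(i, tr$exons$start[i], tr$exons$end[i], transcript_id = tr$transcript_id,
             strand = tr$strand)
  }))
}

# Random small DP instance for the oracle property: coherent hits with
# varying chromosomes, strands, coordinates and E-values.
random_dp_case <- function() {
  n_stages <- sample(1:5, 1)
  ex_len <- sample(50:150, n_stages, replace = TRUE)
  gaps <- if (n_stages > 1) sample(100:500, n_stages - 1, replace = TRUE) else integer(0)
  starts <- as.integer(cumsum(c(100L, utils::head(ex_len, -1) + gaps)))
  tr <- source_transcript("t1", "t1", "chr1", sample(c("+", "-"), 1),
                          data.frame(start = starts, end = starts + ex_len))
  rows <- list()
  for (i in seq_len(n_stages)) {
    for (h in seq_len(sample(0:4, 1))) {
      s <- sample(1:5000, 1)
      rows[[length(rows) + 1L]] <- make_hit(
        i, s, s + sample(40:160, 1),
        target_chrom = sample(c("chr1", "chr1", "chr1", "chr2"), 1),
        strand = sample(c("+", "+", "-"), 1),
        evalue = sample(c(0, 1e-30, 0.5, 2), 1),
        exon_length = ex_len[i],
        align_length = sample(20:160, 1))
    }
  }
  hits <- if (length(rows)) do.call(bind_hits, rows) else
    annolift:::empty_hits()
  list(transcript = tr, stages = build_stages(tr, hits))
}

# Genome with one canonical "+" intron and "C" background: GT only at the
# true donor, AG only at the true acceptor, so rescue is unambiguous.
splice_test_genome <- function(donor = 50L, acceptor = 150L, len = 300L) {
  chars <- rep("C", len)
  chars[(donor + 1):(donor + 2)] <- c("G", "T")
  chars[(acceptor - 1):acceptor] <- c("A", "G")
  as_genome(c(chr1 = paste(chars, collapse = "")))
}
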