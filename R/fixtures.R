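# Seeded synthetic worlds: a source genome with planted canonical genes,
# a mutated target genome with a truth map, and a simulated 12-column
# alignment table, so the full pipeline runs without any external genome
# or aligner.

#' Specify a synthetic fixture world
#'
#' Defaults describe the neutral (identity) world: no mutations, no
#' duplications, no exon deletions. The `default` preset moves the
#' substitution rate to 0.025 to emulate the ~97.5% nucleotide identity
#' regime of closely related mammalian genomes.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_chroms,chrom_length chromosome count and length (bp).
#' @param n_genes number of planted genes (one transcript each).
#' @param exons_per_gene,exon_length,intron_length inclusive `c(min, max)`
#'   ranges.
#' @param gene_gap range of intergenic spacing (bp).
#' @param substitution_rate per-bp substitution probability in the target
#'   (splice-site dinucleotides are exempt: junction motifs are under
#'   strong purifying selection in real genomes).
#' @param indel_rate per-bp probability of a small indel (half deletions
#'   of 1 bp, half insertions of 1-3 bp).
#' @param n_segmental_duplications gene copies appended at the end of
#'   their chromosome; each creates decoy alignment hits.
#' @param skip_exon_prob probability an exon is deleted from the target
#'   (forces skip states).
#' @param noise_hits spurious random hits per transcript in the simulated
#'   alignment table.
#' @param misassembly plant the 2 bp acceptor-side deletion scenario
#'   (see [derive_target_genome()]).
#' @param force_plus_strand place all genes on "+" (used by the
#'   misassembly preset so the planted junction is unambiguous).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 2L, chrom_length = 50000L,
                         n_genes = 10L, exons_per_gene = c(3L, 6L),
                         exon_length = c(80L, 200L),
                         intron_length = c(200L, 800L),
                         gene_gap = c(300L, 800L),
                         substitution_rate = 0, indel_rate = 0,
                         n_segmental_duplications = 0L,
                         skip_exon_prob = 0, noise_hits = 0L,
                         misassembly = FALSE, force_plus_strand = FALSE) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            skip_exon_prob >= 0, skip_exon_prob <= 1,
            chrom_length > 0, n_chroms >= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 gene_gap = as.integer(gene_gap),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 n_segmental_duplications = as.integer(n_segmental_duplications),
                 skip_exon_prob = skip_exon_prob,
                 noise_hits = as.integer(noise_hits),
                 misassembly = isTRUE(misassembly),
                 force_plus_strand = isTRUE(force_plus_strand)),
            class = "fixture_spec")
}

#' Named fixture presets
#'
#' \describe{
#'   \item{identity}{target = source, truth map is the identity.}
#'   \item{default}{2.5% substitutions, sparse 1-3 bp indels, 2 segmental
#'     duplications, 5% exon deletions.}
#'   \item{misassembly}{identity world plus a planted 2 bp deletion at one
#'     acceptor, recoverable only by a 2 bp splice-rescue shift.}
#'   \item{repeats}{1% substitutions and 3 segmental duplications (decoy
#'     stress).}
#' }
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return a [fixture_spec()].
#' @export
fixture_preset <- function(preset = c("identity", "default", "misassembly",
                                      "repeats"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    identity = fixture_spec(seed = seed),
    default = fixture_spec(seed = seed, substitution_rate = 0.025,
                           indel_rate = 5e-4, n_segmental_duplications = 2L,
                           skip_exon_prob = 0.05),
    misassembly = fixture_spec(seed = seed, misassembly = TRUE,
                               force_plus_strand = TRUE),
    repeats = fixture_spec(seed = seed, substitution_rate = 0.01,
                           n_segmental_duplications = 3L))
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate the source world: genome plus annotations
#'
#' Plants `n_genes` multi-exon genes (one transcript each) into random
#' chromosome sequences, overwriting each intron's boundary dinucleotides
#' so every junction is canonical GT-AG on the transcript strand. With
#' `misassembly = TRUE` the first intron of gene 1 additionally gets a
#' fixed tail (`...CCTTAG`) and the downstream exon a leading `AG`, the
#' scaffold for the planted 2 bp-shift scenario.
#'
#' @param spec a [fixture_spec()].
#' @return object of class `fixture_world`: `genome` (DNAStringSet),
#'   `transcripts` (list of `source_transcript`), `misassembly` (planted
#'   junction info or NULL), `spec`.
#' @export
make_source_world <- function(spec) {
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  chars <- lapply(chroms, function(x) rand_bases(spec$chrom_length))
  names(chars) <- chroms
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  cursors <- stats::setNames(rep(0L, spec$n_chroms), chroms)
  transcripts <- list()
  mis <- NULL
  for (g in seq_len(spec$n_genes)) {
    chrom <- chroms[((g - 1) %% spec$n_chroms) + 1]
    n_ex <- rint(spec$exons_per_gene)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(spec$exon_length), 0L)
    in_len <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(i) rint(spec$intron_length), 0L)
    } else integer(0)
    strand <- if (spec$force_plus_strand) "+" else sample(c("+", "-"), 1)
    gap <- rint(spec$gene_gap)
    start0 <- cursors[[chrom]] + gap
    span <- sum(ex_len) + sum(in_len)
    if (start0 + span + 10L > spec$chrom_length) {
      stop(sprintf("chromosome %s too short for gene %d; increase chrom_length",
                   chrom, g))
    }
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- start0
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i]
      pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
    }
    cc <- chars[[chrom]]
    for (i in seq_len(max(0, n_ex - 1))) {
      d <- ends[i]          # intron [d, a), 0-based
      a <- starts[i + 1]
      if (strand == "+") {
        cc[(d + 1):(d + 2)] <- c("G", "T")
        cc[(a - 1):a] <- c("A", "G")
      } else {
        cc[(d + 1):(d + 2)] <- c("C", "T")
        cc[(a - 1):a] <- c("A", "C")
      }
    }
    if (spec$misassembly && g == 1L && n_ex > 1) {
      d <- ends[1]
      a <- starts[2]
      cc[(a - 5):a] <- c("C", "C", "T", "T", "A", "G")
      cc[(a + 1):(a + 2)] <- c("A", "G")  # downstream exon leads with AG
      cc[(d + 3):(d + 4)] <- c("C", "C")  # no accidental GT near the donor
      mis <- list(chrom = chrom, transcript_id = sprintf("t%03d", g),
                  donor_pos = d, acceptor_pos = a)
    }
    chars[[chrom]] <- cc
    transcripts[[g]] <- source_transcript(
      transcript_id = sprintf("t%03d", g), gene_id = sprintf("g%03d", g),
      chrom = chrom, strand = strand,
      exons = data.frame(start = starts, end = ends))
    cursors[[chrom]] <- ends[n_ex]
  }
  genome <- as_genome(vapply(chars, paste, character(1), collapse = ""))
  structure(list(genome = genome, transcripts = transcripts,
                 misassembly = mis, spec = spec),
            class = "fixture_world")
}

#' Derive the mutated target genome and its truth map
#'
#' Applies per-bp substitutions and small indels, deletes exons with
#' probability `skip_exon_prob`, removes the terminal "AG" of the planted
#' intron in misassembly mode, and appends segmental duplication copies
#' of whole genes at the end of their chromosome. Splice-site
#' dinucleotides are exempt from mutation. The truth map records where
#' every surviving source exon lies in the target.
#'
#' @param world a `fixture_world`.
#' @return object of class `target_world`: `genome` (DNAStringSet),
#'   `truth` (data.frame transcript_id, exon_index, chrom, start, end,
#'   strand, deleted), `decoys` (same columns, duplication copies).
#' @export
derive_target_genome <- function(world) {
  spec <- world$spec
  set.seed(spec$seed + 1L)
  src_chars <- lapply(as.character(world$genome), function(s) {
    strsplit(s, "", fixed = TRUE)[[1]]
  })
  chroms <- names(world$genome)

  # per-chromosome protected positions (0-based) = intron boundary motifs
  protected <- stats::setNames(lapply(chroms, function(x) integer(0)), chroms)
  for (tr in world$transcripts) {
    if (tr$N < 2) next
    d <- tr$exons$end[-tr$N]
    a <- tr$exons$start[-1]
    protected[[tr$chrom]] <- c(protected[[tr$chrom]],
                               d, d + 1L, a - 2L, a - 1L)
  }

  # exon deletions
  del_exons <- list()
  for (tr in world$transcripts) {
    drop <- stats::runif(tr$N) < spec$skip_exon_prob
    if (any(drop)) {
      del_exons[[tr$transcript_id]] <- which(drop)
    }
  }

  tgt_chars <- list()
  map0 <- list()  # map0[[chrom]][p + 1] = target 0-based pos of source pos p
  for (chrom in chroms) {
    cc <- src_chars[[chrom]]
    L <- length(cc)
    prot <- rep(FALSE, L)
    prot[protected[[chrom]] + 1L] <- TRUE
    drop_pos <- rep(FALSE, L)
    for (tr in world$transcripts) {
      if (tr$chrom != chrom) next
      for (i in del_exons[[tr$transcript_id]]) {
        drop_pos[(tr$exons$start[i] + 1L):tr$exons$end[i]] <- TRUE
      }
    }
    if (!is.null(world$misassembly) && world$misassembly$chrom == chrom) {
      a <- world$misassembly$acceptor_pos
      drop_pos[(a - 1L):a] <- TRUE  # delete the intron's terminal "AG"
    }
    sub <- stats::runif(L) < spec$substitution_rate & !prot & !drop_pos
    if (any(sub)) {
      cc[sub] <- vapply(cc[sub], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    del <- stats::runif(L) < spec$indel_rate / 2 & !prot & !drop_pos
    ins <- stats::runif(L) < spec$indel_rate / 2 & !prot
    out <- ifelse(drop_pos | del, "", cc)
    if (any(ins)) {
      for (p in which(ins)) {
        out[p] <- paste0(out[p], paste(rand_bases(sample(1:3, 1)), collapse = ""))
      }
    }
    tgt_chars[[chrom]] <- paste(out, collapse = "")
    map0[[chrom]] <- c(0L, cumsum(nchar(out)))
  }

  truth <- do.call(rbind, lapply(world$transcripts, function(tr) {
    m <- map0[[tr$chrom]]
    deleted <- seq_len(tr$N) %in% del_exons[[tr$transcript_id]]
    data.frame(transcript_id = tr$transcript_id,
               exon_index = seq_len(tr$N),
               chrom = tr$chrom,
               start = m[tr$exons$start + 1L],
               end = m[tr$exons$end + 1L],
               strand = tr$strand,
               deleted = deleted,
               stringsAsFactors = FALSE)
  }))

  # segmental duplications: whole-gene copies appended to the chromosome
  decoys <- NULL
  if (spec$n_segmental_duplications > 0 && length(world$transcripts)) {
    set.seed(spec$seed + 7L)
    picks <- rep(seq_along(world$transcripts),
                 length.out = spec$n_segmental_duplications)
    dec <- list()
    for (gi in picks) {
      tr <- world$transcripts[[gi]]
      m <- map0[[tr$chrom]]
      g_start <- m[min(tr$exons$start) + 1L]
      g_end <- m[max(tr$exons$end) + 1L]
      body <- substr(tgt_chars[[tr$chrom]], g_start + 1L, g_end)
      spacer <- paste(rand_bases(200L), collapse = "")
      offset <- nchar(tgt_chars[[tr$chrom]]) + nchar(spacer) - g_start
      tgt_chars[[tr$chrom]] <- paste0(tgt_chars[[tr$chrom]], spacer, body)
      tt <- truth[truth$transcript_id == tr$transcript_id & !truth$deleted, ,
                  drop = FALSE]
      if (nrow(tt)) {
        tt$start <- tt$start + offset
        tt$end <- tt$end + offset
        dec[[length(dec) + 1L]] <- tt
      }
    }
    if (length(dec)) decoys <- do.call(rbind, dec)
  }

  genome <- as_genome(vapply(tgt_chars, paste, character(1), collapse = "")[chroms])
  structure(list(genome = genome, truth = truth, decoys = decoys,
                 spec = spec), class = "target_world")
}

#' Simulate the 12-column alignment table
#'
#' For every surviving source exon one hit is emitted at its true target
#' location (E-value drawn around 1e-50, full-length alignment); each
#' segmental-duplication copy contributes a decoy hit with slightly worse
#' E-value and 97% aligned length, and `noise_hits` adds random spurious
#' hits. Query ids follow the `transcriptID|exonIndex|exonLength`
#' convention; subject coordinates are 1-based inclusive with minus-strand
#' hits encoded by inverted sstart/send, matching real aligner output.
#'
#' @param world the `fixture_world`.
#' @param target the matching `target_world`.
#' @param path optional output path; when given, lines are written as a
#'   tab-separated file.
#' @return the table as a data.frame of raw columns, invisibly when
#'   `path` is given.
#' @export
simulate_alignment_table <- function(world, target, path = NULL) {
  spec <- world$spec
  set.seed(spec$seed + 2L)
  exlen <- stats::setNames(
    lapply(world$transcripts, exon_lengths),
    vapply(world$transcripts, `[[`, "", "transcript_id"))
  tlen <- genome_lengths(target$genome)
  mk_row <- function(tid, i, elen, chrom, start, end, strand, evalue, alen,
                     pident) {
    sstart <- if (strand == "+") start + 1L else end
    send <- if (strand == "+") end else start + 1L
    c(sprintf("%s|%d|%d", tid, i, elen), chrom, sprintf("%.2f", pident),
      alen, 0L, 0L, 1L, alen, sstart, send, sprintf("%.2e", evalue),
      2L * alen)
  }
  rows <- list()
  emit <- function(df, evalue_lo, evalue_hi, alen_frac, pident) {
    for (r in seq_len(nrow(df))) {
      tid <- df$transcript_id[r]
      i <- df$exon_index[r]
      elen <- exlen[[tid]][i]
      alen <- max(1L, as.integer(floor(alen_frac * elen)))
      ev <- 10^-stats::runif(1, evalue_lo, evalue_hi)
      rows[[length(rows) + 1L]] <<- mk_row(tid, i, elen, df$chrom[r],
                                           df$start[r], df$end[r],
                                           df$strand[r], ev, alen, pident)
    }
  }
  surv <- target$truth[!target$truth$deleted & target$truth$end >
                         target$truth$start, , drop = FALSE]
  emit(surv, 40, 60, 1, 100 - 100 * spec$substitution_rate)
  if (!is.null(target$decoys)) {
    emit(target$decoys, 18, 22, 0.97, 95)
  }
  if (spec$noise_hits > 0) {
    for (tr in world$transcripts) {
      for (k in seq_len(spec$noise_hits)) {
        i <- sample(tr$N, 1)
        elen <- exlen[[tr$transcript_id]][i]
        alen <- max(1L, elen %/% 2L)
        chrom <- sample(names(tlen), 1)
        start <- sample(max(1L, tlen[[chrom]] - alen), 1) - 1L
        rows[[length(rows) + 1L]] <- mk_row(tr$transcript_id, i, elen, chrom,
                                            start, start + alen,
                                            sample(c("+", "-"), 1), 1e-5,
                                            alen, 85)
      }
    }
  }
  mat <- if (length(rows)) do.call(rbind, rows) else matrix(character(0), ncol = 12)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  if (!is.null(path)) {
    lines <- if (nrow(mat)) apply(mat, 1, paste, collapse = "\t") else character(0)
    writeLines(lines, path)
    return(invisible(df))
  }
  df
}

#' Write a complete fixture world to disk
#'
#' Produces the four pipeline inputs (source genePred, source genome
#' FASTA, target genome FASTA, alignment table) plus the truth map as
#' plain-text files in `dir`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named list of file paths plus the in-memory `world` and
#'   `target` objects, invisibly.
#' @export
generate_fixture_files <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  world <- make_source_world(spec)
  target <- derive_target_genome(world)
  paths <- list(
    annotations = file.path(dir, "source.gp"),
    source_genome = file.path(dir, "source_genome.fa"),
    target_genome = file.path(dir, "target_genome.fa"),
    alignments = file.path(dir, "alignments.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_genepred(world$transcripts, paths$annotations)
  Biostrings::writeXStringSet(world$genome, paths$source_genome, width = 70L)
  Biostrings::writeXStringSet(target$genome, paths$target_genome, width = 70L)
  simulate_alignment_table(world, target, path = paths$alignments)
  utils::write.table(target$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(world = world, target = target)))
}
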