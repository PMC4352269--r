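test_that("genePred rows map to 0-based half-open exon blocks", {
  path <- withr::local_tempfile(lines = paste(
    c("tx1", "chr1", "+", 100, 400, 400, 400, 2, "100,300,", "200,400,"),
    collapse = "\t"))
  trs <- read_source_annotations(path, "genepred")
  expect_length(trs, 1)
  tr <- trs[[1]]
  expect_equal(tr$exons$start, c(100L, 300L))
  expect_equal(tr$exons$end, c(200L, 400L))
  expect_equal(intron_lengths(tr), 100L)
  expect_equal(exon_lengths(tr), c(100L, 100L))
})

test_that("genePred errors name the offending line and zero-exon rows are dropped", {
  bad <- withr::local_tempfile(lines = c(
    paste(c("ok", "chr1", "+", 0, 10, 10, 10, 1, "0,", "10,"), collapse = "\t"),
    "too\tfew\tcolumns"))
  expect_error(read_source_annotations(bad, "genepred"), "line 2")
  zero <- withr::local_tempfile(lines = paste(
    c("empty", "chr1", "+", 0, 0, 0, 0, 0, ",", ","), collapse = "\t"))
  expect_warning(trs <- read_source_annotations(zero, "genepred"), "zero exons")
  expect_length(trs, 0)
  empty <- withr::local_tempfile(lines = character(0))
  expect_length(read_source_annotations(empty, "genepred"), 0)
})

test_that("GTF exon features on '-' strand parse to ascending sorted blocks", {
  path <- withr::local_tempfile(lines = c(
    "# comment",
    paste(c("chr2", "src", "exon", 301, 400, ".", "-", ".",
            'gene_id "g1"; transcript_id "tA";'), collapse = "\t"),
    paste(c("chr2", "src", "exon", 101, 200, ".", "-", ".",
            'gene_id "g1"; transcript_id "tA";'), collapse = "\t"),
    paste(c("chr2", "src", "CDS", 101, 200, ".", "-", ".",
            'gene_id "g1"; transcript_id "tA";'), collapse = "\t")))
  trs <- read_source_annotations(path, "gtf")
  expect_length(trs, 1)
  expect_equal(trs[[1]]$exons$start, c(100L, 300L))
  expect_equal(trs[[1]]$exons$end, c(200L, 400L))
  expect_identical(trs[[1]]$strand, "-")
  expect_identical(trs[[1]]$gene_id, "g1")
})

test_that("exon sequence extraction is strand-aware", {
  gen <- as_genome(c(chr1 = "ACGTTT"))
  plus <- source_transcript("p", "p", "chr1", "+", data.frame(start = 0, end = 4))
  expect_identical(extract_exon_sequences(gen, plus), "ACGT")
  minus <- source_transcript("m", "m", "chr1", "-", data.frame(start = 1, end = 4))
  expect_identical(extract_exon_sequences(gen, minus), "ACG")  # revcomp("CGT")
  out <- source_transcript("o", "o", "chr1", "+", data.frame(start = 2, end = 9))
  expect_error(extract_exon_sequences(gen, out), "out of range")
})

test_that("extraction on '-' is the reverse complement of extraction on '+'", {
  set.seed(42)
  gen <- as_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                  collapse = "")))
  for (k in 1:10) {
    s <- sample(0:150, 1)
    e <- s + sample(5:40, 1)
    p <- source_transcript("p", "p", "chr1", "+", data.frame(start = s, end = e))
    m <- source_transcript("m", "m", "chr1", "-", data.frame(start = s, end = e))
    expect_identical(extract_exon_sequences(gen, m),
                     revcomp(extract_exon_sequences(gen, p)))
  }
})

test_that("annotation table writes the N flag and round-trips exon blocks", {
  a1 <- candidate_annotation("tA", "tA", "chr1", "+",
                             data.frame(start = c(10, 50), end = c(20, 70)),
                             score = 91.5, canonical_flag = "N")
  a2 <- candidate_annotation("tB", "tB", "chr1", "-",
                             data.frame(start = 5, end = 9), score = 100)
  path <- withr::local_tempfile()
  expect_equal(write_annotation_table(list(a1, a2), path), 2)
  lines <- readLines(path)
  expect_match(lines[1], "^#name")
  fields <- strsplit(lines[-1], "\t")
  # sorted by txStart: tB (5) before tA (10); N flag in last column
  expect_identical(vapply(fields, `[`, "", 1), c("tB", "tA"))
  # trailing flag column: empty for canonical (trailing tab), "N" otherwise
  expect_identical(vapply(fields, function(f) {
    if (length(f) >= 12) f[12] else ""
  }, ""), c("", "N"))
  # cds fields collapse to txEnd (no CDS inference)
  expect_identical(fields[[2]][6:7], c("70", "70"))
  back <- read_source_annotations(path, "genepred")
  expect_equal(back[[2]]$exons, a1$blocks)
  expect_identical(back[[2]]$strand, "+")
  expect_identical(back[[1]]$strand, "-")
})

test_that("empty annotation sets write header-only or empty files", {
  p1 <- withr::local_tempfile()
  write_annotation_table(list(), p1)
  expect_identical(length(readLines(p1)), 1L)
  p2 <- withr::local_tempfile()
  write_annotation_table(list(), p2, header = FALSE)
  expect_identical(length(readLines(p2)), 0L)
})

test_that("transcript FASTA concatenates blocks and reverse-complements '-' records", {
  gen <- as_genome(c(chr1 = "ACGTTT"))
  blocks <- data.frame(start = c(0, 4), end = c(2, 6))
  plus <- candidate_annotation("p", "p", "chr1", "+", blocks, 100)
  minus <- candidate_annotation("m", "m", "chr1", "-", blocks, 100)
  path <- withr::local_tempfile()
  expect_equal(write_transcript_fasta(gen, list(plus, minus), path), 2)
  seqs <- Biostrings::readDNAStringSet(path)
  got <- as.character(seqs)
  names(got) <- sub("\\s.*", "", names(seqs))
  expect_identical(unname(got[c("p", "m")]), c("ACTT", "AAGT"))
  expect_match(names(seqs)[1], "source=")
  expect_equal(unname(nchar(got)), rep(sum(blocks$end - blocks$start), 2))
  p0 <- withr::local_tempfile()
  expect_equal(write_transcript_fasta(gen, list(), p0), 0)
})
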