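#' Read a genome FASTA into a genome sequence object
#'
#' Loads a (multi-)FASTA file with [Biostrings::readDNAStringSet()] and
#' normalizes it for use as a random-access genome: sequence names are
#' truncated at the first whitespace and bases are uppercased.
#'
#' @param path path to an uncompressed or gzipped FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome_fasta <- function(path) {
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  as_genome(gen)
}

#' Coerce sequences to a genome object
#'
#' Accepts a named character vector or a `DNAStringSet`; names are the
#' chromosome identifiers. All coordinates taken by [genome_slice()] are
#' 0-based half-open.
#'
#' @param x named character vector of sequences or a `DNAStringSet`.
#' @return an uppercased `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("genome sequences must be named by chromosome")
    }
    x <- Biostrings::DNAStringSet(x)
  }
  if (!methods::is(x, "DNAStringSet")) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(x))) stop("duplicated chromosome names in genome")
  Biostrings::DNAStringSet(toupper(x))
}

#' Chromosome lengths of a genome
#' @param genome a genome object from [as_genome()].
#' @return named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Extract a genomic slice
#'
#' @param genome a genome object.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return uppercase nucleotide string of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start > end) {
    stop(sprintf("slice [%d,%d) out of range for %s (length %d)",
                 start, end, chrom, len))
  }
  if (start == end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
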