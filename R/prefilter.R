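# Optional input-cleaning filters applied to read libraries before analysis.
# All return a new read_library with totals recomputed.

rebuild_library <- function(lib, keep) {
  rec <- lib$records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(name = lib$name, records = rec,
                 total_abundance = sum(rec$abundance)),
            class = "read_library")
}

#' Discard reads containing ambiguous bases
#'
#' @param lib a `read_library`.
#' @return filtered `read_library`.
#' @export
filter_ambiguous <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  rebuild_library(lib, grepl("^[ACGT]+$", lib$records$sequence))
}

max_kmer_fraction <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(0)
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  max(tabulate(factor(kmers))) / n
}

#' Discard low-complexity reads
#'
#' A sequence is discarded when its most frequent single, di- or
#' tri-nucleotide accounts for more than 75%, 37.5% or 25% of its
#' overlapping 1-, 2- or 3-mer windows, respectively (denominator
#' `L - k + 1`). The thresholds are strict: a sequence exactly at a boundary
#' is kept.
#'
#' @param lib a `read_library`.
#' @return filtered `read_library`.
#' @export
filter_low_complexity <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  keep <- vapply(lib$records$sequence, function(s) {
    max_kmer_fraction(s, 1L) <= 0.75 &&
      max_kmer_fraction(s, 2L) <= 0.375 &&
      max_kmer_fraction(s, 3L) <= 0.25
  }, logical(1), USE.NAMES = FALSE)
  rebuild_library(lib, keep)
}

#' Keep only reads conserved across all replicate libraries
#'
#' @param libs list of `read_library` objects (>= 2; a single library is
#'   returned unchanged with a warning).
#' @return list of filtered libraries, each restricted to the sequences
#'   present (abundance >= 1) in every input library.
#' @export
filter_conservation <- function(libs) {
  stopifnot(is.list(libs), all(vapply(libs, inherits, logical(1), "read_library")))
  if (length(libs) < 2L) {
    warning("conservation filter needs >= 2 libraries; returning input unchanged")
    return(libs)
  }
  common <- Reduce(intersect, lapply(libs, function(l) l$records$sequence))
  lapply(libs, function(l) rebuild_library(l, l$records$sequence %in% common))
}

#' Keep only reads with an exact full-length genome match
#'
#' A read is kept iff it occurs as an exact substring (0 mismatches) of either
#' strand of any chromosome.
#'
#' @param lib a `read_library`.
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @return filtered `read_library`.
#' @export
filter_genome_match <- function(lib, genome) {
  stopifnot(inherits(lib, "read_library"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_transcriptome_fasta(genome)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  if (length(genome) == 0L) stop("genome is empty")
  keep <- vapply(lib$records$sequence, function(s) {
    fwd <- Biostrings::vcountPattern(s, genome, fixed = TRUE)
    if (any(fwd > 0L)) return(TRUE)
    any(Biostrings::vcountPattern(revcomp(s), genome, fixed = TRUE) > 0L)
  }, logical(1), USE.NAMES = FALSE)
  rebuild_library(lib, keep)
}

#' Filter reads by length range and minimum abundance
#'
#' @param lib a `read_library`.
#' @param min_len,max_len inclusive length bounds (nt).
#' @param min_abundance minimum collapsed read abundance.
#' @return filtered `read_library`.
#' @export
filter_size_abundance <- function(lib, min_len, max_len, min_abundance = 1L) {
  stopifnot(inherits(lib, "read_library"), min_len <= max_len)
  len <- nchar(lib$records$sequence)
  rebuild_library(lib, len >= min_len & len <= max_len &
                    lib$records$abundance >= min_abundance)
}
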