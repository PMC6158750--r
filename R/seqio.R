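#' @importFrom Rcpp sourceCpp
#' @useDynLib paretarget, .registration = TRUE
"_PACKAGE"

# ---- read libraries --------------------------------------------------------

new_read_library <- function(sequences, abundances, names = NULL,
                             name = "library") {
  stopifnot(length(sequences) == length(abundances))
  if (is.null(names)) names <- sequences
  ord <- order(sequences)
  sequences <- sequences[ord]; abundances <- abundances[ord]; names <- names[ord]
  first <- !duplicated(sequences)
  ab <- as.integer(tapply(abundances, factor(sequences, levels = sequences[first]),
                          sum))
  rec <- data.frame(name = names[first], sequence = sequences[first],
                    abundance = ab, stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  structure(list(name = name, records = rec,
                 total_abundance = sum(rec$abundance)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> '%s': %d non-redundant sequences, total abundance %d\n",
              x$name, nrow(x$records), x$total_abundance))
  invisible(x)
}

# cheap structural validation so malformed input fails with a line number
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no reads: '", path, "' is empty")
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA in '", path, "': line ", nonblank[1L],
         " does not start a record")
  bad <- nonblank[!startsWith(trimws(lines[nonblank]), ">") &
                    !grepl("^[A-Za-z*.-]+$", trimws(lines[nonblank]))]
  if (length(bad) > 0L)
    stop("malformed FASTA in '", path, "': unexpected characters at line ",
         bad[1L])
  invisible(lines)
}

normalize_seq <- function(x) chartr("U", "T", toupper(x))

#' Read a redundant (or count-collapsed) FASTA read library
#'
#' Reads an adapter-trimmed sRNA or degradome library in redundant FASTA
#' format and collapses identical sequences, summing abundances. Two collapsed
#' dialects are also accepted: a header ending in `-<count>` or `(x<count>)`
#' contributes `<count>` copies; any other record contributes one copy.
#' U is normalised to T and sequences are uppercased.
#'
#' @param path FASTA file path.
#' @param name library label (defaults to the file name).
#' @return A `read_library`: list with `name`, `records` (data.frame of
#'   `name`, `sequence`, `abundance`) and `total_abundance`.
#' @export
read_redundant_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no reads: '", path, "' contains no records")
  seqs <- normalize_seq(as.character(set))
  hdr <- names(set)
  hdr <- sub("\\s.*$", "", hdr)
  count <- rep(1L, length(hdr))
  m1 <- regmatches(hdr, regexpr("-([0-9]+)$", hdr))
  has1 <- grepl("-[0-9]+$", hdr)
  count[has1] <- as.integer(sub("^-", "", m1))
  has2 <- grepl("\\(x[0-9]+\\)$", hdr)
  count[has2] <- as.integer(sub("^.*\\(x([0-9]+)\\)$", "\\1", hdr[has2]))
  base <- sub("-[0-9]+$", "", hdr)
  base[has2] <- sub("\\(x[0-9]+\\)$", "", hdr[has2])
  new_read_library(seqs, count, names = base, name = name)
}

# ---- transcriptomes --------------------------------------------------------

#' Read a transcriptome FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase transcript sequences (U
#'   normalised to T), in file order, named by the first header token.
#' @export
read_transcriptome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate transcript ids: ", paste(dup, collapse = ", "))
  seqs <- normalize_seq(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty transcript sequence: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Extract transcript sequences from a GFF3 annotation and genome
#'
#' For every mRNA feature, concatenates its exon children (when
#' `include_utrs = TRUE`) or CDS children (otherwise) in genomic order;
#' minus-strand transcripts are reverse-complemented. Coordinates are the GFF3
#' standard 1-based inclusive.
#'
#' @param gff3 GFF3 file path.
#' @param genome genome FASTA path, or a named character vector of chromosome
#'   sequences.
#' @param include_utrs logical; use exons (TRUE) or CDS only (FALSE).
#' @return named character vector of transcript sequences keyed by the mRNA
#'   `ID` attribute. mRNAs with no usable children are skipped with a warning.
#' @export
extract_transcripts_gff3 <- function(gff3, genome, include_utrs = TRUE) {
  gr <- rtracklayer::import(gff3)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_transcriptome_fasta(genome)
  child_type <- if (include_utrs) "exon" else "CDS"
  types <- as.character(gr$type)
  mrna <- gr[types == "mRNA"]
  if (length(mrna) == 0L) return(character(0))
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }, character(1))
  out <- character(0)
  for (i in seq_along(mrna)) {
    id <- as.character(mrna$ID[i])
    seqid <- as.character(GenomicRanges::seqnames(mrna)[i])
    if (!seqid %in% names(genome))
      stop("seqid '", seqid, "' not present in the genome")
    kids <- which(types == child_type & parent_of == id)
    if (length(kids) == 0L) {
      warning("mRNA '", id, "' has no ", child_type, " children; skipped")
      next
    }
    kg <- gr[kids]
    kg <- kg[order(GenomicRanges::start(kg))]
    chrom <- genome[[seqid]]
    pieces <- substring(chrom, GenomicRanges::start(kg), GenomicRanges::end(kg))
    seq <- paste(pieces, collapse = "")
    if (as.character(GenomicRanges::strand(mrna)[i]) == "-") seq <- revcomp(seq)
    out[id] <- seq
  }
  out
}

# ---- results output --------------------------------------------------------

results_columns <- function() {
  c("srna_name", "srna_sequence", "srna_abundance_raw", "srna_abundance_norm",
    "transcript_id", "cleavage_position", "category", "peak_abundance_raw",
    "peak_abundance_weighted", "peak_abundance_norm", "alignment_score",
    "duplex", "mfe", "mfe_ratio", "p_value")
}

#' Write a prediction results table as CSV
#'
#' Rows are sorted deterministically by transcript id, cleavage position and
#' sRNA sequence. An empty result set yields a header-only file.
#'
#' @param results data.frame with the standard result columns (see
#'   [predict_targets()]).
#' @param path output file path.
#' @export
write_results_csv <- function(results, path) {
  cols <- results_columns()
  if (is.null(results) || nrow(results) == 0L) {
    results <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    missing <- setdiff(cols, names(results))
    if (length(missing) > 0L)
      stop("results are missing columns: ", paste(missing, collapse = ", "))
    results <- results[order(results$transcript_id, results$cleavage_position,
                             results$srna_sequence), cols, drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.csv(results, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
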