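#' 2-bit integer encoding of nucleotide sequences
#'
#' Encodes a DNA sequence as a single non-negative number by concatenating a
#' 2-bit code per base (first/5' base in the most significant bit pair) and
#' reading the result as an integer. The sRNA and mRNA codes are inverses of
#' each other (sRNA: A=00, C=01, G=10, T/U=11; mRNA: A=11, C=10, G=01, T/U=00),
#' so a sRNA k-mer and the mRNA k-mer it pairs with positionwise (antiparallel,
#' Watson-Crick) are represented by the same number.
#'
#' @param sequence character vector of sequences over A/C/G/T (U is not
#'   accepted here; normalise upstream with [read_redundant_fasta()] etc.).
#' @param mode `"sRNA"` or `"mRNA"`.
#' @return For `encode_seq`, an object of class `encoded_seq`: a list with
#'   `value` (numeric, exact for sequences up to 26 nt), `length` and `mode`.
#'   For length > 1 input, a list of such objects.
#' @examples
#' encode_seq("ACGT", "sRNA")$value   # 27
#' encode_seq("GGGGGGG", "sRNA")$value == encode_seq("CCCCCCC", "mRNA")$value
#' @seealso [decode_seq()]
#' @export
encode_seq <- function(sequence, mode = c("sRNA", "mRNA")) {
  mode <- match.arg(mode)
  stopifnot(is.character(sequence), all(nzchar(sequence)))
  vals <- encode_values_cpp(sequence, mode == "sRNA")
  mk <- function(v, l) {
    structure(list(value = v, length = l, mode = mode), class = "encoded_seq")
  }
  if (length(sequence) == 1L) mk(vals[1L], nchar(sequence)) else
    Map(mk, vals, nchar(sequence))
}

#' Decode a 2-bit encoded sequence
#'
#' Inverse of [encode_seq()] for the same mode.
#'
#' @param value numeric encoded value, or an `encoded_seq` object (in which
#'   case `length` and `mode` are taken from it).
#' @param length nucleotide count.
#' @param mode `"sRNA"` or `"mRNA"`.
#' @return character sequence.
#' @examples
#' decode_seq(0, 7, "sRNA")       # "AAAAAAA"
#' decode_seq(16383, 7, "mRNA")   # "AAAAAAA"
#' @export
decode_seq <- function(value, length = NULL, mode = c("sRNA", "mRNA")) {
  if (inherits(value, "encoded_seq")) {
    length <- value$length
    mode <- value$mode
    value <- value$value
  } else {
    mode <- match.arg(mode)
    if (is.null(length)) stop("'length' is required when decoding a bare value")
  }
  if (any(value < 0 | value >= 4^length))
    stop("encoded value out of range [0, 4^length)")
  as.character(decode_values_cpp(as.numeric(value), as.integer(length),
                                 mode == "sRNA"))
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> %s-mode, %d nt, value %.0f (%s)\n",
              x$mode, x$length, x$value, decode_seq(x)))
  invisible(x)
}

# reverse complement for plain DNA character vectors (internal)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
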