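# Cleavage-anchored sRNA-mRNA duplex alignment: enumeration, best-alignment
# selection and rendering.

as_duplex_alignment <- function(a, srna, window) {
  structure(list(srna = srna, target_window = window, score = a$score,
                 n_mismatches = a$n_mismatches, n_wobbles = a$n_wobbles,
                 n_gaps = a$n_gaps, states = a$states,
                 target_line = a$target_line, srna_line = a$srna_line),
            class = "duplex_alignment")
}

#' Enumerate all rule-compliant duplex alignments
#'
#' Depth-first search anchored at the cleavage site: sRNA position 10 is
#' paired (never gapped) with window index 17, the alignment proceeds toward
#' the sRNA 5' end and, on success, toward the 3' end. At each step the pair
#' is classified as Watson-Crick match, G:U wobble or mismatch, and
#' single-nucleotide gaps may be inserted in either strand (bounded jointly
#' by `max_gaps`). Any branch that breaks a rule (running score above
#' `max_score`, count maxima, adjacency, position-10/11 prohibitions) is
#' pruned.
#'
#' @param srna sRNA sequence, 5'->3' (A/C/G/T).
#' @param window 32-nt candidate window (transcript sense strand, 5'->3').
#' @param rules a `targeting_rules` object.
#' @return list of `duplex_alignment` objects (possibly empty).
#' @export
enumerate_duplex_alignments <- function(srna, window, rules) {
  srna <- normalize_seq(srna)
  window <- normalize_seq(window)
  stopifnot(inherits(rules, "targeting_rules"))
  raw <- duplex_align_all_cpp(srna, window, unclass(rules))
  lapply(raw, as_duplex_alignment, srna = srna, window = window)
}

#' Align a sRNA to a target-sequence candidate
#'
#' Enumerates all valid alignments (see [enumerate_duplex_alignments()]) and
#' returns the best one under the selection rule of [select_best()], or `NULL`
#' when no alignment satisfies the targeting rules.
#'
#' @param srna sRNA sequence, 5'->3'.
#' @param candidate a 32-nt window string, or one row of a candidate
#'   data.frame (its `window` column is used).
#' @param rules a `targeting_rules` object.
#' @return a `duplex_alignment` or `NULL`.
#' @export
align_duplex <- function(srna, candidate, rules) {
  window <- if (is.data.frame(candidate)) candidate$window[1L] else candidate
  all <- enumerate_duplex_alignments(srna, window, rules)
  if (length(all) == 0L) return(NULL)
  select_best(all)
}

#' Select the best duplex alignment
#'
#' Lexicographic minimum by (alignment score, number of gaps, mismatches plus
#' G:U wobbles); remaining ties are broken deterministically by the 5'-most
#' first difference in pair states (match < wobble < mismatch < gap).
#'
#' @param alignments non-empty list of `duplex_alignment` objects.
#' @return the selected `duplex_alignment`.
#' @export
select_best <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments to select from")
  best <- alignments[[1L]]
  for (a in alignments[-1L]) if (duplex_before(a, best)) best <- a
  best
}

# TRUE if a orders strictly before b
duplex_before <- function(a, b) {
  if (a$score != b$score) return(a$score < b$score)
  if (a$n_gaps != b$n_gaps) return(a$n_gaps < b$n_gaps)
  mwa <- a$n_mismatches + a$n_wobbles
  mwb <- b$n_mismatches + b$n_wobbles
  if (mwa != mwb) return(mwa < mwb)
  # states are stored window-5'->3' == sRNA 3'->5'; compare from the sRNA 5' end
  sa <- rev(a$states); sb <- rev(b$states)
  n <- min(length(sa), length(sb))
  for (i in seq_len(n)) {
    if (sa[i] != sb[i]) return(sa[i] < sb[i])
  }
  length(sa) < length(sb)
}

#' Render a duplex alignment as a 3-line text block
#'
#' Line 1: aligned target excerpt 5'->3' (DNA alphabet); line 2: pairing
#' symbols (`|` match, `o` G:U wobble, space mismatch, `-` gap); line 3: the
#' sRNA 3'->5', rendered in the RNA alphabet (U for T).
#'
#' @param a a `duplex_alignment`.
#' @return single string with three newline-separated fixed-width lines.
#' @export
render_duplex <- function(a) {
  stopifnot(inherits(a, "duplex_alignment"))
  sym <- c("|", "o", " ", "-", "-")[a$states + 1L]
  paste(a$target_line, paste(sym, collapse = ""),
        chartr("T", "U", a$srna_line), sep = "\n")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> score %.2f (%d mm, %d G:U, %d gap)\n",
              x$score, x$n_mismatches, x$n_wobbles, x$n_gaps))
  cat(render_duplex(x), "\n")
  invisible(x)
}
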