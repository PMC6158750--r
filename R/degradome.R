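# Exact-match alignment of degradome tags to transcripts via sorted encoded
# lists and binary search; degradation profiles; peak categories; candidate
# extraction and TR2 grouping.

#' Build a sorted, encoded fragment index from a degradome library
#'
#' Reads within the accepted size range are 2-bit encoded and stored in one
#' ascending-sorted value list per read length, ready for binary search.
#'
#' @param deg a `read_library` of degradome tags.
#' @param min_len,max_len accepted degradome tag length range (nt).
#' @return object of class `fragment_index`: list keyed by length, each with
#'   sorted `values`, parallel `abundance` and `sequence`, and an
#'   `n_matches` slot filled by [align_degradome()].
#' @export
build_fragment_index <- function(deg, min_len = 19L, max_len = 21L) {
  stopifnot(inherits(deg, "read_library"))
  rec <- deg$records[grepl("^[ACGT]+$", deg$records$sequence), , drop = FALSE]
  len <- nchar(rec$sequence)
  rec <- rec[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no degradome reads within the accepted size range [",
         min_len, ", ", max_len, "]")
  idx <- lapply(split(rec, nchar(rec$sequence)), function(d) {
    v <- encode_values_cpp(d$sequence, TRUE)
    o <- order(v)
    list(values = v[o], abundance = d$abundance[o], sequence = d$sequence[o],
         n_matches = integer(length(v)))
  })
  structure(list(by_length = idx, library = deg$name,
                 total_abundance = deg$total_abundance),
            class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  n <- vapply(x$by_length, function(e) length(e$values), integer(1))
  cat(sprintf("<fragment_index> '%s': %d sequences over lengths {%s}\n",
              x$library, sum(n), paste(names(n), collapse = ", ")))
  invisible(x)
}

#' Align degradome tags to transcripts (exact match, sense strand)
#'
#' Every length-l window of every transcript is encoded with the same 2-bit
#' code as the reads and binary-searched in the sorted fragment list for that
#' length; a hit records the tag's abundance at the window start position
#' (the tag's 5' end, a putative cleavage position). The weighted abundance of
#' a hit is the tag abundance divided by the total number of transcriptome
#' windows the tag matches, so multi-mapping tags distribute their evidence.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param index a `fragment_index`.
#' @return named list (one entry per transcript with at least one hit) of
#'   degradation profiles: data.frames with `pos`, `abundance`,
#'   `weighted_abundance`, sorted by position.
#' @export
align_degradome <- function(transcripts, index) {
  stopifnot(inherits(index, "fragment_index"))
  hits <- vector("list", length(transcripts) * length(index$by_length))
  h <- 0L
  for (tx in names(transcripts)) {
    for (len in names(index$by_length)) {
      e <- index$by_length[[len]]
      sc <- scan_transcript_cpp(transcripts[[tx]], e$values, as.integer(len))
      if (length(sc$pos) > 0L) {
        h <- h + 1L
        hits[[h]] <- data.frame(transcript = tx, pos = sc$pos, len = len,
                                ridx = sc$idx, stringsAsFactors = FALSE)
      }
    }
  }
  if (h == 0L) return(structure(list(), names = character(0)))
  hits <- do.call(rbind, hits[seq_len(h)])
  # per-read transcriptome-wide match counts -> weighted abundance
  key <- paste(hits$len, hits$ridx)
  nmatch <- table(key)
  hits$abundance <- mapply(function(l, i) index$by_length[[l]]$abundance[i],
                           hits$len, hits$ridx)
  hits$weighted <- hits$abundance / as.integer(nmatch[key])
  profiles <- lapply(split(hits, hits$transcript), function(d) {
    agg_ab <- tapply(d$abundance, d$pos, sum)
    agg_w <- tapply(d$weighted, d$pos, sum)
    pos <- as.integer(names(agg_ab))
    o <- order(pos)
    data.frame(pos = pos[o], abundance = as.integer(agg_ab)[o],
               weighted_abundance = as.numeric(agg_w)[o])
  })
  profiles
}

#' Assign cleavage-peak categories to a degradation profile
#'
#' Categories follow the CleaveLand convention with one modification: reads
#' of abundance 1 are excluded from the average-coverage calculation, which
#' separates genuine low-abundance peaks from background degradation.
#' Category 0: abundance > 1, the unique maximum on the transcript;
#' category 1: abundance > 1, a tied maximum; category 2: abundance > 1 and
#' above the average; category 3: abundance > 1 and at or below the average;
#' category 4: abundance exactly 1.
#'
#' @param profile degradation profile data.frame (`pos`, `abundance`,
#'   `weighted_abundance`).
#' @return the profile with a `category` integer column appended.
#' @export
assign_categories <- function(profile) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0L)
  ab <- profile$abundance
  M <- max(ab)
  n_max <- sum(ab == M)
  gt1 <- ab > 1L
  avg <- if (any(gt1)) mean(ab[gt1]) else 0
  cat <- integer(length(ab))
  cat[!gt1] <- 4L
  is_max <- gt1 & ab == M
  cat[is_max] <- if (n_max == 1L) 0L else 1L
  rest <- gt1 & !is_max
  cat[rest & ab > avg] <- 2L
  cat[rest & ab <= avg] <- 3L
  profile$category <- cat
  profile
}

empty_candidates <- function() {
  data.frame(transcript_id = character(0), pos = integer(0),
             window = character(0), abundance = integer(0),
             weighted_abundance = numeric(0), category = integer(0),
             tr1 = numeric(0), tr2 = numeric(0), stringsAsFactors = FALSE)
}

#' Extract 32-nt target-sequence candidates from a categorised profile
#'
#' For every signal position `p` with an allowed category and sufficient
#' abundance, takes 16 nt towards both the 5' and 3' ends (window positions
#' `p-16 .. p+15`, so `p` sits at window index 17); positions within 16 nt of
#' either transcript end yield no candidate. TR2 (the 7 bases opposite sRNA
#' positions 8-14 under gap-free anchoring; transcript `p+2` down to `p-4`)
#' and TR1 (opposite positions 1-7; `p+9` down to `p+3`) are encoded in mRNA
#' mode for matrix lookup and grouping.
#'
#' @param transcript_id transcript identifier.
#' @param sequence transcript sequence.
#' @param profile categorised degradation profile for this transcript.
#' @param allowed_categories integer vector of categories to keep.
#' @param min_fragment_abundance minimum peak abundance.
#' @return candidate data.frame (`transcript_id`, `pos`, `window`,
#'   `abundance`, `weighted_abundance`, `category`, `tr1`, `tr2`).
#' @export
extract_candidates <- function(transcript_id, sequence, profile,
                               allowed_categories = 0:3,
                               min_fragment_abundance = 1L) {
  stopifnot(!is.null(profile$category))
  L <- nchar(sequence)
  keep <- profile$category %in% allowed_categories &
    profile$abundance >= min_fragment_abundance &
    profile$pos >= 17L & profile$pos <= L - 15L
  if (!any(keep)) return(empty_candidates())
  d <- profile[keep, , drop = FALSE]
  window <- substr(rep(sequence, nrow(d)), d$pos - 16L, d$pos + 15L)
  clean <- grepl("^[ACGT]+$", window)   # windows touching ambiguous bases are unusable
  if (!any(clean)) return(empty_candidates())
  d <- d[clean, , drop = FALSE]
  window <- window[clean]
  rev7 <- function(x) vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  tr2 <- encode_values_cpp(rev7(substr(window, 13L, 19L)), FALSE)
  tr1 <- encode_values_cpp(rev7(substr(window, 20L, 26L)), FALSE)
  out <- data.frame(transcript_id = transcript_id, pos = d$pos, window = window,
                    abundance = d$abundance,
                    weighted_abundance = d$weighted_abundance,
                    category = d$category, tr1 = tr1, tr2 = tr2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group target-sequence candidates by their TR2 code
#'
#' @param cands candidate data.frame (possibly spanning many transcripts).
#' @return named list of data.frames keyed by the decimal TR2 value.
#' @export
group_by_tr2 <- function(cands) {
  if (is.null(cands) || nrow(cands) == 0L) return(structure(list(), names = character(0)))
  split(cands, cands$tr2)
}
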