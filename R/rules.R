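# Configurable targeting rules, the two published presets, region extraction,
# lazily memoized valid-region alignment matrix rows, and the three-stage
# candidate filter.

rule_fields <- function() {
  c("max_score", "max_mismatches", "max_adjacent_mismatches", "max_gu_wobbles",
    "mismatch_score", "gu_wobble_score", "gap_score", "max_gaps",
    "core_start", "core_end", "core_multiplier",
    "max_mismatches_core", "max_adjacent_mismatches_core",
    "allow_mismatch_pos10", "pos10_mismatch_score",
    "allow_mismatch_pos11", "pos11_mismatch_score",
    "permissible_mismatch_positions", "non_permissible_mismatch_positions",
    "gu_counts_as_mismatch")
}

#' Construct a targeting rule set
#'
#' Builds the configurable constraint/scoring set governing sRNA-mRNA duplex
#' acceptance. Two presets are provided: `"allen"` (mismatch 1, G:U wobble
#' 0.5, gap 1, positions 2-13 doubled, score cutoff 4, at most 4 mismatches /
#' 2 adjacent / 1 gap, no mismatch or wobble at sRNA positions 10-11) and
#' `"fahlgren_carrington"`, identical except that a mismatch or G:U wobble is
#' permitted at positions 10 and 11. Any field can be overridden via `...`.
#'
#' @param preset `"allen"` or `"fahlgren_carrington"`.
#' @param ... named overrides of individual rule fields (see
#'   [write_targeting_rules()] for the field names).
#' @return object of class `targeting_rules`.
#' @export
targeting_rules <- function(preset = c("allen", "fahlgren_carrington"), ...) {
  preset <- match.arg(preset)
  r <- list(
    max_score = 4.0,
    max_mismatches = 4L,
    max_adjacent_mismatches = 2L,
    max_gu_wobbles = 24L,
    mismatch_score = 1.0,
    gu_wobble_score = 0.5,
    gap_score = 1.0,
    max_gaps = 1L,
    core_start = 2L,
    core_end = 13L,
    core_multiplier = 2.0,
    max_mismatches_core = 4L,
    max_adjacent_mismatches_core = 2L,
    allow_mismatch_pos10 = FALSE,
    pos10_mismatch_score = 1.0,
    allow_mismatch_pos11 = FALSE,
    pos11_mismatch_score = 1.0,
    permissible_mismatch_positions = integer(0),
    non_permissible_mismatch_positions = integer(0),
    gu_counts_as_mismatch = FALSE
  )
  if (preset == "fahlgren_carrington") {
    r$allow_mismatch_pos10 <- TRUE
    r$allow_mismatch_pos11 <- TRUE
  }
  over <- list(...)
  bad <- setdiff(names(over), rule_fields())
  if (length(bad) > 0L) stop("unknown rule field(s): ", paste(bad, collapse = ", "))
  r[names(over)] <- over
  validate_rules(structure(r, class = "targeting_rules", preset = preset))
}

validate_rules <- function(r) {
  stopifnot(inherits(r, "targeting_rules"))
  r$permissible_mismatch_positions <-
    as.integer(r$permissible_mismatch_positions)
  r$non_permissible_mismatch_positions <-
    as.integer(r$non_permissible_mismatch_positions)
  int_fields <- c("max_mismatches", "max_adjacent_mismatches", "max_gu_wobbles",
                  "max_gaps", "core_start", "core_end", "max_mismatches_core",
                  "max_adjacent_mismatches_core")
  for (f in int_fields) r[[f]] <- as.integer(r[[f]])
  if (r$core_start > r$core_end) stop("core_start must be <= core_end")
  if (r$max_gaps < 0L) stop("max_gaps must be >= 0")
  scores <- c(r$max_score, r$mismatch_score, r$gu_wobble_score, r$gap_score,
              r$pos10_mismatch_score, r$pos11_mismatch_score, r$core_multiplier)
  if (any(scores < 0)) stop("all scores and multipliers must be >= 0")
  r
}

#' @export
print.targeting_rules <- function(x, ...) {
  cat(sprintf(
    "<targeting_rules>%s max_score %.2g; mm %.2g / G:U %.2g / gap %.2g; core %d-%d x%.2g; pos10/11 %s\n",
    if (!is.null(attr(x, "preset"))) paste0(" [", attr(x, "preset"), "]") else "",
    x$max_score, x$mismatch_score, x$gu_wobble_score, x$gap_score,
    x$core_start, x$core_end, x$core_multiplier,
    if (x$allow_mismatch_pos10 || x$allow_mismatch_pos11) "permitted" else "forbidden"))
  invisible(x)
}

#' Read / write a targeting rule configuration file
#'
#' The configuration file is a flat JSON object whose keys are exactly the
#' rule field names; presets round-trip through it unchanged.
#'
#' @param path JSON file path.
#' @return `read_targeting_rules` returns a `targeting_rules` object.
#' @export
read_targeting_rules <- function(path) {
  raw <- jsonlite::fromJSON(path)
  missing <- setdiff(rule_fields(), names(raw))
  if (length(missing) > 0L)
    stop("rule file is missing field(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(names(raw), rule_fields())
  if (length(bad) > 0L)
    stop("rule file has unknown field(s): ", paste(bad, collapse = ", "))
  validate_rules(structure(raw[rule_fields()], class = "targeting_rules"))
}

#' @param rules a `targeting_rules` object.
#' @rdname read_targeting_rules
#' @export
write_targeting_rules <- function(rules, path) {
  stopifnot(inherits(rules, "targeting_rules"))
  jsonlite::write_json(unclass(rules)[rule_fields()], path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

rules_signature <- function(rules) {
  paste(vapply(unclass(rules)[rule_fields()],
               function(v) paste(format(v, digits = 17), collapse = "|"),
               character(1)),
        collapse = ";")
}

# ---- regions ---------------------------------------------------------------

#' Extract the three 7-mer regions of a sRNA
#'
#' R1 spans sRNA positions 1-7, R2 positions 8-14 and R3 the last 7
#' nucleotides (overlapping R2 when the sRNA is shorter than 21 nt), all in
#' 5'-to-3' numbering and encoded in sRNA mode.
#'
#' @param srna sRNA sequence (>= 14 nt, A/C/G/T).
#' @return object of class `region_codes`: list of `encoded_seq` values `r1`,
#'   `r2`, `r3` plus `srna_length` and the sRNA itself.
#' @export
extract_regions <- function(srna) {
  srna <- normalize_seq(srna)
  L <- nchar(srna)
  if (L < 14L) stop("sRNA must be at least 14 nt to carry the R1/R2 regions")
  structure(list(
    r1 = encode_seq(substr(srna, 1L, 7L), "sRNA"),
    r2 = encode_seq(substr(srna, 8L, 14L), "sRNA"),
    r3 = encode_seq(substr(srna, L - 6L, L), "sRNA"),
    srna_length = L, srna = srna), class = "region_codes")
}

# memoized rows of the conceptual 16384 x 16384 valid-alignment matrices
.region_cache <- new.env(parent = emptyenv())

#' Row of a valid-region alignment matrix
#'
#' For a sRNA region 7-mer, returns every mRNA 7-mer code that can pair with
#' it in at least one alignment that does not, within the region alone, exceed
#' any global rule budget (score with positional/core multipliers at the
#' region's absolute sRNA positions, mismatch/wobble/gap/adjacency maxima,
#' position-10/11 prohibitions for R2). When `rules$max_gaps > 0`, codes
#' reachable through register shifts caused by up to `max_gaps` gaps are also
#' included, which makes the three-stage filter conservative: it never removes
#' a candidate the full duplex aligner would accept. Rows are memoized per
#' `(region, code, srna_length, rules)`.
#'
#' @param region `"R1"`, `"R2"` or `"R3"`.
#' @param code sRNA region code (0..16383), an `encoded_seq`, or a 7-nt
#'   sequence.
#' @param srna_length full sRNA length (fixes R3's absolute positions).
#' @param rules a `targeting_rules` object.
#' @return integer vector of valid mRNA 7-mer codes (sorted ascending).
#' @export
region_row <- function(region = c("R1", "R2", "R3"), code, srna_length, rules) {
  region <- match.arg(region)
  if (inherits(code, "encoded_seq")) code <- code$value
  if (is.character(code)) code <- encode_seq(code, "sRNA")$value
  stopifnot(code >= 0, code < 16384)
  key <- paste(region, code, srna_length, rules_signature(rules), sep = "#")
  hit <- .region_cache[[key]]
  if (!is.null(hit)) return(hit)
  ok <- region_row_cpp(as.integer(substr(region, 2L, 2L)), as.integer(code),
                       as.integer(srna_length), unclass(rules))
  row <- which(ok) - 1L
  .region_cache[[key]] <- row
  row
}

region_pair_valid <- function(region, scode, mcode, srna_length, rules) {
  region_pair_valid_cpp(as.integer(substr(region, 2L, 2L)), as.integer(scode),
                        as.integer(mcode), as.integer(srna_length),
                        unclass(rules))
}

# ---- three-stage candidate filtering ---------------------------------------

# TR3 of a candidate window for a given sRNA length: the 7 window bases
# opposite sRNA positions (L-6)..L, read 3'->5' and encoded in mRNA mode.
tr3_code_for <- function(windows, srna_length) {
  lo <- 27L - srna_length
  piece <- substr(windows, lo, lo + 6L)
  encode_values_cpp(vapply(piece, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE), FALSE)
}

#' Three-stage filtering of target-sequence candidates
#'
#' Stage 1 keeps only candidate groups whose TR2 code can align to the sRNA's
#' R2 region; stage 2 drops candidates whose TR1 cannot align to R1; stage 3
#' computes TR3 from each surviving window for this sRNA's length and drops
#' candidates whose TR3 cannot align to R3. Validity is evaluated with the
#' same budgets as [region_row()], so the filter never discards a candidate
#' the full duplex aligner would accept.
#'
#' @param regions `region_codes` for the sRNA (see [extract_regions()]).
#' @param groups named list of candidate data.frames keyed by TR2 code (see
#'   [group_by_tr2()]), or a single candidate data.frame.
#' @param rules a `targeting_rules` object.
#' @return data.frame of surviving candidates (possibly 0 rows).
#' @export
three_stage_filter <- function(regions, groups, rules) {
  stopifnot(inherits(regions, "region_codes"))
  if (is.data.frame(groups)) groups <- group_by_tr2(groups)
  if (length(groups) == 0L) return(empty_candidates())
  L <- regions$srna_length
  # stage 1: TR2 vs R2, on the group keys
  tr2_vals <- as.numeric(names(groups))
  ok2 <- vapply(tr2_vals, function(m)
    region_pair_valid("R2", regions$r2$value, m, L, rules), logical(1))
  cand <- do.call(rbind, groups[ok2])
  if (is.null(cand) || nrow(cand) == 0L) return(empty_candidates())
  # stage 2: TR1 vs R1
  tr1_vals <- sort(unique(cand$tr1))
  ok1 <- vapply(tr1_vals, function(m)
    region_pair_valid("R1", regions$r1$value, m, L, rules), logical(1))
  cand <- cand[cand$tr1 %in% tr1_vals[ok1], , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_candidates())
  # stage 3: TR3 (window slice fixed by this sRNA's length) vs R3
  tr3 <- tr3_code_for(cand$window, L)
  tr3_vals <- sort(unique(tr3))
  ok3 <- vapply(tr3_vals, function(m)
    region_pair_valid("R3", regions$r3$value, m, L, rules), logical(1))
  cand <- cand[tr3 %in% tr3_vals[ok3], , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
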