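# Deterministic synthetic-data generator: random transcriptomes with planted
# sRNA-target-degradome triples, so every pipeline stage can be validated
# against known truth without external datasets.

#' Generate a random transcriptome
#'
#' Uniform-random A/C/G/T sequences, reproducible from the seed.
#'
#' @param n number of transcripts (>= 1).
#' @param min_len,max_len transcript length range (nt).
#' @param seed integer seed driving all randomness.
#' @param fasta optional path; when given, the transcriptome is also written
#'   as FASTA.
#' @return named character vector of transcript sequences.
#' @export
make_transcriptome <- function(n, min_len = 500L, max_len = 1500L, seed = 1L,
                               fasta = NULL) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(min_len <= max_len, min_len >= 1L)
  set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("TX%04d", seq_len(n))
  if (!is.null(fasta)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), fasta)
  }
  seqs
}

pair_partner <- function(b) chartr("ACGT", "TGCA", b)

#' Plant known sRNA-target-degradome triples into a transcriptome
#'
#' For each site a transcript, cleavage position and sRNA length are chosen at
#' random; the sRNA is written as the (optionally edited) reverse complement
#' of the site so that its position 10 faces the cleavage position; degradome
#' tags whose 5' ends sit exactly at the cleavage position are emitted at the
#' requested abundance; and Poisson background degradation tags of abundance 1
#' (category 4 by construction) can be added. The truth table records, for
#' every planted site, the expected peak category (derived from the planted
#' abundances by the category definitions) and the expected alignment score
#' under the named preset (computed from the edit arithmetic, independently of
#' the aligner).
#'
#' @param transcripts named character vector (see [make_transcriptome()]).
#' @param n_sites number of planted sites.
#' @param srna_len_range inclusive sRNA length range.
#' @param n_mismatches,n_wobbles number of planted edits per sRNA, placed at
#'   random eligible positions (never 10 or 11).
#' @param peak_abundance degradome tag abundance at each planted site
#'   (recycled across sites).
#' @param srna_abundance abundance given to each planted sRNA.
#' @param background_rate expected number of abundance-1 background tags per
#'   transcript nucleotide (Poisson).
#' @param deg_len degradome tag length (nt).
#' @param preset rule preset used to validate the edit spec and compute
#'   expected scores; an infeasible edit spec errors at generation time.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, `srna.fasta`,
#'   `degradome.fasta` and `truth.csv` are written there.
#' @return list with `srna` and `degradome` (`read_library` objects) and
#'   `truth` (data.frame: `srna_name`, `srna_sequence`, `transcript_id`,
#'   `cleavage_position`, `expected_category`, `expected_score`).
#' @export
plant_interactions <- function(transcripts, n_sites,
                               srna_len_range = c(19L, 24L),
                               n_mismatches = 0L, n_wobbles = 0L,
                               peak_abundance = 10L, srna_abundance = 10L,
                               background_rate = 0, deg_len = 20L,
                               preset = "allen", seed = 1L, out_dir = NULL) {
  stopifnot(n_sites >= 1L, deg_len >= 15L)
  rules <- targeting_rules(preset)
  set.seed(seed)
  peak_abundance <- rep_len(as.integer(peak_abundance), n_sites)
  txn <- names(transcripts)
  used <- lapply(txn, function(x) integer(0))
  names(used) <- txn

  truth <- vector("list", n_sites)
  srna_seqs <- character(n_sites)
  deg_seqs <- character(0); deg_ab <- integer(0)

  # edits placed at non-core positions cost least; if even the cheapest
  # arrangement breaks the preset, the requested edits are infeasible outright
  min_score <- n_mismatches * rules$mismatch_score +
    n_wobbles * rules$gu_wobble_score
  if (min_score > rules$max_score ||
      n_mismatches + n_wobbles * rules$gu_counts_as_mismatch >
        rules$max_mismatches)
    stop("edit spec infeasible under preset '", preset,
         "': minimum expected score ", min_score)
  mult <- function(i) ifelse(i >= rules$core_start & i <= rules$core_end,
                             rules$core_multiplier, 1)
  pick <- function(pool, n) pool[sample.int(length(pool), n)]
  ok_complexity <- function(s)
    max_kmer_fraction(s, 1L) <= 0.75 && max_kmer_fraction(s, 2L) <= 0.375 &&
      max_kmer_fraction(s, 3L) <= 0.25

  for (k in seq_len(n_sites)) {
    placed <- FALSE
    for (try in 1:500) {
      tx <- txn[sample.int(length(txn), 1L)]
      L <- nchar(transcripts[[tx]])
      lens <- srna_len_range[1L]:srna_len_range[2L]
      Ls <- lens[sample.int(length(lens), 1L)]
      lo <- max(17L, Ls - 9L)
      hi <- min(L - 15L, L - deg_len + 1L)
      if (hi < lo) next
      p <- (lo:hi)[sample.int(hi - lo + 1L, 1L)]
      if (any(abs(used[[tx]] - p) < 40L)) next  # keep planted peaks separated

      site <- substr(transcripts[[tx]], p + 10L - Ls, p + 9L) # paired 5'->3'
      tag <- substr(transcripts[[tx]], p, p + deg_len - 1L)
      if (!ok_complexity(tag)) next
      sv <- strsplit(revcomp(site), "", fixed = TRUE)[[1]]
      tv <- strsplit(site, "", fixed = TRUE)[[1]]
      # sRNA position i pairs site base (Ls - i + 1)
      eligible <- setdiff(seq_len(Ls), c(10L, 11L))
      wobble_ok <- eligible[tv[Ls - eligible + 1L] %in% c("G", "T")]
      if (length(wobble_ok) < n_wobbles) next
      wpos <- if (n_wobbles > 0L) pick(wobble_ok, n_wobbles) else integer(0)
      mpool <- setdiff(eligible, wpos)
      if (length(mpool) < n_mismatches) next
      mpos <- if (n_mismatches > 0L) pick(mpool, n_mismatches) else integer(0)
      score <- sum(rules$gu_wobble_score * mult(wpos)) +
        sum(rules$mismatch_score * mult(mpos))
      if (score > rules$max_score) next      # resample edit positions
      for (i in wpos) {
        tb <- tv[Ls - i + 1L]
        sv[i] <- if (tb == "G") "T" else "G" # sRNA U:G / G:U wobble
      }
      for (i in mpos) {
        tb <- tv[Ls - i + 1L]
        bad <- setdiff(c("A", "C", "G", "T"),
                       c(pair_partner(tb), if (tb == "G") "T",
                         if (tb == "T") "G"))
        sv[i] <- bad[sample.int(length(bad), 1L)]
      }
      srna <- paste(sv, collapse = "")
      if (!ok_complexity(srna)) next
      placed <- TRUE
      used[[tx]] <- c(used[[tx]], p)
      break
    }
    if (!placed)
      stop("edit spec infeasible or transcripts too small/crowded at site ", k)
    srna_seqs[k] <- srna
    deg_seqs <- c(deg_seqs, substr(transcripts[[tx]], p, p + deg_len - 1L))
    deg_ab <- c(deg_ab, peak_abundance[k])
    truth[[k]] <- data.frame(srna_name = sprintf("planted_%03d", k),
                             srna_sequence = srna, transcript_id = tx,
                             cleavage_position = p,
                             expected_score = score,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # background degradation: abundance-1 tags at random positions
  if (background_rate > 0) {
    for (tx in txn) {
      L <- nchar(transcripts[[tx]])
      nb <- stats::rpois(1L, background_rate * max(L - deg_len + 1L, 0L))
      if (nb == 0L) next
      avail <- setdiff(seq_len(L - deg_len + 1L),
                       truth$cleavage_position[truth$transcript_id == tx])
      if (length(avail) == 0L) next
      pos <- avail[sample.int(length(avail), min(nb, length(avail)))]
      deg_seqs <- c(deg_seqs, substr(rep(transcripts[[tx]], length(pos)),
                                     pos, pos + deg_len - 1L))
      deg_ab <- c(deg_ab, rep(1L, length(pos)))
    }
  }

  deg_lib <- new_read_library(deg_seqs, deg_ab, name = "degradome")
  srna_lib <- new_read_library(srna_seqs, rep(as.integer(srna_abundance), n_sites),
                               names = truth$srna_name, name = "srna")

  # expected categories from the planted abundance landscape (the degradome
  # library itself), by direct application of the category definitions
  prof_cache <- lapply(transcripts[unique(truth$transcript_id)], function(s)
    assign_categories(profile_from_library(s, deg_lib, deg_len)))
  truth$expected_category <- vapply(seq_len(nrow(truth)), function(k) {
    prof <- prof_cache[[truth$transcript_id[k]]]
    prof$category[match(truth$cleavage_position[k], prof$pos)]
  }, integer(1))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_library_fasta(srna_lib, file.path(out_dir, "srna.fasta"))
    write_library_fasta(deg_lib, file.path(out_dir, "degradome.fasta"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(srna = srna_lib, degradome = deg_lib, truth = truth)
}

# abundance landscape of a library on one transcript (exact substring match),
# used only to derive expected categories for the truth table
profile_from_library <- function(sequence, lib, deg_len) {
  pos <- integer(0); ab <- integer(0)
  for (i in seq_len(nrow(lib$records))) {
    s <- lib$records$sequence[i]
    hits <- gregexpr(s, sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    pos <- c(pos, as.integer(hits))
    ab <- c(ab, rep(lib$records$abundance[i], length(hits)))
  }
  agg <- tapply(ab, pos, sum)
  p <- as.integer(names(agg))
  o <- order(p)
  data.frame(pos = p[o], abundance = as.integer(agg)[o],
             weighted_abundance = NA_real_)
}

#' Write a read library as count-collapsed FASTA
#'
#' Headers carry the abundance as a trailing `-<count>` tag, the dialect
#' accepted by [read_redundant_fasta()].
#'
#' @param lib a `read_library`.
#' @param path output FASTA path.
#' @export
write_library_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "read_library"))
  writeLines(paste0(">", lib$records$name, "-", lib$records$abundance, "\n",
                    lib$records$sequence), path)
  invisible(path)
}
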