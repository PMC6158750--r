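# End-to-end orchestration: prefilters -> fragment index -> degradome
# alignment -> categories -> candidates -> region prefilter -> duplex
# alignment -> confidence filters -> results table.

#' Reads-per-million normalisation
#'
#' @param raw raw abundance.
#' @param library_total post-filter total abundance of the library.
#' @return `raw * 1e6 / library_total`.
#' @export
normalize_rpm <- function(raw, library_total) {
  if (library_total <= 0) stop("library total must be positive")
  raw * 1e6 / library_total
}

as_library_list <- function(x, what) {
  if (inherits(x, "read_library")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "read_library")))
    return(x)
  stop(what, " must be a read_library or a list of read_library objects")
}

merge_libraries <- function(libs, name = "merged") {
  seqs <- unlist(lapply(libs, function(l) l$records$sequence))
  abs <- unlist(lapply(libs, function(l) l$records$abundance))
  nms <- unlist(lapply(libs, function(l) l$records$name))
  if (length(seqs) == 0L)
    return(new_read_library(character(0), integer(0), name = name))
  new_read_library(seqs, abs, names = nms, name = name)
}

#' Predict sRNA targets from degradome evidence
#'
#' Runs the full prediction pipeline: input prefilters, per-degradome-library
#' fragment indexing and exact-match alignment, peak categorisation, 32-nt
#' candidate extraction and TR2 grouping, per-sRNA three-stage region
#' filtering, cleavage-anchored duplex alignment and the optional MFE-ratio
#' and per-transcript binomial p-value filters. The prediction path contains
#' no randomness: identical inputs and settings give identical output.
#'
#' @param transcripts named character vector of transcript sequences (see
#'   [read_transcriptome_fasta()] / [extract_transcripts_gff3()]).
#' @param srna one `read_library` or a list of replicate libraries.
#' @param degradome one `read_library` or a list of replicate libraries; one
#'   results table is produced per degradome library.
#' @param rules a `targeting_rules` object.
#' @param min_srna_len,max_srna_len accepted sRNA length range (nt).
#' @param min_srna_abundance minimum sRNA abundance (stringent default 5).
#' @param deg_min_len,deg_max_len accepted degradome tag length range (nt).
#' @param categories peak categories retained (stringent default drops 4).
#' @param min_fragment_abundance minimum peak abundance at the cleavage site.
#' @param mfe_ratio_cutoff discard predictions with MFE ratio below this
#'   (`NULL` disables the filter); the boundary value is kept.
#' @param pvalue_cutoff discard predictions with p-value above this; the
#'   filter is optional and off by default (`NULL`). The conventional cutoff
#'   when enabled is 0.05.
#' @param low_complexity apply the low-complexity filter to both read classes.
#' @param conservation require sRNAs to be present in every sRNA replicate,
#'   and add a conservation-intersected summary across degradome replicates.
#' @param genome_filter optional genome (named character vector, DNAStringSet
#'   or FASTA path); sRNAs without an exact full-length genome match are
#'   dropped.
#' @param prefilter logical; set to `FALSE` to bypass the three-stage region
#'   filter and send every candidate to the duplex aligner (the result set is
#'   identical by construction; the filter only prunes the search).
#' @param energy_backend `"internal"` or `"rnaplex"` (see [duplex_mfe()]).
#' @return object of class `target_predictions`: list with `results` (one
#'   data.frame per degradome library), `conserved` (intersected summary or
#'   `NULL`) and `settings`.
#' @export
predict_targets <- function(transcripts, srna, degradome,
                            rules = targeting_rules("allen"),
                            min_srna_len = 19L, max_srna_len = 24L,
                            min_srna_abundance = 5L,
                            deg_min_len = 19L, deg_max_len = 21L,
                            categories = 0:3, min_fragment_abundance = 1L,
                            mfe_ratio_cutoff = 0.7, pvalue_cutoff = NULL,
                            low_complexity = TRUE, conservation = FALSE,
                            genome_filter = NULL, prefilter = TRUE,
                            energy_backend = "internal") {
  stopifnot(is.character(transcripts), length(transcripts) > 0L,
            !is.null(names(transcripts)), inherits(rules, "targeting_rules"))
  transcripts <- vapply(transcripts, normalize_seq, character(1))

  srna_libs <- lapply(as_library_list(srna, "srna"), function(l) {
    l <- filter_ambiguous(l)
    if (low_complexity) l <- filter_low_complexity(l)
    l <- filter_size_abundance(l, min_srna_len, max_srna_len, min_srna_abundance)
    if (!is.null(genome_filter)) l <- filter_genome_match(l, genome_filter)
    l
  })
  if (conservation && length(srna_libs) >= 2L)
    srna_libs <- filter_conservation(srna_libs)
  srna_merged <- merge_libraries(srna_libs, name = "sRNA")
  if (nrow(srna_merged$records) == 0L)
    stop("no sRNA sequences survive the input filters")
  srna_total <- srna_merged$total_abundance

  deg_libs <- lapply(as_library_list(degradome, "degradome"), function(l) {
    l2 <- filter_ambiguous(l)
    if (low_complexity) l2 <- filter_low_complexity(l2)
    l2 <- filter_size_abundance(l2, deg_min_len, deg_max_len, 1L)
    l2$name <- l$name
    l2
  })

  srec <- srna_merged$records
  srec <- srec[order(srec$sequence), , drop = FALSE]
  results <- list()
  for (dl in deg_libs) {
    if (nrow(dl$records) == 0L)
      stop("degradome library '", dl$name, "' is empty after filtering")
    index <- build_fragment_index(dl, deg_min_len, deg_max_len)
    profiles <- align_degradome(transcripts, index)
    profiles <- lapply(profiles, assign_categories)
    cands <- do.call(rbind, c(lapply(names(profiles), function(tx)
      extract_candidates(tx, transcripts[[tx]], profiles[[tx]],
                         allowed_categories = categories,
                         min_fragment_abundance = min_fragment_abundance)),
      list(empty_candidates())))
    groups <- group_by_tr2(cands)
    rows <- list()
    for (i in seq_len(nrow(srec))) {
      s <- srec$sequence[i]
      regions <- extract_regions(s)
      surv <- if (prefilter) three_stage_filter(regions, groups, rules) else cands
      if (nrow(surv) == 0L) next
      n_eval <- table(surv$transcript_id)
      for (j in seq_len(nrow(surv))) {
        best <- align_duplex(s, surv$window[j], rules)
        if (is.null(best)) next
        ratio <- mfe_ratio(best, backend = energy_backend)
        if (!is.null(mfe_ratio_cutoff) && ratio < mfe_ratio_cutoff) next
        tx <- surv$transcript_id[j]
        pv <- site_pvalue(surv$category[j], profiles[[tx]],
                          as.integer(n_eval[[tx]]))
        if (!is.null(pvalue_cutoff) && pv > pvalue_cutoff) next
        rows[[length(rows) + 1L]] <- data.frame(
          srna_name = srec$name[i], srna_sequence = s,
          srna_abundance_raw = srec$abundance[i],
          srna_abundance_norm = normalize_rpm(srec$abundance[i], srna_total),
          transcript_id = tx, cleavage_position = surv$pos[j],
          category = surv$category[j],
          peak_abundance_raw = surv$abundance[j],
          peak_abundance_weighted = surv$weighted_abundance[j],
          peak_abundance_norm = normalize_rpm(surv$abundance[j],
                                              dl$total_abundance),
          alignment_score = best$score,
          duplex = gsub("\n", ";", render_duplex(best), fixed = TRUE),
          mfe = alignment_energy(best, backend = energy_backend),
          mfe_ratio = ratio, p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
    res <- if (length(rows) > 0L) do.call(rbind, rows) else {
      as.data.frame(setNames(rep(list(character(0)), length(results_columns())),
                             results_columns()))
    }
    if (nrow(res) > 0L) {
      res <- res[order(res$transcript_id, res$cleavage_position,
                       res$srna_sequence), , drop = FALSE]
      rownames(res) <- NULL
    }
    results[[dl$name]] <- res
  }

  conserved <- NULL
  if (conservation && length(results) >= 2L) {
    keys <- lapply(results, function(r)
      paste(r$srna_sequence, r$transcript_id, r$cleavage_position))
    common <- Reduce(intersect, keys)
    first <- results[[1L]]
    conserved <- first[keys[[1L]] %in% common, , drop = FALSE]
    rownames(conserved) <- NULL
  }

  structure(list(results = results, conserved = conserved,
                 settings = list(rules = rules, categories = categories,
                                 min_srna_abundance = min_srna_abundance,
                                 mfe_ratio_cutoff = mfe_ratio_cutoff,
                                 pvalue_cutoff = pvalue_cutoff,
                                 srna_total = srna_total)),
            class = "target_predictions")
}

#' @export
print.target_predictions <- function(x, ...) {
  cat("<target_predictions>\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: %d interaction(s)", nm, nrow(r)))
    if (nrow(r) > 0L) {
      tab <- table(factor(r$category, levels = 0:4))
      cat(" [", paste(sprintf("cat%d:%d", 0:4, as.integer(tab)), collapse = " "),
          "]", sep = "")
    }
    cat("\n")
  }
  if (!is.null(x$conserved))
    cat(sprintf("  conserved across replicates: %d\n", nrow(x$conserved)))
  invisible(x)
}

#' Run a complete analysis from a configuration list
#'
#' Thin orchestration wrapper around [predict_targets()] for scripted use:
#' reads the reference (transcriptome FASTA, or GFF3 + genome), the sRNA and
#' degradome FASTA libraries, runs the prediction and writes one CSV per
#' degradome library (plus a conservation-intersected summary when requested)
#' and a log file into `config$out_dir`.
#'
#' @param config named list. Required: `srna` and `degradome` (character
#'   vectors of FASTA paths) and either `transcriptome` (FASTA) or `gff3` +
#'   `genome`. Optional: `include_utrs`, `rules` (`"allen"`,
#'   `"fahlgren_carrington"` or a rule JSON path), `out_dir`, and any
#'   argument of [predict_targets()] by the same name.
#' @return the `target_predictions` object, invisibly.
#' @export
run_analysis <- function(config) {
  stopifnot(is.list(config))
  if (!is.null(config$gff3)) {
    if (is.null(config$genome))
      stop("a GFF3 reference requires a corresponding genome")
    transcripts <- extract_transcripts_gff3(
      config$gff3, config$genome,
      include_utrs = isTRUE(config$include_utrs %||% TRUE))
  } else if (!is.null(config$transcriptome)) {
    transcripts <- read_transcriptome_fasta(config$transcriptome)
  } else stop("config needs 'transcriptome' or 'gff3' + 'genome'")
  rules <- config$rules %||% "allen"
  if (is.character(rules)) {
    rules <- if (rules %in% c("allen", "fahlgren_carrington", "fc")) {
      targeting_rules(if (rules == "fc") "fahlgren_carrington" else rules)
    } else read_targeting_rules(rules)
  }
  srna <- lapply(config$srna, read_redundant_fasta)
  degradome <- lapply(config$degradome, read_redundant_fasta)
  pass <- intersect(names(config),
                    setdiff(names(formals(predict_targets)),
                            c("transcripts", "srna", "degradome", "rules")))
  pred <- do.call(predict_targets,
                  c(list(transcripts = transcripts, srna = srna,
                         degradome = degradome, rules = rules),
                    config[pass]))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- c(sprintf("libraries: %d sRNA, %d degradome",
                     length(srna), length(degradome)),
             sprintf("transcripts: %d", length(transcripts)),
             sprintf("sRNA normalisation base (post-filter total): %d",
                     pred$settings$srna_total))
    for (nm in names(pred$results)) {
      f <- file.path(out_dir, paste0(sub("\\.fa(sta)?$", "", nm), "_results.csv"))
      write_results_csv(pred$results[[nm]], f)
      log <- c(log, sprintf("%s: %d interaction(s) -> %s", nm,
                            nrow(pred$results[[nm]]), f))
    }
    if (!is.null(pred$conserved)) {
      f <- file.path(out_dir, "conserved_results.csv")
      write_results_csv(pred$conserved, f)
      log <- c(log, sprintf("conserved summary: %d interaction(s) -> %s",
                            nrow(pred$conserved), f))
    }
    writeLines(log, file.path(out_dir, "analysis.log"))
  }
  invisible(pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
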