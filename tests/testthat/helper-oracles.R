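# Independent oracles used to validate the package's aligners. These are
# deliberately naive enumeration/bookkeeping implementations that share no
# code with the package internals.

BASES <- c("A", "C", "G", "T")
BCODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

pair_cls <- function(sb, tb) {
  a <- BCODE[[sb]]; b <- BCODE[[tb]]
  if (a + b == 3L) 0L
  else if ((a == 2L && b == 3L) || (a == 3L && b == 2L)) 1L
  else 2L
}

# ---- exhaustive duplex oracle (max_gaps <= 1) ------------------------------
# Enumerates every alignment configuration explicitly: no gap, a bulged sRNA
# base at any position j != 10, or a skipped window base before pairing
# position j != 10. Columns are laid out in duplex order and every rule is
# re-checked from the final column list.

oracle_duplex <- function(srna, window, rules) {
  stopifnot(rules$max_gaps <= 1L)
  L <- nchar(srna)
  s <- strsplit(srna, "")[[1]]
  w <- strsplit(window, "")[[1]]

  build_cols <- function(type, j) {
    ip <- L:1
    if (type == "none") {
      d <- data.frame(ipos = ip, wpos = 27L - ip, state = NA_integer_)
    } else if (type == "sbulge") {
      wp <- if (j < 10) ifelse(ip > j, 27L - ip,
                               ifelse(ip == j, NA, 27L - ip - 1L))
      else ifelse(ip < j, 27L - ip, ifelse(ip == j, NA, 27L - ip + 1L))
      d <- data.frame(ipos = ip, wpos = wp, state = NA_integer_)
      d$state[d$ipos == j] <- 4L
    } else { # tbulge: window base skipped before pairing position j
      wp <- if (j < 10) ifelse(ip > j, 27L - ip, 27L - ip + 1L)
      else ifelse(ip < j, 27L - ip, 27L - ip - 1L)
      d <- data.frame(ipos = ip, wpos = wp, state = NA_integer_)
      gap <- data.frame(ipos = j, wpos = 27L - j, state = 3L)
      at <- which(d$ipos == j)
      d <- if (j < 10) rbind(d[seq_len(at - 1L), ], gap,
                             d[at:nrow(d), ])
      else rbind(d[seq_len(at), ], gap, d[-seq_len(at), ])
    }
    d
  }

  eval_cols <- function(d) {
    paired <- is.na(d$state)
    if (any(paired & (d$wpos < 1L | d$wpos > 32L))) return(NULL)
    st <- d$state
    st[paired] <- mapply(function(i, wi) pair_cls(s[i], w[wi]),
                         d$ipos[paired], d$wpos[paired])
    core <- d$ipos >= rules$core_start & d$ipos <= rules$core_end
    mult <- ifelse(core, rules$core_multiplier, 1)
    pen <- numeric(nrow(d))
    pen[st == 1L] <- rules$gu_wobble_score * mult[st == 1L]
    msc <- ifelse(d$ipos == 10L, rules$pos10_mismatch_score,
                  ifelse(d$ipos == 11L, rules$pos11_mismatch_score,
                         rules$mismatch_score))
    pen[st == 2L] <- (msc * mult)[st == 2L]
    pen[st >= 3L] <- rules$gap_score * mult[st >= 3L]
    score <- sum(pen)
    if (score > rules$max_score + 1e-9) return(NULL)
    if (!rules$allow_mismatch_pos10 && any(d$ipos == 10L & st != 0L)) return(NULL)
    if (!rules$allow_mismatch_pos11 && any(d$ipos == 11L & st != 0L)) return(NULL)
    if (any(st == 2L & d$ipos %in% rules$non_permissible_mismatch_positions))
      return(NULL)
    if (length(rules$permissible_mismatch_positions) > 0L &&
        any(st == 2L & !d$ipos %in% rules$permissible_mismatch_positions))
      return(NULL)
    mm <- sum(st == 2L); wob <- sum(st == 1L); gaps <- sum(st >= 3L)
    if (wob > rules$max_gu_wobbles || gaps > rules$max_gaps) return(NULL)
    eff <- st == 2L | st >= 3L | (st == 1L & rules$gu_counts_as_mismatch)
    mm_eff <- sum(st == 2L | (st == 1L & rules$gu_counts_as_mismatch))
    if (mm_eff > rules$max_mismatches) return(NULL)
    if (sum((st == 2L | (st == 1L & rules$gu_counts_as_mismatch)) & core) >
        rules$max_mismatches_core) return(NULL)
    runmax <- function(x) if (any(x)) max(rle(x)$lengths[rle(x)$values]) else 0L
    if (runmax(eff) > rules$max_adjacent_mismatches) return(NULL)
    if (runmax(eff & core) > rules$max_adjacent_mismatches_core) return(NULL)
    list(score = score, gaps = gaps, mmwob = mm + wob)
  }

  res <- list(eval_cols(build_cols("none", NA)))
  if (rules$max_gaps >= 1L) {
    for (j in setdiff(seq_len(L), 10L)) {
      res <- c(res, list(eval_cols(build_cols("sbulge", j)),
                         eval_cols(build_cols("tbulge", j))))
    }
  }
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0L) return(NULL)
  key <- vapply(res, function(r) c(r$score, r$gaps, r$mmwob) %*% c(1e6, 1e3, 1),
                numeric(1))
  res[[which.min(key)]]
}

# ---- region feasibility oracle (max_gaps <= 1) -----------------------------
# Explicit enumeration of the region alignment configurations: unshifted
# pairing, a register shift of up to max_gaps caused by gaps outside the
# region (R1/R3 only; charged a gap and its penalty), or one internal bulge
# of either kind. Target positions outside the 7-mer are free.

.region_layout_cache <- new.env(parent = emptyenv())

oracle_region_valid <- function(region, scode, mcode, srna_len, rules) {
  stopifnot(rules$max_gaps <= 1L)
  s7 <- strsplit(decode_seq(scode, 7, "sRNA"), "")[[1]]
  t7 <- strsplit(decode_seq(mcode, 7, "mRNA"), "")[[1]]
  abs0 <- switch(region, R1 = 0L, R2 = 7L, R3 = srna_len - 7L)

  eval_cfg <- function(cols, pre_gaps = 0L) {
    # cols: data.frame(k, c, state) in ascending absolute-position order;
    # state NA = pair/free, 3 = skipped target base, 4 = bulged sRNA base
    ipos <- abs0 + cols$k
    st <- cols$state
    free <- is.na(st) & (cols$c < 1L | cols$c > 7L)
    st[free] <- 0L
    idx <- which(is.na(st))
    st[idx] <- mapply(function(k, c) pair_cls(s7[k], t7[c]),
                      cols$k[idx], cols$c[idx])
    core <- ipos >= rules$core_start & ipos <= rules$core_end
    mult <- ifelse(core, rules$core_multiplier, 1)
    pen <- numeric(length(st))
    pen[st == 1L] <- rules$gu_wobble_score * mult[st == 1L]
    msc <- ifelse(ipos == 10L, rules$pos10_mismatch_score,
                  ifelse(ipos == 11L, rules$pos11_mismatch_score,
                         rules$mismatch_score))
    pen[st == 2L] <- (msc * mult)[st == 2L]
    pen[st >= 3L] <- rules$gap_score * mult[st >= 3L]
    score <- sum(pen) +
      pre_gaps * rules$gap_score * min(1, rules$core_multiplier)
    if (score > rules$max_score + 1e-9) return(FALSE)
    if (!rules$allow_mismatch_pos10 && any(ipos == 10L & st != 0L)) return(FALSE)
    if (!rules$allow_mismatch_pos11 && any(ipos == 11L & st != 0L)) return(FALSE)
    if (any(st == 2L & ipos %in% rules$non_permissible_mismatch_positions))
      return(FALSE)
    if (length(rules$permissible_mismatch_positions) > 0L &&
        any(st == 2L & !ipos %in% rules$permissible_mismatch_positions))
      return(FALSE)
    if (sum(st == 1L) > rules$max_gu_wobbles) return(FALSE)
    if (sum(st >= 3L) + pre_gaps > rules$max_gaps) return(FALSE)
    mm_eff <- st == 2L | (st == 1L & rules$gu_counts_as_mismatch)
    if (sum(mm_eff) > rules$max_mismatches) return(FALSE)
    if (sum(mm_eff & core) > rules$max_mismatches_core) return(FALSE)
    eff <- st == 2L | st >= 3L | (st == 1L & rules$gu_counts_as_mismatch)
    runmax <- function(x) if (any(x)) max(rle(x)$lengths[rle(x)$values]) else 0L
    if (runmax(eff) > rules$max_adjacent_mismatches) return(FALSE)
    if (runmax(eff & core) > rules$max_adjacent_mismatches_core) return(FALSE)
    TRUE
  }

  key <- paste(region, rules$max_gaps)
  cfgs <- .region_layout_cache[[key]]
  if (is.null(cfgs)) {
  plain <- function(cmap) data.frame(k = 1:7, c = cmap, state = NA_integer_)
  cfgs <- list(list(cols = plain(1:7), pre = 0L))
  g <- rules$max_gaps
  if (g >= 1L) {
    if (region != "R2") {
      cfgs <- c(cfgs, list(list(cols = plain(1:7 + 1L), pre = 1L),
                           list(cols = plain(1:7 - 1L), pre = 1L)))
    }
    # internal single bulges; for R2 a gap never crosses the anchor (k = 3)
    steps <- if (region == "R2") c(1L, 2L, 4L, 5L, 6L, 7L) else 1:7
    dirA <- region == "R1"   # traversal direction: R1 descends, R3 ascends
    for (j in steps) {
      # bulged sRNA base at k = j
      cmap <- 1:7
      if (region == "R2") {
        if (j < 3L) cmap[1:7 < j] <- (1:7)[1:7 < j] + 1L
        else cmap[1:7 > j] <- (1:7)[1:7 > j] - 1L
      } else if (dirA) cmap[1:7 < j] <- (1:7)[1:7 < j] + 1L
      else cmap[1:7 > j] <- (1:7)[1:7 > j] - 1L
      d <- data.frame(k = 1:7, c = cmap, state = NA_integer_)
      d$state[d$k == j] <- 4L
      cfgs <- c(cfgs, list(list(cols = d, pre = 0L)))
      # skipped target base before pairing k = j
      cmap <- 1:7
      if (region == "R2") {
        if (j < 3L) { cmap[j] <- j - 1L; cmap[1:7 < j] <- (1:7)[1:7 < j] - 1L }
        else { cmap[j] <- j + 1L; cmap[1:7 > j] <- (1:7)[1:7 > j] + 1L }
      } else if (dirA) { cmap[j] <- j - 1L; cmap[1:7 < j] <- (1:7)[1:7 < j] - 1L }
      else { cmap[j] <- j + 1L; cmap[1:7 > j] <- (1:7)[1:7 > j] + 1L }
      d <- data.frame(k = 1:7, c = cmap, state = NA_integer_)
      gap <- data.frame(k = j, c = j, state = 3L)
      at <- which(d$k == j)
      before <- if (region == "R2") j >= 3L else !dirA
      d <- if (before) rbind(d[seq_len(at - 1L), ], gap, d[at:nrow(d), ])
      else rbind(d[seq_len(at), ], gap, d[-seq_len(at), ])
      cfgs <- c(cfgs, list(list(cols = d, pre = 0L)))
    }
  }
  .region_layout_cache[[key]] <- cfgs
  }
  for (cfg in cfgs) if (eval_cfg(cfg$cols, cfg$pre)) return(TRUE)
  FALSE
}

# ---- naive degradome scan oracle -------------------------------------------

oracle_scan <- function(transcripts, lib, min_len, max_len) {
  rec <- lib$records[nchar(lib$records$sequence) >= min_len &
                       nchar(lib$records$sequence) <= max_len, , drop = FALSE]
  hits <- list()
  nmatch <- setNames(integer(nrow(rec)), rec$sequence)
  for (i in seq_len(nrow(rec))) {
    for (tx in names(transcripts)) {
      sq <- transcripts[[tx]]
      L <- nchar(sq); k <- nchar(rec$sequence[i])
      if (L < k) next
      starts <- which(vapply(seq_len(L - k + 1L), function(p)
        substr(sq, p, p + k - 1L) == rec$sequence[i], logical(1)))
      if (length(starts) > 0L) {
        nmatch[i] <- nmatch[i] + length(starts)
        hits[[length(hits) + 1L]] <- data.frame(
          transcript = tx, pos = starts, read = i,
          abundance = rec$abundance[i])
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  h$weighted <- h$abundance / nmatch[h$read]
  out <- lapply(split(h, h$transcript), function(d) {
    ab <- tapply(d$abundance, d$pos, sum)
    wt <- tapply(d$weighted, d$pos, sum)
    p <- as.integer(names(ab)); o <- order(p)
    data.frame(pos = p[o], abundance = as.integer(ab)[o],
               weighted_abundance = as.numeric(wt)[o])
  })
  out
}

# planted fixture around a single site, returning the window and edited sRNA
make_site_fixture <- function(n_mm = 0L, n_wob = 0L, Ls = 21L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tx <- random_seq(120)
  p <- 60L
  site <- substr(tx, p + 10L - Ls, p + 9L)
  srna <- rc(site)
  sv <- strsplit(srna, "")[[1]]
  tv <- strsplit(site, "")[[1]]
  eligible <- setdiff(seq_len(Ls), c(10L, 11L))
  wob_ok <- eligible[tv[Ls - eligible + 1L] %in% c("G", "T")]
  pick <- function(pool, n) pool[sample.int(length(pool), n)]
  wpos <- if (n_wob > 0L) pick(wob_ok, n_wob) else integer(0)
  mpos <- if (n_mm > 0L) pick(setdiff(eligible, wpos), n_mm) else integer(0)
  for (i in wpos) sv[i] <- if (tv[Ls - i + 1L] == "G") "T" else "G"
  for (i in mpos) {
    tb <- tv[Ls - i + 1L]
    bad <- setdiff(BASES, c(chartr("ACGT", "TGCA", tb),
                            if (tb == "G") "T", if (tb == "T") "G"))
    sv[i] <- bad[sample.int(length(bad), 1L)]
  }
  list(transcript = tx, pos = p, window = substr(tx, p - 16L, p + 15L),
       srna = paste(sv, collapse = ""), mpos = mpos, wpos = wpos)
}

# length-100 sequence with n "AC" dimers, spread over short runs so that the
# mono and tri fractions stay inside their bounds while AC sweeps its boundary
di_seq <- function(n) {
  r <- min(n, max(1L, 101L - 2L * n))  # runs; each extra AC in a run adds ACA
  sizes <- rep(n %/% r, r)
  if (n %% r > 0) sizes[seq_len(n %% r)] <- sizes[seq_len(n %% r)] + 1L
  seps <- rep(c("G", "T"), length.out = r - 1L)
  core <- paste(vapply(seq_len(r), function(i)
    paste0(strrep("AC", sizes[i]), if (i < r) seps[i] else ""), ""),
    collapse = "")
  pad <- strrep("GTTGG", 20L)
  paste0(core, substr(pad, 1L, 100L - nchar(core)))
}

# length-100 sequence with k "ACG" trimers in one run plus diverse padding
tri_seq <- function(k) {
  core <- strrep("ACG", k)
  pad <- strrep("TTAGG", 20L)
  paste0(core, substr(pad, 1L, 100L - nchar(core)))
}

brute_frac <- function(s, k) {
  n <- nchar(s) - k + 1
  max(table(substring(s, 1:n, 1:n + k - 1))) / n
}

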