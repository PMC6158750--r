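test_that("presets differ only in the position-10/11 permissions", {
  al <- targeting_rules("allen")
  fc <- targeting_rules("fahlgren_carrington")
  expect_equal(al$mismatch_score, 1.0)
  expect_equal(al$gu_wobble_score, 0.5)
  expect_equal(al$gap_score, 1.0)
  expect_equal(c(al$core_start, al$core_end), c(2L, 13L))
  expect_equal(al$core_multiplier, 2.0)
  expect_equal(al$max_score, 4.0)
  expect_equal(al$max_adjacent_mismatches, 2L)
  expect_equal(al$max_mismatches, 4L)
  expect_equal(al$max_gaps, 1L)
  expect_false(al$allow_mismatch_pos10 || al$allow_mismatch_pos11)
  expect_true(fc$allow_mismatch_pos10 && fc$allow_mismatch_pos11)
  diff <- names(which(!mapply(identical, unclass(al), unclass(fc))))
  expect_setequal(diff, c("allow_mismatch_pos10", "allow_mismatch_pos11"))
})

test_that("rule configuration files round-trip presets", {
  f <- tempfile(fileext = ".json")
  for (p in c("allen", "fahlgren_carrington")) {
    r <- targeting_rules(p)
    write_targeting_rules(r, f)
    back <- read_targeting_rules(f)
    expect_equal(unclass(back)[paretarget:::rule_fields()],
                 unclass(r)[paretarget:::rule_fields()])
  }
  expect_error(targeting_rules("allen", nonsense = 1), "unknown rule field")
})

test_that("region extraction follows the fixed coordinates", {
  s21 <- random_seq(21)
  r <- extract_regions(s21)
  expect_identical(decode_seq(r$r1), substr(s21, 1, 7))
  expect_identical(decode_seq(r$r2), substr(s21, 8, 14))
  expect_identical(decode_seq(r$r3), substr(s21, 15, 21))
  s19 <- random_seq(19)
  r19 <- extract_regions(s19)
  expect_identical(decode_seq(r19$r3), substr(s19, 13, 19)) # overlaps R2
  expect_error(extract_regions(random_seq(13)), "14")
})

test_that("a region row always contains its own code; strict rules give {c}", {
  al <- targeting_rules("allen")
  strict <- targeting_rules("allen", max_mismatches = 0L, max_gu_wobbles = 0L,
                            max_gaps = 0L, max_score = 0)
  set.seed(31)
  for (i in 1:5) {
    code <- sample(0:16383, 1)
    for (reg in c("R1", "R2", "R3")) {
      expect_true(code %in% region_row(reg, code, 21, al))
      expect_identical(region_row(reg, code, 21, strict), as.integer(code))
    }
  }
})

test_that("gap-free region rows equal the positionwise brute-force oracle", {
  rules0 <- targeting_rules("allen", max_gaps = 0L)
  set.seed(32)
  all_m <- 0:16383
  for (reg in c("R1", "R2", "R3")) {
    for (L in c(19L, 21L)) {
      code <- sample(all_m, 1)
      want <- all_m[vapply(all_m, function(m)
        oracle_region_valid(reg, code, m, L, rules0), TRUE)]
      expect_identical(region_row(reg, code, L, rules0), want)
    }
  }
})

test_that("gapped region feasibility matches the enumeration oracle on samples", {
  set.seed(33)
  for (rules in list(targeting_rules("allen"),
                     targeting_rules("fahlgren_carrington"),
                     targeting_rules("allen", gu_counts_as_mismatch = TRUE))) {
    for (reg in c("R1", "R2", "R3")) {
      code <- sample(0:16383, 1)
      ms <- sample(0:16383, 400)
      got <- vapply(ms, function(m)
        paretarget:::region_pair_valid(reg, code, m, 21L, rules), TRUE)
      want <- vapply(ms, function(m)
        oracle_region_valid(reg, code, m, 21L, rules), TRUE)
      expect_identical(got, want)
    }
  }
})

test_that("region row size is monotone in the rule budgets", {
  base <- targeting_rules("allen", max_gaps = 0L)
  code <- encode_seq("ACGTGCA", "sRNA")$value
  n0 <- length(region_row("R2", code, 21, base))
  wider <- list(targeting_rules("allen", max_gaps = 0L, max_score = 6),
                targeting_rules("allen", max_gaps = 0L, max_mismatches = 6L),
                targeting_rules("allen"))   # max_gaps 1
  for (r in wider) expect_gte(length(region_row("R2", code, 21, r)), n0)
})

test_that("three-stage filter keeps perfect sites and drops hopeless TR2 groups", {
  set.seed(34)
  al <- targeting_rules("allen")
  fx <- make_site_fixture(0, 0, 21)
  prof <- assign_categories(data.frame(pos = fx$pos, abundance = 5L,
                                       weighted_abundance = 5))
  cand <- extract_candidates("t", fx$transcript, prof)
  surv <- three_stage_filter(extract_regions(fx$srna), group_by_tr2(cand), al)
  expect_equal(nrow(surv), 1L)
  # an unrelated sRNA whose R2 mismatches the TR2 completely is eliminated
  bad_srna <- paste0(substr(fx$srna, 1, 7),
                     chartr("ACGT", "CAAC", substr(fx$srna, 8, 14)),
                     substr(fx$srna, 15, 21))
  surv2 <- three_stage_filter(extract_regions(bad_srna), group_by_tr2(cand), al)
  expect_equal(nrow(surv2), 0L)
})

test_that("prefilter is conservative: identical final predictions on vs bypassed", {
  set.seed(35)
  n_fix <- 250
  presets <- list(targeting_rules("allen"),
                  targeting_rules("fahlgren_carrington"),
                  targeting_rules("allen", max_gaps = 0L))
  for (i in seq_len(n_fix)) {
    rules <- presets[[(i %% length(presets)) + 1L]]
    Ls <- sample(19:24, 1)
    fx <- make_site_fixture(n_mm = sample(0:4, 1), n_wob = sample(0:2, 1),
                            Ls = Ls)
    prof <- assign_categories(data.frame(pos = fx$pos, abundance = 5L,
                                         weighted_abundance = 5))
    cand <- extract_candidates("t", fx$transcript, prof)
    regions <- extract_regions(fx$srna)
    surv <- three_stage_filter(regions, group_by_tr2(cand), rules)
    aln_all <- align_duplex(fx$srna, cand$window[1], rules)
    aln_flt <- if (nrow(surv) > 0) align_duplex(fx$srna, surv$window[1], rules)
    if (is.null(aln_all)) {
      expect_null(aln_flt)
    } else {
      # the filter must never remove a candidate the aligner accepts
      expect_equal(nrow(surv), 1L)
      expect_equal(aln_flt$score, aln_all$score)
    }
  }
})
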