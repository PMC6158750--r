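test_that("a perfect complement aligns with score 0 and all matches", {
  set.seed(41)
  fx <- make_site_fixture(0, 0, 21)
  b <- align_duplex(fx$srna, fx$window, targeting_rules("allen"))
  expect_equal(b$score, 0)
  expect_equal(b$n_mismatches + b$n_wobbles + b$n_gaps, 0L)
  expect_true(all(b$states == 0L))
  expect_identical(nchar(b$srna_line), 21L)
})

test_that("scoring arithmetic follows the preset (core doubling)", {
  set.seed(42)
  # single G:U at sRNA position 5 -> 0.5 * 2 (core 2-13)
  repeat {
    fx <- make_site_fixture(0, 0, 21, seed = sample.int(1e6, 1))
    tv <- strsplit(substr(fx$transcript, fx$pos + 10 - 21, fx$pos + 9), "")[[1]]
    if (tv[21 - 5 + 1] %in% c("G", "T")) break
  }
  sv <- strsplit(fx$srna, "")[[1]]
  sv[5] <- if (tv[21 - 5 + 1] == "G") "T" else "G"
  b <- align_duplex(paste(sv, collapse = ""), fx$window, targeting_rules("allen"))
  expect_equal(b$score, 1.0)
  expect_equal(b$n_wobbles, 1L)
  # single mismatch at position 16 (outside the core) -> 1.0
  sv <- strsplit(fx$srna, "")[[1]]
  tb <- tv[21 - 16 + 1]
  sv[16] <- setdiff(c("A", "C", "G", "T"),
                    c(chartr("ACGT", "TGCA", tb),
                      if (tb == "G") "T", if (tb == "T") "G"))[1]
  b2 <- align_duplex(paste(sv, collapse = ""), fx$window, targeting_rules("allen"))
  expect_equal(b2$score, 1.0)
  expect_equal(b2$n_mismatches, 1L)
})

test_that("a position-10 mismatch is rejected by allen, scored 2.0 by F&C", {
  set.seed(43)
  fx <- make_site_fixture(0, 0, 21)
  tv <- strsplit(substr(fx$transcript, fx$pos + 10 - 21, fx$pos + 9), "")[[1]]
  sv <- strsplit(fx$srna, "")[[1]]
  tb <- tv[21 - 10 + 1]
  sv[10] <- setdiff(c("A", "C", "G", "T"),
                    c(chartr("ACGT", "TGCA", tb),
                      if (tb == "G") "T", if (tb == "T") "G"))[1]
  s10 <- paste(sv, collapse = "")
  expect_null(align_duplex(s10, fx$window, targeting_rules("allen")))
  b <- align_duplex(s10, fx$window, targeting_rules("fahlgren_carrington"))
  expect_equal(b$score, 2.0)   # pos-10 mismatch score 1.0 doubled in the core
  expect_equal(b$n_mismatches, 1L)
})

test_that("aligner agrees with the exhaustive gapped oracle on random pairs", {
  set.seed(44)
  presets <- list(allen = targeting_rules("allen"),
                  fc = targeting_rules("fahlgren_carrington"))
  n_pairs <- 400
  for (nm in names(presets)) {
    rules <- presets[[nm]]
    for (i in seq_len(n_pairs)) {
      Ls <- sample(19:24, 1)
      # mix planted near-sites (alignable) and random windows (mostly not)
      if (i %% 2 == 0) {
        fx <- make_site_fixture(n_mm = sample(0:4, 1), n_wob = sample(0:2, 1),
                                Ls = Ls)
        srna <- fx$srna; window <- fx$window
      } else {
        srna <- random_seq(Ls); window <- random_seq(32)
      }
      got <- align_duplex(srna, window, rules)
      want <- oracle_duplex(srna, window, rules)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_false(is.null(got))
        expect_equal(got$score, want$score)
        expect_equal(got$n_gaps, want$gaps)
        expect_equal(got$n_mismatches + got$n_wobbles, want$mmwob)
      }
    }
  }
})

test_that("selection prefers score, then gaps, then mismatches+wobbles", {
  mk <- function(score, gaps, mm, wob, states) {
    structure(list(srna = "A", target_window = "", score = score,
                   n_mismatches = mm, n_wobbles = wob, n_gaps = gaps,
                   states = states, target_line = "", srna_line = ""),
              class = "duplex_alignment")
  }
  a <- mk(1.0, 0L, 1L, 0L, c(0L, 2L))
  b <- mk(1.0, 1L, 0L, 0L, c(0L, 3L))
  expect_identical(select_best(list(b, a)), a)
  c1 <- mk(0.5, 0L, 0L, 1L, c(0L, 1L))
  expect_identical(select_best(list(a, b, c1)), c1)
  # full tie: broken by the 5'-most state difference; states are stored in
  # window order (sRNA 3'->5'), so d1's mismatch sits at the sRNA 3' end and
  # d1 shows the smaller state at the first 5'-side difference
  d1 <- mk(1.0, 0L, 1L, 0L, c(2L, 0L, 0L))
  d2 <- mk(1.0, 0L, 1L, 0L, c(0L, 0L, 2L))
  expect_identical(select_best(list(d1, d2)), d1)
  expect_identical(select_best(list(d2, d1)), d1)
  expect_error(select_best(list()), "no alignments")
})

test_that("rendering uses | o space - symbols", {
  set.seed(45)
  fx <- make_site_fixture(0, 0, 21)
  b <- align_duplex(fx$srna, fx$window, targeting_rules("allen"))
  lines <- strsplit(render_duplex(b), "\n")[[1]]
  expect_length(lines, 3L)
  expect_identical(lines[2], strrep("|", 21))
  fxw <- make_site_fixture(0, 1, 21)
  bw <- align_duplex(fxw$srna, fxw$window, targeting_rules("allen"))
  expect_equal(sum(strsplit(render_duplex(bw), "\n")[[1]][2] ==
                     strrep("|", 21)), 0)
  expect_equal(lengths(regmatches(render_duplex(bw),
                                  gregexpr("o", render_duplex(bw)))), 1L)
})

test_that("accepted scores never exceed max_score and relaxations never reject", {
  set.seed(46)
  al <- targeting_rules("allen")
  relaxed <- targeting_rules("allen", max_score = 8, max_mismatches = 8L)
  for (i in 1:60) {
    fx <- make_site_fixture(n_mm = sample(0:4, 1), n_wob = sample(0:2, 1))
    b <- align_duplex(fx$srna, fx$window, al)
    if (!is.null(b)) {
      expect_lte(b$score, al$max_score)
      b2 <- align_duplex(fx$srna, fx$window, relaxed)
      expect_false(is.null(b2))
      expect_lte(b2$score, b$score)
    }
  }
})

test_that("an overlong sRNA is a hard error, not a truncation", {
  expect_error(align_duplex(random_seq(27), random_seq(32),
                            targeting_rules("allen")), "overhang")
})
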