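test_that("fragment index stores sorted per-length lists within range", {
  seqs <- c(random_seq(20), random_seq(20), random_seq(21), random_seq(25))
  lib <- paretarget:::new_read_library(seqs, rep(1L, 4), name = "d")
  idx <- build_fragment_index(lib, 19, 21)
  expect_setequal(names(idx$by_length), c("20", "21"))
  expect_false(is.unsorted(idx$by_length[["20"]]$values, strictly = TRUE))
  empty <- paretarget:::new_read_library(random_seq(30), 1L, name = "d")
  expect_error(build_fragment_index(empty, 19, 21), "size range")
})

test_that("a planted tag is found at its 5' end with its abundance", {
  set.seed(21)
  tx <- c(t1 = random_seq(200))
  tag <- substr(tx[["t1"]], 31, 50)
  lib <- paretarget:::new_read_library(tag, 7L, name = "d")
  prof <- align_degradome(tx, build_fragment_index(lib))
  expect_identical(prof[["t1"]]$pos, 31L)
  expect_identical(prof[["t1"]]$abundance, 7L)
  expect_equal(prof[["t1"]]$weighted_abundance, 7)
})

test_that("multi-mapping tags split their weighted abundance", {
  set.seed(22)
  shared <- random_seq(20)
  tx <- c(a = paste0(random_seq(40), shared, random_seq(40)),
          b = paste0(random_seq(60), shared, random_seq(20)))
  lib <- paretarget:::new_read_library(shared, 10L, name = "d")
  prof <- align_degradome(tx, build_fragment_index(lib))
  expect_equal(prof[["a"]]$weighted_abundance, 5)
  expect_equal(prof[["b"]]$weighted_abundance, 5)
  expect_equal(prof[["a"]]$abundance, 10L)
  # conservation: summed weighted abundance equals the read's abundance
  expect_equal(sum(vapply(prof, function(p) sum(p$weighted_abundance), 0)), 10)
})

test_that("binary-search alignment equals the naive substring-scan oracle", {
  set.seed(23)
  tx <- setNames(vapply(1:12, function(i) random_seq(sample(150:400, 1)), ""),
                 paste0("tx", 1:12))
  # reads: half planted from transcripts, half random
  planted <- vapply(1:75, function(i) {
    t <- sample(names(tx), 1)
    L <- sample(19:21, 1)
    p <- sample(nchar(tx[[t]]) - L, 1)
    substr(tx[[t]], p, p + L - 1)
  }, "")
  noise <- vapply(1:75, function(i) random_seq(sample(19:21, 1)), "")
  lib <- paretarget:::new_read_library(c(planted, noise),
                                       sample(1:20, 150, TRUE), name = "d")
  got <- align_degradome(tx, build_fragment_index(lib, 19, 21))
  want <- oracle_scan(tx, lib, 19, 21)
  expect_setequal(names(got), names(want))
  for (t in names(want)) {
    expect_identical(got[[t]]$pos, want[[t]]$pos)
    expect_identical(got[[t]]$abundance, want[[t]]$abundance)
    expect_equal(got[[t]]$weighted_abundance, want[[t]]$weighted_abundance)
  }
})

test_that("category assignment matches the printed definitions", {
  prof <- function(ab) data.frame(pos = seq_along(ab) * 30 + 20,
                                  abundance = as.integer(ab),
                                  weighted_abundance = as.numeric(ab))
  # tied maxima; avg over abundance>1 = (5+5+2)/3 = 4
  p1 <- assign_categories(prof(c(5, 5, 2, 1)))
  expect_identical(p1$category, c(1L, 1L, 3L, 4L))
  # unique maximum; avg = (9+2)/2 = 5.5
  p2 <- assign_categories(prof(c(9, 2, 1)))
  expect_identical(p2$category, c(0L, 3L, 4L))
  expect_identical(assign_categories(prof(1))$category, 4L)
  # above-average case
  p3 <- assign_categories(prof(c(9, 8, 2, 2)))
  expect_identical(p3$category, c(0L, 2L, 3L, 3L))
})

test_that("category partition is exhaustive and exclusive", {
  set.seed(24)
  for (i in 1:50) {
    ab <- sample(1:9, sample(1:12, 1), replace = TRUE)
    p <- assign_categories(data.frame(pos = seq_along(ab) * 40,
                                      abundance = ab,
                                      weighted_abundance = ab))
    expect_true(all(p$category %in% 0:4))
    expect_equal(sum(table(factor(p$category, levels = 0:4))), length(ab))
    expect_lte(sum(p$category == 0L), 1L)
  }
})

test_that("candidate windows are exactly 32 nt and respect boundaries", {
  set.seed(25)
  tx <- random_seq(200)
  prof <- assign_categories(data.frame(pos = c(10L, 17L, 100L, 185L, 186L),
                                       abundance = c(5L, 5L, 5L, 5L, 5L),
                                       weighted_abundance = rep(5, 5)))
  cand <- extract_candidates("t", tx, prof)
  expect_setequal(cand$pos, c(17L, 100L, 185L))   # 10 and 186 overrun
  expect_true(all(nchar(cand$window) == 32L))
  expect_identical(cand$window[cand$pos == 100L], substr(tx, 84, 115))
})

test_that("category and abundance gates exclude candidates", {
  tx <- random_seq(120)
  prof <- assign_categories(data.frame(pos = c(40L, 70L),
                                       abundance = c(9L, 1L),
                                       weighted_abundance = c(9, 1)))
  expect_identical(extract_candidates("t", tx, prof, 0:3)$pos, 40L)
  expect_equal(nrow(extract_candidates("t", tx, prof, 0:3,
                                       min_fragment_abundance = 10L)), 0L)
})

test_that("TR2 of a perfect planted site decodes to the sRNA R2 code", {
  set.seed(26)
  fx <- make_site_fixture(0, 0, 21)
  tx <- fx$transcript
  prof <- assign_categories(data.frame(pos = fx$pos, abundance = 5L,
                                       weighted_abundance = 5))
  cand <- extract_candidates("t", tx, prof)
  reg <- extract_regions(fx$srna)
  expect_equal(cand$tr2, reg$r2$value)   # complement identity
  expect_equal(cand$tr1, reg$r1$value)
})

test_that("TR2 grouping partitions the candidate set", {
  set.seed(27)
  cands <- do.call(rbind, lapply(1:10, function(i) {
    fx <- make_site_fixture(0, 0, 21)
    prof <- assign_categories(data.frame(pos = fx$pos, abundance = 5L,
                                         weighted_abundance = 5))
    extract_candidates(paste0("t", i), fx$transcript, prof)
  }))
  g <- group_by_tr2(cands)
  expect_equal(sum(vapply(g, nrow, 0L)), nrow(cands))
  expect_true(all(vapply(names(g), function(k)
    all(g[[k]]$tr2 == as.numeric(k)), TRUE)))
  expect_length(group_by_tr2(paretarget:::empty_candidates()), 0L)
})
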