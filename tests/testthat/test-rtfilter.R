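test_that("basic filter keeps exactly the PASS+PRECISE calls", {
  calls <- synthetic_calls(20, seed = 5)
  kept <- basic_filter(calls)
  expect_true(all(kept$filter == "PASS" & kept$precise))
  ## enumerate the expected set by hand from the fixture
  expect_identical(kept$id, calls$id[calls$filter == "PASS" & calls$precise])
  expect_equal(nrow(basic_filter(calls[0, ])), 0L)
})

test_that("strict filter applies the four final thresholds exactly", {
  base <- synthetic_calls(1, seed = 1)[1, ]
  base$filter <- "PASS"; base$precise <- TRUE
  cfg <- filter_config(coverage = 30)
  set_fields <- function(mapq, sr, pe, srq) {
    x <- base; x$mapq <- mapq; x$sr <- sr; x$pe <- pe; x$srq <- srq; x
  }
  expect_equal(nrow(strict_filter(set_fields(60L, 14L, 26L, 0.97), cfg)), 1L)
  expect_equal(nrow(strict_filter(set_fields(59L, 14L, 26L, 0.97), cfg)), 0L)  # equality required
  expect_equal(nrow(strict_filter(set_fields(60L, 9L, 26L, 0.97), cfg)), 0L)
  expect_equal(nrow(strict_filter(set_fields(60L, 14L, 61L, 0.97), cfg)), 0L)  # 2 x coverage
  expect_equal(nrow(strict_filter(set_fields(60L, 14L, 60L, 0.97), cfg)), 1L)
  expect_equal(nrow(strict_filter(set_fields(60L, 14L, 26L, 0.9), cfg)), 0L)   # strictly > 0.9
  ## the PE ceiling scales with intended coverage
  expect_equal(nrow(strict_filter(set_fields(60L, 14L, 26L, 0.97),
                                  filter_config(coverage = 10))), 0L)
})

test_that("relaxed filter retains LowQual calls with enough split reads", {
  base <- synthetic_calls(1, seed = 1)[1, ]
  cfg <- filter_config()
  lowq <- function(sr) { x <- base; x$filter <- "LowQual"; x$sr <- sr; x }
  expect_equal(nrow(relaxed_filter(lowq(5L), cfg)), 1L)
  expect_equal(nrow(relaxed_filter(lowq(4L), cfg)), 0L)
  ## every strict survivor is kept by the relaxed tier
  calls <- synthetic_calls(60, seed = 9)
  strict <- strict_filter(basic_filter(calls), cfg)
  relaxed <- relaxed_filter(calls, cfg)
  expect_true(all(strict$id %in% relaxed$id))
  ## alternative composition: strict union LowQual with >= 5 split reads
  cfg2 <- filter_config(relaxed_union_strict = TRUE)
  r2 <- relaxed_filter(calls, cfg2)
  expect_setequal(r2$id, union(strict$id,
                               calls$id[calls$filter == "LowQual" & calls$sr >= 5]))
})

test_that("filter chain is monotone", {
  calls <- synthetic_calls(80, seed = 13)
  cfg <- filter_config()
  b <- basic_filter(calls)
  s <- strict_filter(b, cfg)
  expect_true(all(b$id %in% calls$id))
  expect_true(all(s$id %in% b$id))
  expect_true(all(s$id %in% relaxed_filter(calls, cfg)$id))
})

test_that("reciprocal matching follows connection-type complementarity and the window", {
  jt <- data.frame(junction = c("J1", "J2", "J3"),
                   chrom1 = "chr1", pos1 = c(1000L, 1003L, 1001L),
                   chrom2 = "chr2", pos2 = c(5000L, 5003L, 5002L),
                   ct = c("3to3", "5to5", "3to5"),
                   stringsAsFactors = FALSE)
  p <- match_reciprocal_pairs(jt, window = 100L)
  expect_equal(nrow(p), 1L)               # only the {3to3, 5to5} couple
  expect_setequal(c(p$j1_junction, p$j2_junction), c("J1", "J2"))
  ## outside the window: no pair
  jt2 <- jt; jt2$pos1[2] <- 1500L
  expect_equal(nrow(match_reciprocal_pairs(jt2, window = 100L)), 0L)
  expect_equal(nrow(match_reciprocal_pairs(jt2, window = Inf)), 1L)
})

test_that("56 complementary junction calls pair into 28 candidates", {
  set.seed(31)
  rows <- list()
  for (i in 1:28) {
    ctA <- sample(c("3to3", "3to5"), 1)
    ctB <- rtdetect:::complementary_ct(ctA)
    p1 <- i * 10000L; p2 <- i * 8000L
    rows[[2 * i - 1]] <- data.frame(junction = sprintf("JA%02d", i),
                                    chrom1 = "chr01", pos1 = p1,
                                    chrom2 = "chr16", pos2 = p2, ct = ctA)
    rows[[2 * i]] <- data.frame(junction = sprintf("JB%02d", i),
                                chrom1 = "chr01", pos1 = p1 + 3000L,
                                chrom2 = "chr16", pos2 = p2 + 2500L, ct = ctB)
  }
  jt <- do.call(rbind, rows)
  expect_equal(nrow(jt), 56L)
  pairs <- match_reciprocal_pairs(jt, window = Inf)
  ## complementary CT alone: count matches the junction couples
  expect_equal(sum(!duplicated(t(apply(cbind(pairs$j1_junction,
                                             pairs$j2_junction), 1, sort)))),
               nrow(pairs))
  cross <- table(substr(pairs$j1_junction, 1, 2), substr(pairs$j2_junction, 1, 2))
  pairs100 <- match_reciprocal_pairs(jt, window = 5000L)
  expect_equal(nrow(pairs100), 28L)
})

test_that("pair matching equals a naive quadratic oracle on random calls", {
  calls <- synthetic_calls(50, seed = 77)
  jt <- rtdetect:::junction_table(calls)
  got <- match_reciprocal_pairs(calls, window = 400000L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got_keys <- sort(key(got$j1_junction, got$j2_junction))
  oracle <- character(0)
  for (i in seq_len(nrow(jt))) for (j in seq_len(nrow(jt))) {
    if (i >= j) next
    if (jt$chrom1[i] != jt$chrom1[j] || jt$chrom2[i] != jt$chrom2[j]) next
    ok_ct <- paste(sort(c(jt$ct[i], jt$ct[j])), collapse = "+") %in%
      c("3to3+5to5", "3to5+5to3")
    ok_win <- abs(jt$pos1[i] - jt$pos1[j]) <= 400000L &&
      abs(jt$pos2[i] - jt$pos2[j]) <= 400000L
    if (ok_ct && ok_win)
      oracle <- c(oracle, key(jt$junction[i], jt$junction[j]))
  }
  expect_identical(got_keys, sort(oracle))
  ## permutation invariance
  perm <- calls[sample(seq_len(nrow(calls))), ]
  got2 <- match_reciprocal_pairs(perm, window = 400000L)
  expect_identical(sort(key(got2$j1_junction, got2$j2_junction)), got_keys)
})
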