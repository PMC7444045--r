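## Minimal alignment-record builder for hand-constructed evidence.
mk_rec <- function(qname, mate, chrom, pos, m = 150L, strand = "+",
                   mapq = 60L, clip_left = 0L, clip_right = 0L,
                   is_supp = FALSE, sa_chrom = NA_character_,
                   sa_pos = NA_integer_, sa_strand = NA_character_,
                   mate_chrom = NA_character_, mate_pos = NA_integer_,
                   mate_strand = "+", proper = FALSE, discordant = FALSE) {
  data.frame(qname = qname, mate = mate, chrom = chrom, pos = pos,
             end = pos + m - 1L, strand = strand, mapq = mapq,
             cigar = paste0(if (clip_left) sprintf("%dS", clip_left) else "",
                            sprintf("%dM", m),
                            if (clip_right) sprintf("%dS", clip_right) else ""),
             m = m, clip_left = clip_left, clip_right = clip_right,
             seq = strrep("A", m + clip_left + clip_right), is_supp = is_supp,
             sa_chrom = sa_chrom, sa_pos = sa_pos, sa_strand = sa_strand,
             mate_chrom = mate_chrom, mate_pos = mate_pos,
             mate_strand = mate_strand, proper = proper,
             discordant = discordant, stringsAsFactors = FALSE)
}

disc_pair <- function(qname, chrom1, pos1, strand1, chrom2, pos2, strand2,
                      mapq = 60L) {
  rbind(mk_rec(qname, 1L, chrom1, pos1, strand = strand1, mapq = mapq,
               mate_chrom = chrom2, mate_pos = pos2, mate_strand = strand2,
               discordant = TRUE),
        mk_rec(qname, 2L, chrom2, pos2, strand = strand2, mapq = mapq,
               mate_chrom = chrom1, mate_pos = pos1, mate_strand = strand1,
               discordant = TRUE))
}

test_that("discordant pairs cluster by chromosome pair and orientation", {
  aln <- do.call(rbind, lapply(1:10, function(i)
    disc_pair(sprintf("q%02d", i), "chr1", 5000L + 20L * i, "+",
              "chr2", 9000L + 25L * i, "-")))
  cl <- collect_discordant_pairs(aln, window = 500L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$pe, 10L)
  expect_equal(cl$ct, "5to3")        # head of chr1 to tail of chr2
  ## two opposite orientation groups at the same locus stay apart
  ## (this is the bidirectional repeat signature)
  aln2 <- rbind(aln, do.call(rbind, lapply(1:8, function(i)
    disc_pair(sprintf("r%02d", i), "chr1", 5100L + 20L * i, "-",
              "chr2", 9100L + 25L * i, "+"))))
  cl2 <- collect_discordant_pairs(aln2, window = 500L)
  expect_equal(nrow(cl2), 2L)
  expect_setequal(cl2$ct, c("5to3", "3to5"))
  ## empty input
  expect_equal(nrow(collect_discordant_pairs(aln[0, ])), 0L)
})

test_that("split reads give exact breakends; microhomology spreads placements", {
  fx <- std_carrier()
  tr <- fx$planted$truth
  sp <- collect_split_reads(fx$aln)
  sp <- sp[order(sp$ct), ]
  j1 <- sp[sp$ct == "5to3", ]   # microhomology h = 2 junction
  expect_equal(j1$pos1_hi, tr$bpA)                     # right-most placement
  expect_equal(j1$pos1_hi - j1$pos1_lo, 2L)            # spans the homology
  expect_equal(j1$pos2_hi - j1$pos2_lo, 2L)
  j2 <- sp[sp$ct == "3to5", ]   # blunt-side coordinates are unique
  expect_equal(j2$pos1_lo, j2$pos1_hi)
  expect_equal(j2$pos1_lo, tr$tail_start[["chrA"]])
  expect_equal(j2$pos2_lo, tr$bpB)
})

test_that("caller equals the truth-table brute-force oracle", {
  for (fx in list(std_carrier(), hh_carrier())) {
    pl <- fx$planted
    calls <- call_breakends_from_aln(fx$aln)
    jt <- rtdetect:::junction_table(calls)
    expect_equal(nrow(jt), 2L)
    reads <- annotate_fragments(fx$reads, pl)
    support <- oracle_junction_support(fx)
    for (der in names(rtdetect:::derived_maps(pl))) {
      mp <- rtdetect:::derived_maps(pl)[[der]]
      jrow <- jt[jt$ct == mp$ct, ]
      expect_equal(jrow$sr, support[[mp$ct]]$sr)
      expect_equal(jrow$pe, support[[mp$ct]]$pe)
      js <- mp$jspec
      p1 <- js$end_x; p2 <- js$start_y
      if (js$chrom_x > js$chrom_y) { tmp <- p1; p1 <- p2; p2 <- tmp }
      expect_lte(abs(jrow$pos1 - p1), mp$h)
      expect_lte(abs(jrow$pos2 - p2), mp$h)
    }
    ## error-free: PRECISE, PASS, SRQ = 1
    expect_true(all(jt$precise))
    expect_true(all(jt$filter == "PASS"))
    expect_true(all(abs(jt$srq - 1) < 1e-9))
  }
})

test_that("three low-MAPQ discordant pairs give one imprecise LowQual call", {
  aln <- do.call(rbind, lapply(1:3, function(i)
    disc_pair(sprintf("q%d", i), "chr1", 5000L + 30L * i, "+",
              "chr2", 9000L + 30L * i, "-", mapq = 12L)))
  calls <- call_breakends_from_aln(aln)
  jt <- rtdetect:::junction_table(calls)
  expect_equal(nrow(jt), 1L)
  expect_equal(jt$pe, 3L)
  expect_equal(jt$sr, 0L)
  expect_equal(jt$mapq, 12L)
  expect_false(jt$precise)
  expect_equal(jt$filter, "LowQual")
  ## empty evidence -> empty call list
  expect_equal(nrow(call_breakends_from_aln(aln[0, ])), 0L)
})

test_that("PASS/LowQual is a pure, monotone function of PE, SR and MAPQ", {
  set.seed(1)
  pe <- sample(0:10, 200, TRUE); sr <- sample(0:10, 200, TRUE)
  mapq <- sample(0:60, 200, TRUE)
  st <- filter_status(pe, sr, mapq)
  expect_identical(st, ifelse((pe >= 3 | sr >= 3) & mapq > 20,
                              "PASS", "LowQual"))
  ## adding support never demotes a PASS
  st2 <- filter_status(pe + sample(0:5, 200, TRUE),
                       sr + sample(0:5, 200, TRUE), mapq)
  expect_true(all(!(st == "PASS" & st2 == "LowQual")))
})

test_that("both breakend records of a junction exist and share CT", {
  calls <- call_breakends_from_aln(std_carrier()$aln)
  expect_true(all(calls$mate_id %in% calls$id))
  m <- match(calls$mate_id, calls$id)
  expect_identical(calls$ct, calls$ct[m])
  expect_identical(calls$chrom, calls$chrom2[m])
  expect_identical(calls$pos, calls$pos2[m])
})

test_that("VCF round-trips field-identically and enforces invariants", {
  calls <- synthetic_calls(25, seed = 2)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf(path)
  for (col in c("id", "mate_id", "chrom", "pos", "pos_alt", "chrom2", "pos2",
                "pos2_alt", "ct", "pe", "sr", "mapq", "precise", "filter"))
    expect_identical(back[[col]], calls[[col]], label = col)
  expect_equal(back$srq, calls$srq, tolerance = 1e-6)
  ## REF bases come from the genome when supplied
  g <- make_reference(c(chr1 = 1000L), seed = 1)
  one <- synthetic_calls(1, seed = 3)
  one$chrom <- "chr1"; one$pos <- 17L
  write_vcf(one[1, ], path, genome = g)
  expect_match(readLines(path)[length(readLines(path))],
               paste0("\t", substr(g$seq[[1]], 17, 17), "\t"))
})

test_that("reader understands caller-dialect records and demotes bad PRECISE flags", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr2\t4983988\tBND0a\tN\tN]chr4:81209353]\t.\tPASS\tSVTYPE=BND;PRECISE;CHR2=chr4;POS2=81209353;CT=5to5;PE=28;SR=14;MAPQ=60;SRQ=0.95;XINFO=7",
    "chr5\t100\tBND1a\tN\tN[chr6:200[\t.\tPASS\tSVTYPE=BND;PRECISE;CHR2=chr6;POS2=200;CT=5to3;PE=4;SR=0;MAPQ=60",
    "chr5\t300\tBND2a\tN\tN\t.\tPASS\tSVTYPE=BND;PRECISE;SR=2;MAPQ=60"),
    path)
  expect_warning(expect_warning(v <- read_vcf(path), "PRECISE"),
                 "partner")
  expect_equal(nrow(v), 2L)
  expect_equal(v$ct[1], "5to5")
  expect_equal(v$pe[1], 28L)
  expect_equal(v$srq[1], 0.95)
  expect_true(v$precise[1])
  expect_match(v$info_extra[1], "XINFO=7")   # unknown keys preserved
  expect_false(v$precise[2])                 # SR = 0 demoted
  ## malformed record errors with a line number
  writeLines(c("##fileformat=VCFv4.2", "#CHROM", "chr1\t1\tx"), path)
  expect_error(read_vcf(path), "line 3")
})
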