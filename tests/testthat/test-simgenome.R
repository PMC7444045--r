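test_that("make_reference produces requested chromosomes, reproducibly", {
  g1 <- make_reference(c(c1 = 20000L, c2 = 15000L), seed = 7)
  expect_equal(unname(nchar(g1$seq)), c(20000L, 15000L))
  expect_named(g1$seq, c("c1", "c2"))
  expect_true(all(strsplit(g1$seq[[1]], "")[[1]] %in% c("A", "C", "G", "T")))
  g2 <- make_reference(c(c1 = 20000L, c2 = 15000L), seed = 7)
  expect_identical(g1$seq, g2$seq)
  g3 <- make_reference(c(c1 = 20000L, c2 = 15000L), seed = 8)
  expect_false(identical(g1$seq, g3$seq))
  expect_error(make_reference(c(20000, 15000)), "named")
})

test_that("repeat copies are planted at the stated divergence", {
  pls <- data.frame(chrom = rep(c("c1", "c2"), each = 3),
                    start = c(1000, 5000, 9000, 800, 4000, 8000))
  rs <- repeat_spec(pls, divergence = 0.05, seed = 3)
  g <- make_reference(c(c1 = 20000L, c2 = 15000L), repeats = rs, seed = 1)
  expect_equal(nrow(g$repeats), 6L)
  ## count mismatches of each emitted copy against the monomer directly
  mism <- vapply(seq_len(6), function(i) {
    b <- g$repeats[i, ]
    count_mismatches(substr(g$seq[[b$chrom]], b$start, b$end), rs$monomer)
  }, numeric(1))
  expect_true(mean(mism) <= 2 * 0.05 * 250)
  expect_true(all(mism < 50))
  ## out-of-bounds placement errors with a named location
  bad <- repeat_spec(data.frame(chrom = "c1", start = 19900), seed = 3)
  expect_error(make_reference(c(c1 = 20000L), repeats = bad, seed = 1),
               "c1:19900")
})

test_that("blunt no-loss planting is pure segment arithmetic", {
  g <- make_reference(c(chrA = 200000L, chrB = 150000L), seed = 7)
  tr <- rt_truth("chrA", "chrB", 100000, 50000, "HT/TH")
  pl <- plant_translocation(g, tr)
  expect_setequal(unname(nchar(pl$derived)), c(150000L, 200000L))
  ## derived sequences are exact concatenations of retained segments
  expect_identical(pl$derived[[1]],
                   paste0(substr(g$seq[["chrA"]], 1, 100000),
                          substr(g$seq[["chrB"]], 50001, 150000)))
})

test_that("derived chromosomes obey the balanced-RT conservation identity", {
  for (seed in 1:12) {
    pl <- random_planted(seed)
    tr <- pl$truth
    ins_total <- sum(vapply(tr$junctions, function(j) j$ins_len, numeric(1)))
    expect_identical(
      sum(nchar(pl$derived)),
      as.integer(tr$lenA + tr$lenB - sum(tr$gap) + ins_total))
    ## gap = reported loss + homology accounted on that chromosome
    expect_equal(sum(tr$gap), sum(tr$loss) +
                   sum(vapply(tr$junctions, function(j) j$h, numeric(1))))
  }
})

test_that("every base outside the gaps appears exactly once across the derived pair", {
  pl <- random_planted(99, len_a = 8000L, len_b = 6000L)
  tr <- pl$truth
  seqs <- pl$genome$seq
  ## reconstruct the four retained segments independently from truth
  ## coordinates and account for each
  headA <- substr(seqs[[tr$chrA]], 1, tr$bpA)
  tailA <- substr(seqs[[tr$chrA]], tr$tail_start[[tr$chrA]], nchar(seqs[[tr$chrA]]))
  headB <- substr(seqs[[tr$chrB]], 1, tr$bpB)
  tailB <- substr(seqs[[tr$chrB]], tr$tail_start[[tr$chrB]], nchar(seqs[[tr$chrB]]))
  der_all <- paste0(pl$derived[[1]], pl$derived[[2]])
  if (tr$connection == "HT/TH") {
    expect_identical(der_all, paste0(headA, tr$junctions[[1]]$insertion, tailB,
                                     headB, tr$junctions[[2]]$insertion, tailA))
  } else {
    expect_identical(der_all, paste0(headA, tr$junctions[[1]]$insertion,
                                     revcomp(headB),
                                     revcomp(tailA), tr$junctions[[2]]$insertion,
                                     tailB))
  }
})

test_that("planted microhomology is literally present in both flanks", {
  pl <- std_carrier()$planted
  tr <- pl$truth
  j1 <- tr$junctions[[1]]
  expect_equal(j1$h, 2L)
  ## the 2 bases preceding the retained tail of chrB equal the last 2
  ## retained bases of the chrA head
  seqs <- pl$genome$seq
  expect_identical(
    substr(seqs[["chrB"]], tr$tail_start[["chrB"]] - 2L, tr$tail_start[["chrB"]] - 1L),
    substr(seqs[["chrA"]], tr$bpA - 1L, tr$bpA))
})

test_that("simulated coverage, read fidelity and junction flags are as configured", {
  fx <- std_carrier()
  reads <- fx$reads
  rl <- reads$config$read_len
  total_read_bases <- 2 * rl * nrow(reads$frags)
  genome_bases <- sum(nchar(fx$genome$seq))
  cov <- total_read_bases / genome_bases
  expect_gt(cov, 27); expect_lt(cov, 33)
  ## error rate 0: every read is an exact substring of its haplotype
  haps <- carrier_haplotypes(fx$planted)
  idx <- seq(1, nrow(reads$frags), by = 500)
  for (i in idx) {
    fr <- reads$frags[i, ]
    src <- haps[[fr$hap]][[fr$contig]]
    expect_identical(fr$r1, substr(src, fr$start, fr$start + rl - 1L))
    expect_identical(fr$r2, revcomp(substr(src, fr$end - rl + 1L, fr$end)))
  }
  ## junction flags follow from coordinates alone
  ann <- annotate_fragments(reads, fx$planted)$frags
  mp <- rtdetect:::derived_maps(fx$planted)
  der1 <- names(mp)[1]
  j <- mp[[der1]]$x_len
  on_der <- ann$contig == der1
  expect_identical(ann$spans_junction[on_der],
                   ann$start[on_der] <= j & ann$end[on_der] >= j + mp[[der1]]$g + 1L)
  expect_true(any(ann$r1_crosses | ann$r2_crosses))
})

test_that("fragment subsampling is exact, seeded and mate-preserving", {
  fx <- std_carrier()
  expect_identical(subsample_reads(fx$reads, 1), fx$reads)
  s1 <- subsample_reads(fx$reads, 0.5, seed = 4)
  expect_equal(nrow(s1$frags), round(0.5 * nrow(fx$reads$frags)), tolerance = 0,
               ignore_attr = TRUE)
  s2 <- subsample_reads(fx$reads, 0.5, seed = 4)
  expect_identical(s1$frags$qname, s2$frags$qname)
  s3 <- subsample_reads(fx$reads, 0.5, seed = 5)
  expect_false(identical(s1$frags$qname, s3$frags$qname))
  expect_error(subsample_reads(fx$reads, 0), "fraction")
})

test_that("truth alignments place reads exactly and flag pairs correctly", {
  fx <- std_carrier()
  aln <- fx$aln
  seqs <- c(fx$planted$genome$seq)
  ## aligned blocks of plain records match the reference exactly
  plain <- aln[aln$m == nchar(aln$seq) & !aln$is_supp, ]
  idx <- seq(1, nrow(plain), by = 700)
  for (i in idx) {
    r <- plain[i, ]
    expect_identical(r$seq, substr(seqs[[r$chrom]], r$pos, r$end))
  }
  ## a proper pair is never discordant
  expect_false(any(aln$proper & aln$discordant, na.rm = TRUE))
  ## split records reference a consistent partner
  spl <- aln[!is.na(aln$sa_chrom) & !aln$is_supp, ]
  sup <- aln[aln$is_supp, ]
  m <- match(paste(spl$qname, spl$mate), paste(sup$qname, sup$mate))
  expect_false(anyNA(m))
  expect_identical(spl$sa_chrom, sup$chrom[m])
  expect_identical(spl$sa_pos, sup$pos[m])
})

test_that("a 40/110 junction-crossing read splits at the planted breakpoints", {
  g <- make_reference(c(chrA = 5000L, chrB = 4000L), seed = 2)
  tr <- rt_truth("chrA", "chrB", 2000, 1500, "HT/TH")
  pl <- plant_translocation(g, tr)
  ## one fragment whose read 1 covers the junction with a 110/40 split
  reads <- structure(list(
    frags = data.frame(hap = 2L, contig = names(pl$derived)[1],
                       start = 1891L, end = 2200L, qname = "frag0000001",
                       r1 = substr(pl$derived[[1]], 1891, 2040),
                       r2 = revcomp(substr(pl$derived[[1]], 2051, 2200)),
                       stringsAsFactors = FALSE),
    config = sim_config(seed = 1)), class = "rt_reads")
  aln <- emit_truth_alignments(reads, pl$genome, pl)
  r1 <- aln[aln$mate == 1L, ]
  pri <- r1[!r1$is_supp, ]; sup <- r1[r1$is_supp, ]
  expect_identical(pri$cigar, "110M40S")
  expect_identical(pri$chrom, "chrA")
  expect_identical(pri$end, 2000L)          # breakpoint on chrA
  expect_identical(sup$cigar, "110S40M")
  expect_identical(sup$chrom, "chrB")
  expect_identical(sup$pos, 1501L)          # retained tail start on chrB
  ## pair straddling without crossing: both mates plain, discordant
  r2 <- aln[aln$mate == 2L, ]
  expect_identical(r2$chrom, "chrB")
  expect_true(all(aln$discordant[!aln$is_supp]))
})
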