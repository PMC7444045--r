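test_that("the junction consensus equals the derived-chromosome sequence", {
  fx <- std_carrier()
  sp <- collect_split_reads(fx$aln)
  der1 <- fx$planted$derived[[1]]
  for (i in seq_len(nrow(sp))) {
    grp <- sp[i, , drop = FALSE]
    cons <- assemble_junction_consensus(grp$members[[1]], grp)
    expect_equal(cons$srq, 1)
    expect_equal(cons$disagreement, 0)
    expect_gte(nchar(cons$seq), 150L)
    ## error-free consensus is an exact substring of a derived
    ## chromosome (in one of the two junction orientations)
    found <- any(vapply(fx$planted$derived, function(d)
      grepl(cons$seq, d, fixed = TRUE) ||
        grepl(cons$seq, revcomp(d), fixed = TRUE), logical(1)))
    expect_true(found)
  }
  ## single read: consensus is that read
  one <- sp[1, , drop = FALSE]
  m1 <- one$members[[1]][1, , drop = FALSE]
  cons1 <- assemble_junction_consensus(m1, one)
  expect_equal(nchar(cons1$seq), 150L)
  expect_equal(cons1$srq, 1)
})

test_that("majority vote absorbs 1% sequencing error", {
  g <- make_reference(c(chrA = 30000L, chrB = 20000L), seed = 17)
  tr <- rt_truth("chrA", "chrB", 15000, 10000, "HT/TH",
                 jun1 = junction_arch("MICROHOMOLOGY", h = 4),
                 loss = c(3, 0))
  pl <- plant_translocation(g, tr)
  reads <- simulate_read_pairs(carrier_haplotypes(pl),
                               sim_config(coverage = 30, error_rate = 0.01,
                                          seed = 8))
  aln <- emit_truth_alignments(reads, pl$genome, pl)
  sp <- collect_split_reads(aln)
  grp <- sp[sp$ct == "5to3", , drop = FALSE]
  expect_gte(grp$sr, 10L)
  cons <- assemble_junction_consensus(grp$members[[1]], grp)
  expect_lt(cons$disagreement, 0.05)
  ch <- characterize_junction(cons, pl$genome, grp)
  expect_equal(ch$type, "MICROHOMOLOGY")
  expect_equal(ch$h, 4L)
})

test_that("characterization agrees with a brute-force placement oracle", {
  ## small instances: the oracle enumerates every split of the junction
  ## window against both extended flanks
  for (seed in c(3, 8, 21, 34, 55)) {
    pl <- random_planted(seed, len_a = 2000L, len_b = 1600L)
    tr <- pl$truth
    for (jn in 1:2) {
      j <- tr$junctions[[jn]]
      js <- j$jspec
      W <- 60L
      cons_seq <- paste0(rtdetect:::x_flank(pl$genome$seq, js, W), j$insertion,
                         rtdetect:::y_flank(pl$genome$seq, js, W))
      ## oracle: maximal prefix/suffix agreement against the reference
      flank1 <- paste0(rtdetect:::x_flank(pl$genome$seq, js, W),
                       rtdetect:::x_cont(pl$genome$seq, js, W))
      n <- nchar(cons_seq)
      L <- 0L
      while (L < n && L < nchar(flank1) &&
             substr(cons_seq, L + 1, L + 1) == substr(flank1, L + 1, L + 1))
        L <- L + 1L
      flank2 <- paste0(rtdetect:::y_prec(pl$genome$seq, js, W),
                       rtdetect:::y_flank(pl$genome$seq, js, W))
      R <- 0L
      while (R < n && R < nchar(flank2) &&
             substr(cons_seq, n - R, n - R) ==
             substr(flank2, nchar(flank2) - R, nchar(flank2) - R))
        R <- R + 1L
      g_or <- n - L - R
      type_or <- if (g_or < 0) "MICROHOMOLOGY" else if (g_or == 0) "BLUNT"
                 else "MICROINSERTION"
      expect_equal(type_or, j$type, label = sprintf("seed %d junction %d", seed, jn))
      if (j$type == "MICROHOMOLOGY") expect_equal(-g_or, j$h)
      if (j$type == "MICROINSERTION")
        expect_equal(substr(cons_seq, L + 1, L + g_or), j$insertion)
    }
  }
})

test_that("planted architectures are recovered exactly through the pipeline", {
  ## parameter recovery at reduced replicate count (the acceptance
  ## suite runs the full set)
  ok <- 0L
  for (seed in 1:12) {
    pl <- random_planted(seed)
    reads <- simulate_read_pairs(carrier_haplotypes(pl),
                                 sim_config(coverage = 30, seed = seed + 70))
    aln <- emit_truth_alignments(reads, pl$genome, pl)
    rec <- recover_architecture(pl, aln)
    expect_true(rec$ok, label = sprintf("seed %d: %s", seed, rec$why))
    ok <- ok + rec$ok
  }
  expect_equal(ok, 12L)
})

test_that("bases lost follow from the retained-segment boundaries", {
  ## printed-coordinate worked examples
  expect_equal(compute_bases_lost(4983988, 4983990),
               list(count = 1L, interval = c(4983989, 4983989)))
  expect_equal(compute_bases_lost(97320431, 97320436),
               list(count = 4L, interval = c(97320432, 97320435)))
  expect_equal(compute_bases_lost(1000, 1001), list(count = 0L, interval = NULL))
  expect_error(compute_bases_lost(1001, 1000), "unbalanced")
})

test_that("derived-chromosome arithmetic reproduces the published pig RTs", {
  ex <- pig_rt_examples()
  jn <- ex$junctions
  der_of <- function(rt) {
    j <- jn[jn$rt == rt, ]
    derive_chromosomes(lapply(1:2, function(i) list(
      chrom1 = j$chrom1[i], pos1 = j$pos1[i], side1 = j$side1[i],
      chrom2 = j$chrom2[i], pos2 = j$pos2[i], side2 = j$side2[i],
      ins_len = j$ins_len[i])), ex$chrom_lengths)
  }
  t24 <- der_of("t2_4")
  expect_equal(t24$total_mb, c(86.2, 196.7))
  expect_equal(t24$seg1_mb, c(5.0, 147.0))
  expect_equal(t24$seg2_mb, c(81.2, 49.7))
  t714 <- der_of("t7_14")
  expect_equal(t714$total_mb, c(210.9, 52.7))
  t116 <- der_of("t1_16")
  expect_equal(t116$total_mb, c(153.7, 200.5))
  expect_equal(t116$seg1_mb, c(97.3, 177.0))
  ## derived sizes relate to parents as the karyotype shows
  expect_equal(t24$vs_parent1, c("shorter", "longer"))
  ## chromosome-length conservation across the pair (losses are < 0.05 Mb)
  expect_equal(sum(t24$total_bp) + 5,   # 3 lost + 2 homology-covered
               sum(ex$chrom_lengths[c("2", "4")]))
})

test_that("megabase reporting rounds half-up at one decimal", {
  expect_equal(rtdetect:::mb(86193341), 86.2)
  expect_equal(rtdetect:::mb(146952005), 147.0)
  expect_equal(rtdetect:::mb(50000), 0.1)   # 0.05 rounds up
  expect_equal(rtdetect:::round_half_up(0.25, 1), 0.3)
  expect_equal(rtdetect:::round_half_up(0.24, 1), 0.2)
})

test_that("gene context classifies exon, intron and intergenic breakpoints", {
  track <- data.frame(
    chrom = "c1",
    start = c(100, 150, 400, 1000, 1100),
    end   = c(800, 250, 500, 1500, 1200),
    strand = "+",
    type = c("gene", "exon", "exon", "gene", "exon"),
    id = c("G1", "G1", "G1", "G2", "G2"), stringsAsFactors = FALSE)
  expect_equal(gene_context("c1", 200, track)$class, "EXON")
  expect_equal(gene_context("c1", 300, track)$class, "INTRON")
  expect_equal(gene_context("c1", 300, track)$ids, "G1")
  expect_equal(gene_context("c1", 900, track)$class, "INTERGENIC")
  expect_equal(gene_context("c2", 200, track)$class, "INTERGENIC")
})

test_that("the published eight breakpoints annotate as printed", {
  ex <- pig_rt_examples()
  ## synthetic gene track built around the published breakpoints: the
  ## six disrupted genes (intron or exon) and two intergenic breaks
  gene_at <- function(chrom, pos, id, exonic) {
    g <- data.frame(chrom = chrom, start = pos - 5000, end = pos + 5000,
                    strand = "+", type = "gene", id = id)
    ex_start <- if (exonic) pos - 50 else pos + 1000
    rbind(g, data.frame(chrom = chrom, start = ex_start, end = ex_start + 200,
                        strand = "+", type = "exon", id = id))
  }
  track <- rbind(
    gene_at("2", 4983988, "ENSSSCG00000032003", exonic = FALSE),
    gene_at("4", 81209353, "C1orf112", exonic = TRUE),
    gene_at("6", 27901326, "SLC9A5", exonic = FALSE),
    gene_at("8", 1266615, "ZFYVE28", exonic = FALSE),
    gene_at("14", 49733352, "CABIN1", exonic = FALSE),
    gene_at("16", 23532204, "EGFLAM", exonic = FALSE))
  expected <- list(
    list("2", 4983988, "INTRON", "ENSSSCG00000032003"),
    list("4", 81209353, "EXON", "C1orf112"),
    list("6", 27901326, "INTRON", "SLC9A5"),
    list("8", 1266615, "INTRON", "ZFYVE28"),
    list("7", 118889969, "INTERGENIC", NULL),
    list("14", 49733352, "INTRON", "CABIN1"),
    list("1", 97320431, "INTERGENIC", NULL),
    list("16", 23532204, "INTRON", "EGFLAM"))
  for (e in expected) {
    ctx <- gene_context(e[[1]], e[[2]], track)
    expect_equal(ctx$class, e[[3]], label = paste(e[[1]], e[[2]]))
    if (!is.null(e[[4]])) expect_true(e[[4]] %in% ctx$ids)
  }
})

test_that("gene tracks round-trip through GFF3", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttoy\tgene\t100\t800\t.\t+\t.\tID=gene:G1;Name=G1",
    "c1\ttoy\texon\t150\t250\t.\t+\t.\tID=exon:G1.1;Parent=gene:G1;Name=G1",
    "c1\ttoy\tmRNA\t100\t800\t.\t+\t.\tID=tx:G1.t1;Parent=gene:G1"), path)
  track <- read_gene_track(path)
  expect_equal(nrow(track), 2L)         # mRNA dropped
  expect_setequal(track$type, c("gene", "exon"))
  expect_equal(gene_context("c1", 200, track)$class, "EXON")
})
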