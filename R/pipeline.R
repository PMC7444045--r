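## End-to-end orchestration: blind screen, targeted (unblinded)
## chromosome-pair search, and the coverage-titration experiment.

#' Run the blind RT screen on a set of alignments
#'
#' Full pipeline under the strict tier: breakend calling, basic
#' filtering (PASS + PRECISE), strict filtering, reciprocal-pair
#' matching within the pairing window, breakpoint-pattern
#' classification of all four breakends and the final RT decision.
#' Chromosomes named in `exclude` (unplaced contigs, mitochondrion)
#' are removed before calling.
#'
#' @param aln `rt_aln` alignment records.
#' @param config List merged over defaults: `coverage`, `sample`,
#'   `pair_window`, `exclude` (character vector of chromosome names),
#'   `min_support`, `min_mapq`, plus [classify_config()] fields under
#'   `classify` and [filter_config()] fields under `filter`.
#' @param repeats Optional repeat annotation for classification.
#' @param cohort Optional list of `bnd_calls` from other samples for
#'   the recurrence check.
#' @return List of class `rt_run_report`: stage counts (raw calls,
#'   basic-filtered, strict-filtered, reciprocal pairs, confirmed RTs),
#'   the call sets, candidate pairs with verdicts and per-breakend
#'   classifications.
#' @export
run_blind_screen <- function(aln, config = list(), repeats = NULL,
                             cohort = list()) {
  cfg <- modify_defaults(list(coverage = 30, sample = "S1",
                              pair_window = 100L,
                              exclude = c("chrM", "MT"),
                              min_support = 3L, min_mapq = 20L), config)
  fcfg <- do.call(filter_config,
                  c(list(coverage = cfg$coverage,
                         pair_window = cfg$pair_window),
                    cfg$filter %||% list()))
  ccfg <- do.call(classify_config,
                  c(list(coverage = cfg$coverage), cfg$classify %||% list()))
  aln <- aln[!(aln$chrom %in% cfg$exclude), , drop = FALSE]
  calls <- call_breakends_from_aln(aln, params = list(
    min_support = cfg$min_support, min_mapq = cfg$min_mapq,
    sample = cfg$sample))
  bas <- basic_filter(calls)
  str <- strict_filter(bas, fcfg)
  pairs <- match_reciprocal_pairs(str, window = fcfg$pair_window)
  classifications <- list()
  verdicts <- character(nrow(pairs))
  reasons <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cls <- classify_pair_breakends(pairs[i, ], aln, ccfg, repeats)
    rec <- recurrence_check(list(chrom1 = pairs$j1_chrom1[i],
                                 pos1 = pairs$j1_pos1[i],
                                 chrom2 = pairs$j1_chrom2[i],
                                 pos2 = pairs$j1_pos2[i]),
                            cohort, window = fcfg$pair_window)
    d <- decide_rt(cls, rec)
    classifications[[i]] <- cls
    verdicts[i] <- d$verdict
    reasons[i] <- paste(d$reasons, collapse = "; ")
  }
  pairs$verdict <- verdicts
  pairs$reasons <- reasons
  structure(list(
    sample = cfg$sample,
    counts = c(raw = nrow(junction_table(calls)),
               basic = nrow(junction_table(bas)),
               strict = nrow(junction_table(str)),
               pairs = nrow(pairs),
               confirmed = sum(verdicts == "CONFIRMED_RT")),
    calls = calls, basic = bas, strict = str, pairs = pairs,
    classifications = classifications,
    config = cfg), class = "rt_run_report")
}

#' Targeted (unblinded) search of one chromosome pair
#'
#' Restricts the raw, unfiltered call set to the named chromosome pair
#' and applies only the reciprocal connection-type matching and the
#' pairing window, reporting all candidate pairs with their full
#' evidence so a relaxed policy (or a human) can adjudicate. This is
#' the rescue mode for RTs whose breakpoints sit in repetitive
#' sequence and therefore fail the strict blind screen.
#'
#' @param calls Raw `bnd_calls`.
#' @param chrom_pair Character vector of the two chromosome names.
#' @param window Pairing window (bp).
#' @return `rt_pairs` data frame (possibly empty, with a warning if the
#'   chromosomes are absent from the call set).
#' @export
run_targeted_search <- function(calls, chrom_pair, window = 100L) {
  stopifnot(length(chrom_pair) == 2L)
  cp <- sort(chrom_pair)
  sel <- calls[(calls$chrom == cp[1] & calls$chrom2 == cp[2]) |
               (calls$chrom == cp[2] & calls$chrom2 == cp[1]), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning(sprintf("no calls involve chromosome pair %s/%s", cp[1], cp[2]))
    return(match_reciprocal_pairs(empty_bnd_calls(), window))
  }
  match_reciprocal_pairs(sel, window = window)
}

#' Coverage-titration experiment
#'
#' For each replicate, simulates a carrier at full coverage, then for
#' each subsampling fraction recalls and refilters under each tier and
#' records whether the planted RT is detected (pair surviving filter +
#' matching), called but filtered away, or not called at all.
#'
#' @param planted `rt_planted` carrier.
#' @param config `sim_config()` for the full-coverage run.
#' @param fractions Subsampling fractions of fragments.
#' @param tiers Subset of `c("strict", "relaxed")`.
#' @param replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param truth_tol Breakpoint tolerance (bp) for calling a detection.
#' @return Data frame of class `rt_titration`: one row per (replicate,
#'   fraction, tier) with `outcome` in DETECTED / CALLED_BUT_FILTERED /
#'   NOT_CALLED.
#' @export
coverage_titration <- function(planted, config = sim_config(),
                               fractions = c(0.3, 0.5, 0.6, 1.0),
                               tiers = c("strict", "relaxed"),
                               replicates = 10L, seed = 1L,
                               truth_tol = 25L) {
  tr <- planted$truth
  haps <- carrier_haplotypes(planted)
  rows <- list()
  for (r in seq_len(replicates)) {
    cfg <- config; cfg$seed <- as.integer(seed + 101L * r)
    reads <- simulate_read_pairs(haps, cfg)
    for (f in fractions) {
      sub <- subsample_reads(reads, f, seed = cfg$seed + 13L)
      aln <- emit_truth_alignments(sub, planted$genome, planted)
      calls <- call_breakends_from_aln(aln)
      eff_cov <- config$coverage * f
      fcfg <- filter_config(coverage = eff_cov)
      raw_hit <- truth_called(calls, tr, truth_tol)
      for (tier in tiers) {
        kept <- if (tier == "strict") strict_filter(basic_filter(calls), fcfg)
                else relaxed_filter(calls, fcfg)
        pairs <- match_reciprocal_pairs(kept, window = fcfg$pair_window)
        detected <- truth_pair_present(pairs, tr, truth_tol)
        outcome <- if (detected) "DETECTED"
                   else if (raw_hit) "CALLED_BUT_FILTERED" else "NOT_CALLED"
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, fraction = f, coverage = eff_cov, tier = tier,
          outcome = outcome, seed = cfg$seed, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("rt_titration", "data.frame")
  res
}

## Are both truth junctions present in the raw call set?
truth_called <- function(calls, tr, tol = 25L) {
  jt <- junction_table(calls)
  all(vapply(tr$junctions, function(j) {
    js <- j$jspec
    p1 <- js$end_x; p2 <- js$start_y
    ch <- sort(c(js$chrom_x, js$chrom_y))
    if (js$chrom_x > js$chrom_y) { tmp <- p1; p1 <- p2; p2 <- tmp }
    any(jt$chrom1 == ch[1] & jt$chrom2 == ch[2] &
        abs(jt$pos1 - p1) <= tol & abs(jt$pos2 - p2) <= tol)
  }, logical(1)))
}

## Is a reciprocal pair matching the planted truth present?
truth_pair_present <- function(pairs, tr, tol = 25L) {
  if (nrow(pairs) == 0L) return(FALSE)
  hit_j <- function(j, chrom1, pos1, chrom2, pos2) {
    js <- j$jspec
    p1 <- js$end_x; p2 <- js$start_y
    c1 <- js$chrom_x; c2 <- js$chrom_y
    if (c1 > c2) { tmp <- p1; p1 <- p2; p2 <- tmp; tm <- c1; c1 <- c2; c2 <- tm }
    chrom1 == c1 & chrom2 == c2 & abs(pos1 - p1) <= tol & abs(pos2 - p2) <= tol
  }
  any(vapply(seq_len(nrow(pairs)), function(i) {
    (hit_j(tr$junctions[[1]], pairs$j1_chrom1[i], pairs$j1_pos1[i],
           pairs$j1_chrom2[i], pairs$j1_pos2[i]) &
     hit_j(tr$junctions[[2]], pairs$j2_chrom1[i], pairs$j2_pos1[i],
           pairs$j2_chrom2[i], pairs$j2_pos2[i])) |
    (hit_j(tr$junctions[[2]], pairs$j1_chrom1[i], pairs$j1_pos1[i],
           pairs$j1_chrom2[i], pairs$j1_pos2[i]) &
     hit_j(tr$junctions[[1]], pairs$j2_chrom1[i], pairs$j2_pos1[i],
           pairs$j2_chrom2[i], pairs$j2_pos2[i]))
  }, logical(1)))
}

#' Recover a planted junction architecture through the full pipeline
#'
#' Calls breakends from the alignments, matches the reciprocal pair,
#' reconstructs both junctions at base-pair resolution and compares
#' type, microhomology length, insertion sequence and per-chromosome
#' lost-base counts against the planted truth. Insertions are compared
#' up to reverse complement because the characterization orients every
#' junction with the lexicographically first chromosome as its left
#' flank, which may be the opposite of the orientation the derived
#' chromosome was written in.
#'
#' @param planted `rt_planted` carrier.
#' @param aln `rt_aln` truth alignments of that carrier.
#' @param pair_window Reciprocal pairing window (bp).
#' @return List with `ok` (logical) and `why` (diagnostic string).
#' @export
recover_architecture <- function(planted, aln, pair_window = 100L) {
  tr <- planted$truth
  fail <- function(why) list(ok = FALSE, why = why)
  calls <- call_breakends_from_aln(aln)
  pairs <- match_reciprocal_pairs(basic_filter(calls), window = pair_window)
  if (!truth_pair_present(pairs, tr)) return(fail("truth pair not matched"))
  pair <- pairs[1, ]
  rep <- junction_report(pair, aln, planted$genome)
  if (!all(vapply(rep$junctions, function(x) x$type != "UNRESOLVED",
                  logical(1))))
    return(fail("junction unresolved"))
  for (jt in tr$junctions) {
    got <- Filter(function(x) x$ct == jt$ct, rep$junctions)
    if (length(got) == 0L) return(fail(sprintf("no junction with CT %s", jt$ct)))
    got <- got[[1]]
    if (got$type != jt$type)
      return(fail(sprintf("%s: type %s != %s", jt$ct, got$type, jt$type)))
    if (got$h != jt$h)
      return(fail(sprintf("%s: h %d != %d", jt$ct, got$h, jt$h)))
    if (jt$type == "MICROINSERTION" &&
        !(got$insertion %in% c(jt$insertion, revcomp(jt$insertion))))
      return(fail(sprintf("%s: insertion mismatch", jt$ct)))
  }
  for (ch in c(tr$chrA, tr$chrB)) {
    want <- tr$loss[[ch]]
    got <- if (!is.null(rep$lost[[ch]])) rep$lost[[ch]]$count else NA_integer_
    if (is.na(got) || got != want)
      return(fail(sprintf("%s: lost %s != %d", ch, got, want)))
  }
  list(ok = TRUE, why = "")
}

#' Serialize a run report or titration grid as TSV
#'
#' @param x An `rt_run_report` or `rt_titration`.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "rt_run_report")) {
    df <- data.frame(sample = x$sample, t(x$counts), stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "rt_titration")) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(x)) {
    drop <- vapply(x, is.list, logical(1))
    write.table(x[, !drop, drop = FALSE], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else stop("unsupported report object")
  invisible(path)
}

#' @export
print.rt_run_report <- function(x, ...) {
  cat(sprintf("RT blind screen [%s]\n", x$sample))
  cat(sprintf("  junctions: raw %d -> basic %d -> strict %d; pairs %d; confirmed RTs %d\n",
              x$counts["raw"], x$counts["basic"], x$counts["strict"],
              x$counts["pairs"], x$counts["confirmed"]))
  invisible(x)
}

#' Detection summary of a titration grid
#' @param x `rt_titration` result.
#' @export
titration_summary <- function(x) {
  agg <- aggregate(list(detected = x$outcome == "DETECTED"),
                   by = list(fraction = x$fraction, coverage = x$coverage,
                             tier = x$tier), FUN = mean)
  agg[order(agg$tier, agg$fraction), , drop = FALSE]
}
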