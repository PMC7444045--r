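## Automated breakpoint-pattern classification. At a genuine RT
## breakend the locus shows normal (concordant, high-MAPQ) reads from
## the intact homologue on both sides, plus discordant pairs in a
## single orientation and split reads from the derived chromosome.
## Repeat-artifact loci instead show either discordant/split evidence
## with the good concordant reads lacking, or overlapping forward and
## reverse discordant pairs in the same area.

#' Classification thresholds
#' @param window Locus window around the breakend (bp; at least a read
#'   length).
#' @param min_depth Minimum mean concordant depth on the intact side
#'   (default: a third of the intended coverage).
#' @param min_disc Minimum discordant pairs per orientation for that
#'   orientation to count as supported.
#' @param min_mapq Mapping quality below which a read does not count as
#'   a good concordant read.
#' @param coverage Intended fold coverage (sets `min_depth` default).
#' @export
classify_config <- function(window = 500L, coverage = 30,
                            min_depth = coverage / 3, min_disc = 3L,
                            min_mapq = 20L, min_dir_overlap = 20L) {
  list(window = as.integer(window), min_depth = min_depth,
       min_disc = as.integer(min_disc), min_mapq = as.integer(min_mapq),
       min_dir_overlap = as.integer(min_dir_overlap))
}

#' Profile the read support around one breakend
#'
#' Counts are computed exactly from records overlapping
#' `[pos - window, pos + window]`: mean per-base concordant depth
#' (proper pairs with MAPQ at or above the threshold) separately on the
#' left and right of the breakend, discordant-pair counts by
#' orientation, split-read count, overlapping repeat annotations.
#'
#' @param aln `rt_aln` records.
#' @param chrom,pos Breakend position.
#' @param side `"head"` or `"tail"`: which side of the breakend the
#'   retained segment lies on. For a head (5') breakend the intact
#'   side is to the right of the breakend, for a tail (3') breakend to
#'   the left.
#' @param config A [classify_config()].
#' @param repeats Repeat annotation data frame (chrom/start/end), or
#'   NULL.
#' @return List of class `locus_profile`.
#' @export
profile_locus <- function(aln, chrom, pos, side = "head",
                          config = classify_config(), repeats = NULL) {
  w <- config$window
  lo <- pos - w; hi <- pos + w
  loc <- aln[!aln$is_supp & aln$chrom == chrom & aln$end >= lo & aln$pos <= hi, ,
             drop = FALSE]
  conc <- loc[!is.na(loc$proper) & loc$proper & loc$mapq >= config$min_mapq, ,
              drop = FALSE]
  depth_in <- function(a, b) {
    if (b < a) return(0)
    ov <- pmin(conc$end, b) - pmax(conc$pos, a) + 1L
    sum(ov[ov > 0]) / (b - a + 1L)
  }
  depth_left <- depth_in(lo, pos - 1L)
  depth_right <- depth_in(pos + 1L, hi)
  disc <- loc[!is.na(loc$discordant) & loc$discordant, , drop = FALSE]
  fwd <- disc[disc$strand == "+", , drop = FALSE]
  rev <- disc[disc$strand == "-", , drop = FALSE]
  disc_fwd <- nrow(fwd)
  disc_rev <- nrow(rev)
  ## overlap of the forward- and reverse-orientation footprints: at a
  ## true RT breakend pair the two orientations abut (forward reads end
  ## at the head breakend, reverse reads start at the tail breakend);
  ## at a repeat artifact they overlap over the repeat copy
  dir_overlap <- if (disc_fwd > 0L && disc_rev > 0L)
    min(max(fwd$end), max(rev$end)) - max(min(fwd$pos), min(rev$pos)) + 1L
  else -Inf
  split_n <- sum(!is.na(loc$sa_chrom))
  rep_ov <- if (is.null(repeats) || nrow(repeats) == 0L) {
    empty_repeat_bed()
  } else {
    repeats[repeats$chrom == chrom & repeats$start <= hi & repeats$end >= lo, ,
            drop = FALSE]
  }
  structure(list(chrom = chrom, pos = pos, side = side, window = w,
                 depth_left = depth_left, depth_right = depth_right,
                 intact_depth = if (side == "head") depth_right else depth_left,
                 disc_fwd = disc_fwd, disc_rev = disc_rev,
                 dir_overlap = dir_overlap,
                 split = split_n, repeats = rep_ov),
            class = "locus_profile")
}

#' Classify a breakend locus profile
#'
#' * `REPEAT_BIDIRECTIONAL`: both discordant orientations supported
#'   with overlapping footprints in the same area (at a genuine RT the
#'   two orientations abut at the two nearby breakends instead of
#'   overlapping).
#' * `REPEAT_ONLY_DISCORDANT`: discordant/split evidence but the good
#'   reads from the intact chromosome are lacking.
#' * `RT_LIKE`: intact-side concordant depth present, at least one
#'   split read, single-orientation discordant support.
#' * `AMBIGUOUS`: anything else.
#'
#' @param profile A [profile_locus()] result.
#' @param config A [classify_config()].
#' @return Character scalar, one of the four pattern labels.
#' @export
classify_breakend <- function(profile, config = classify_config()) {
  both_dir <- profile$disc_fwd >= config$min_disc &&
    profile$disc_rev >= config$min_disc &&
    profile$dir_overlap >= config$min_dir_overlap
  if (both_dir) return("REPEAT_BIDIRECTIONAL")
  evidence <- profile$disc_fwd + profile$disc_rev + profile$split
  if (profile$intact_depth < config$min_depth && evidence >= config$min_disc)
    return("REPEAT_ONLY_DISCORDANT")
  ## discordant orientation facing this breakend: forward reads point
  ## into a head (5') breakend, reverse reads into a tail (3') one
  facing <- if (profile$side == "head") profile$disc_fwd else profile$disc_rev
  if (profile$intact_depth >= config$min_depth && profile$split >= 1L &&
      facing >= config$min_disc)
    return("RT_LIKE")
  "AMBIGUOUS"
}

#' Count cohort samples sharing a breakend locus
#'
#' @param junction A junction-table row (or list) with `chrom1`,
#'   `pos1`, `chrom2`, `pos2`.
#' @param cohort List of `bnd_calls` tables from other samples.
#' @param window Locus match window in bp.
#' @return Number of other samples containing a call whose both
#'   breakends fall within `window` of the candidate's.
#' @export
recurrence_check <- function(junction, cohort, window = 100L) {
  if (length(cohort) == 0L) return(0L)
  n <- 0L
  for (cs in cohort) {
    jt <- junction_table(cs)
    hit <- any(jt$chrom1 == junction$chrom1 & jt$chrom2 == junction$chrom2 &
               abs(jt$pos1 - junction$pos1) <= window &
               abs(jt$pos2 - junction$pos2) <= window)
    if (hit) n <- n + 1L
  }
  n
}

#' Decide whether a candidate pair is a confirmed RT
#'
#' A true RT shows the RT-like pattern at its breakends on both
#' chromosomes involved and is not recurrent across unrelated samples
#' (recurrent inter-chromosomal adjacencies are repeat-driven).
#'
#' @param classifications Character vector of the four breakend
#'   patterns (junction 1 chrom1/chrom2, junction 2 chrom1/chrom2).
#' @param recurrence Cohort recurrence count from [recurrence_check()].
#' @param policy List: `min_rt_like` (default 4 = all four breakends)
#'   and `max_recurrence` (default 0).
#' @return List with `verdict` (CONFIRMED_RT / NON_RT) and `reasons`.
#' @export
decide_rt <- function(classifications, recurrence = 0L,
                      policy = list(min_rt_like = 4L, max_recurrence = 0L)) {
  min_rt <- policy$min_rt_like %||% 4L
  max_rec <- policy$max_recurrence %||% 0L
  n_rt <- sum(classifications == "RT_LIKE")
  reasons <- character(0)
  if (n_rt < min_rt)
    reasons <- c(reasons, sprintf("only %d of %d breakends RT-like (%s)",
                                  n_rt, length(classifications),
                                  paste(classifications, collapse = ",")))
  if (recurrence > max_rec)
    reasons <- c(reasons, sprintf("locus recurrent in %d other sample(s)",
                                  recurrence))
  list(verdict = if (length(reasons)) "NON_RT" else "CONFIRMED_RT",
       reasons = reasons)
}

#' Classify all four breakends of a reciprocal candidate pair
#'
#' @param pair One `rt_pairs` row.
#' @param aln `rt_aln` records.
#' @param config A [classify_config()].
#' @param repeats Optional repeat annotation.
#' @return Character vector of four pattern labels, named by breakend.
#' @export
classify_pair_breakends <- function(pair, aln, config = classify_config(),
                                    repeats = NULL) {
  out <- character(0)
  for (jn in 1:2) {
    pre <- paste0("j", jn, "_")
    sides <- sides_from_ct(pair[[paste0(pre, "ct")]])
    for (k in 1:2) {
      chrom <- pair[[paste0(pre, "chrom", k)]]
      pos <- pair[[paste0(pre, "pos", k)]]
      prof <- profile_locus(aln, chrom, pos, sides[k], config, repeats)
      out[paste0("J", jn, "_", chrom)] <- classify_breakend(prof, config)
    }
  }
  out
}
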