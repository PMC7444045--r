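## Tiered filtering of inter-chromosomal breakend calls and
## reciprocal-pair matching.
##
## basic tier:   PASS filter status and PRECISE (split-read refined).
## strict tier:  maximum mapping quality (MAPQ = 60), at least 10
##               supporting split reads, at most 2 x intended coverage
##               discordant pairs, consensus identity SRQ > 0.9.
##               Applied after the basic tier.
## relaxed tier: suited to lower-coverage samples: PASS or LowQual with
##               at least 5 split reads.

#' Filter configuration for the tiered RT screen
#'
#' @param coverage Intended fold coverage of the sample; the strict
#'   tier's discordant-pair ceiling is `2 * coverage`.
#' @param strict_mapq Required (maximum) mapping quality.
#' @param strict_min_sr Minimum split reads, strict tier.
#' @param strict_min_srq SRQ must exceed this (strict inequality).
#' @param relaxed_min_sr Minimum split reads, relaxed tier.
#' @param relaxed_union_strict If `TRUE`, the relaxed tier is the union
#'   of strict-retained calls and LowQual calls with enough split
#'   reads, instead of the default (PASS or LowQual) with enough split
#'   reads.
#' @param pair_window Reciprocal pairing window in bp: both breakends
#'   on the same chromosome must lie within this distance.
#' @export
filter_config <- function(coverage = 30, strict_mapq = 60L,
                          strict_min_sr = 10L, strict_min_srq = 0.9,
                          relaxed_min_sr = 5L,
                          relaxed_union_strict = FALSE,
                          pair_window = 100L) {
  stopifnot(coverage > 0, strict_min_sr >= 1, relaxed_min_sr >= 1,
            pair_window >= 1)
  list(coverage = coverage, max_pe = 2 * coverage, strict_mapq = strict_mapq,
       strict_min_sr = strict_min_sr, strict_min_srq = strict_min_srq,
       relaxed_min_sr = relaxed_min_sr,
       relaxed_union_strict = relaxed_union_strict,
       pair_window = pair_window)
}

#' Basic filter: keep PASS, PRECISE calls
#' @param calls `bnd_calls`.
#' @export
basic_filter <- function(calls) {
  calls[calls$filter == "PASS" & calls$precise, , drop = FALSE]
}

#' Strict (final) filter
#'
#' Keep calls with MAPQ equal to the maximum, at least
#' `strict_min_sr` split reads, no more than `2 * coverage` discordant
#' pairs and SRQ strictly greater than `strict_min_srq`. Meant to be
#' composed after [basic_filter()].
#' @param calls `bnd_calls`.
#' @param config A [filter_config()].
#' @export
strict_filter <- function(calls, config = filter_config()) {
  keep <- calls$mapq == config$strict_mapq &
    calls$sr >= config$strict_min_sr &
    calls$pe <= config$max_pe &
    !is.na(calls$srq) & calls$srq > config$strict_min_srq
  calls[keep, , drop = FALSE]
}

#' Relaxed filter for lower-coverage samples
#'
#' Calls that failed the caller's quality filter (LowQual instead of
#' PASS) are retained as long as they have at least `relaxed_min_sr`
#' split reads.
#' @param calls `bnd_calls`.
#' @param config A [filter_config()].
#' @export
relaxed_filter <- function(calls, config = filter_config()) {
  if (config$relaxed_union_strict) {
    strict <- strict_filter(basic_filter(calls), config)
    lowq <- calls[calls$filter == "LowQual" & calls$sr >= config$relaxed_min_sr, ,
                  drop = FALSE]
    out <- rbind(strict, lowq)
    out[!duplicated(out$id), , drop = FALSE]
  } else {
    calls[calls$filter %in% c("PASS", "LowQual") &
          calls$sr >= config$relaxed_min_sr, , drop = FALSE]
  }
}

## One row per junction (a junction is represented by two mated BND
## records; deduplicate by junction id, keeping the record whose
## chromosome sorts first so pos1 always refers to chrom1).
junction_table <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(junction = character(0), chrom1 = character(0),
                      pos1 = integer(0), chrom2 = character(0),
                      pos2 = integer(0), ct = character(0), pe = integer(0),
                      sr = integer(0), mapq = integer(0), srq = numeric(0),
                      precise = logical(0), filter = character(0),
                      stringsAsFactors = FALSE))
  first <- calls[calls$chrom < calls$chrom2 |
                 (calls$chrom == calls$chrom2 & calls$pos <= calls$pos2), ,
                 drop = FALSE]
  ## junctions whose both records sort the other way (should not occur,
  ## but keep them rather than lose them)
  missing <- setdiff(unique(calls$junction), unique(first$junction))
  if (length(missing))
    first <- rbind(first, calls[match(missing, calls$junction), , drop = FALSE])
  first <- first[!duplicated(first$junction), , drop = FALSE]
  data.frame(junction = first$junction, chrom1 = first$chrom,
             pos1 = first$pos, pos1_alt = first$pos_alt,
             chrom2 = first$chrom2, pos2 = first$pos2,
             pos2_alt = first$pos2_alt,
             ct = first$ct, pe = first$pe, sr = first$sr, mapq = first$mapq,
             srq = first$srq, precise = first$precise, filter = first$filter,
             stringsAsFactors = FALSE)
}

#' Match reciprocal junction pairs by complementary connection type
#'
#' Enumerates unordered pairs of junctions on the same chromosome pair
#' whose connection types are complementary ({3to3, 5to5} or
#' {3to5, 5to3}) and, when `window` is finite, whose two breakends on
#' each shared chromosome lie within `window` bp of each other. A
#' junction may appear in several pairs; all are reported, sorted by
#' chromosome pair and position.
#'
#' @param calls `bnd_calls` (or a junction table).
#' @param window Pairing window in bp; use `Inf` to apply only the
#'   connection-type test.
#' @return Data frame of class `rt_pairs`, one row per candidate pair
#'   with `j1_*`/`j2_*` columns and a `verdict` initialized to
#'   CANDIDATE.
#' @export
match_reciprocal_pairs <- function(calls, window = 100L) {
  jt <- if (!is.null(calls$junction) && !is.null(calls$chrom1)) calls
        else junction_table(calls)
  out <- list()
  if (nrow(jt) >= 2L) {
    key <- paste(jt$chrom1, jt$chrom2)
    for (kp in unique(key)) {
      g <- jt[key == kp, , drop = FALSE]
      n <- nrow(g)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (g$ct[j] != complementary_ct(g$ct[i])) next
        if (is.finite(window) &&
            (abs(g$pos1[i] - g$pos1[j]) > window ||
             abs(g$pos2[i] - g$pos2[j]) > window)) next
        a <- g[i, , drop = FALSE]; b <- g[j, , drop = FALSE]
        names(a) <- paste0("j1_", names(a)); names(b) <- paste0("j2_", names(b))
        out[[length(out) + 1L]] <- cbind(
          data.frame(chrom1 = g$chrom1[i], chrom2 = g$chrom2[i],
                     stringsAsFactors = FALSE), a, b)
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom1 = character(0), chrom2 = character(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$chrom1, res$chrom2, res$j1_pos1, res$j2_pos1), ,
               drop = FALSE]
  }
  res$verdict <- rep("CANDIDATE", nrow(res))
  rownames(res) <- NULL
  class(res) <- c("rt_pairs", "data.frame")
  res
}
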