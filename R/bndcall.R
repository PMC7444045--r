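## Inter-chromosomal breakend (BND) calling from discordant read pairs
## and split reads.
##
## Connection-type (CT) dialect used throughout the package, with
## "first" the lexicographically smaller chromosome name:
##   3to3 joins the two tails (3' ends), 5to5 the two heads,
##   3to5 tail-of-first to head-of-second, 5to3 head-of-first to
##   tail-of-second.
## A record whose aligned segment ends at the breakend (soft clip on
## the reference-right side) supports a head (5') breakend; a clip on
## the reference-left side supports a tail (3') breakend.

ct_from_sides <- function(chrom1, side1, chrom2, side2) {
  code <- function(s) if (s == "head") "5" else "3"
  paste0(code(side1), "to", code(side2))
}

complementary_ct <- function(ct) {
  switch(ct, "3to3" = "5to5", "5to5" = "3to3",
         "3to5" = "5to3", "5to3" = "3to5",
         stop("unknown connection type: ", ct))
}

#' Group discordant read pairs into evidence clusters
#'
#' Pairs whose mates map to different chromosomes are grouped by
#' unordered chromosome pair and orientation class (which maps onto the
#' connection type), then clustered positionally: two pairs join a
#' cluster when their endpoints on both chromosomes are within
#' `window` bp.
#'
#' @param aln `rt_aln` alignment records.
#' @param window Clustering window in bp (defaults to roughly the
#'   insert-size median plus three spreads).
#' @return Data frame of clusters: chromosome pair, `ct`, `pe` support,
#'   endpoint support intervals and member mapping qualities.
#' @export
collect_discordant_pairs <- function(aln, window = 500L) {
  ## every pair whose mates map to different chromosomes counts,
  ## including fragments that also carry split-read evidence (the two
  ## evidence classes overlap, as they do for real hybrid callers)
  pri <- aln[!aln$is_supp & !is.na(aln$discordant) & aln$discordant &
             aln$mate == 1L, , drop = FALSE]
  empty <- data.frame(chrom1 = character(0), chrom2 = character(0),
                      ct = character(0), pe = integer(0),
                      pos1_lo = integer(0), pos1_hi = integer(0),
                      pos2_lo = integer(0), pos2_hi = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pri) == 0L) { empty$mapqs <- I(list()); empty$qnames <- I(list()); return(empty) }
  r2 <- aln[!aln$is_supp & aln$mate == 2L, , drop = FALSE]
  j <- match(pri$qname, r2$qname)
  ok <- !is.na(j)
  pri <- pri[ok, , drop = FALSE]; j <- j[ok]
  obs <- data.frame(
    qname = pri$qname,
    chromA = pri$chrom, estA = ifelse(pri$strand == "+", pri$end, pri$pos),
    sideA = ifelse(pri$strand == "+", "head", "tail"), mapqA = pri$mapq,
    chromB = r2$chrom[j], estB = ifelse(r2$strand[j] == "+", r2$end[j], r2$pos[j]),
    sideB = ifelse(r2$strand[j] == "+", "head", "tail"), mapqB = r2$mapq[j],
    stringsAsFactors = FALSE)
  ## orient: chrom1 = lexicographically smaller
  swap <- obs$chromA > obs$chromB
  o <- data.frame(
    qname = obs$qname,
    chrom1 = ifelse(swap, obs$chromB, obs$chromA),
    est1 = ifelse(swap, obs$estB, obs$estA),
    side1 = ifelse(swap, obs$sideB, obs$sideA),
    chrom2 = ifelse(swap, obs$chromA, obs$chromB),
    est2 = ifelse(swap, obs$estA, obs$estB),
    side2 = ifelse(swap, obs$sideA, obs$sideB),
    mapq = pmin(obs$mapqA, obs$mapqB), stringsAsFactors = FALSE)
  o$ct <- mapply(ct_from_sides, o$chrom1, o$side1, o$chrom2, o$side2)
  out <- list()
  for (key in unique(paste(o$chrom1, o$chrom2, o$ct))) {
    g <- o[paste(o$chrom1, o$chrom2, o$ct) == key, , drop = FALSE]
    for (cl in split_by_gap(g, window)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom1 = cl$chrom1[1], chrom2 = cl$chrom2[1], ct = cl$ct[1],
        pe = nrow(cl),
        pos1_lo = min(cl$est1), pos1_hi = max(cl$est1),
        pos2_lo = min(cl$est2), pos2_hi = max(cl$est2),
        mapqs = I(list(cl$mapq)), qnames = I(list(cl$qname)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## Split a group of observations into positional clusters: sort by est1
## and break at gaps > window, then refine by est2.
split_by_gap <- function(g, window) {
  g <- g[order(g$est1), , drop = FALSE]
  b1 <- cumsum(c(0L, diff(g$est1) > window))
  res <- list()
  for (p in split(g, b1)) {
    p <- p[order(p$est2), , drop = FALSE]
    b2 <- cumsum(c(0L, diff(p$est2) > window))
    res <- c(res, split(p, b2))
  }
  res
}

#' Collect split-read evidence grouped per putative junction
#'
#' Each split read (primary plus supplementary segment on different
#' chromosomes) yields an exact candidate breakend pair from its clip
#' boundaries and an orientation class; reads are grouped when their
#' breakend pairs agree to within `hom_window` bp (microhomology makes
#' individual placements ambiguous within the homology length).
#'
#' Reads soft-clipped at the junction whose unaligned part was too
#' short to place as a supplementary segment still support the junction
#' consensus; those with at least `min_clip` clipped bases at a
#' matching boundary are added to the group's split-read count (the
#' clipped-read rescue every hybrid caller performs when it realigns
#' reads against the assembled junction consensus).
#'
#' @param aln `rt_aln` records.
#' @param hom_window Grouping window for near-identical breakend pairs.
#' @param min_clip Minimum clipped bases for a non-split record to
#'   count as consensus support.
#' @return Data frame of split groups with per-junction positions
#'   (extremes of the consistent placements), `sr` counts and member
#'   records for consensus building.
#' @export
collect_split_reads <- function(aln, hom_window = 15L, min_clip = 5L) {
  spl <- aln[!is.na(aln$sa_chrom), , drop = FALSE]
  empty <- data.frame(chrom1 = character(0), chrom2 = character(0),
                      ct = character(0), sr = integer(0),
                      pos1_lo = integer(0), pos1_hi = integer(0),
                      pos2_lo = integer(0), pos2_hi = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(spl) == 0L) {
    empty$mapqs <- I(list()); empty$members <- I(list()); return(empty)
  }
  pri <- spl[!spl$is_supp, , drop = FALSE]
  sup0 <- spl[spl$is_supp, , drop = FALSE]
  j <- match(paste(pri$qname, pri$mate), paste(sup0$qname, sup0$mate))
  ok <- !is.na(j)
  pri <- pri[ok, , drop = FALSE]
  sup <- sup0[j[ok], , drop = FALSE]
  inter <- pri$chrom != sup$chrom
  pri <- pri[inter, , drop = FALSE]; sup <- sup[inter, , drop = FALSE]
  if (nrow(pri) == 0L) {
    empty$mapqs <- I(list()); empty$members <- I(list()); return(empty)
  }
  part <- function(df) {
    bad <- df$clip_left > 0L & df$clip_right > 0L
    data.frame(chrom = df$chrom,
               be = ifelse(df$clip_right > 0L, df$end, df$pos),
               side = ifelse(df$clip_right > 0L, "head", "tail"),
               mapq = df$mapq, bad = bad | (df$clip_left == 0L & df$clip_right == 0L),
               stringsAsFactors = FALSE)
  }
  pA <- part(pri); pB <- part(sup)
  keep <- !(pA$bad | pB$bad)
  n_discarded <- sum(!keep)
  pA <- pA[keep, , drop = FALSE]; pB <- pB[keep, , drop = FALSE]
  pri <- pri[keep, , drop = FALSE]; sup <- sup[keep, , drop = FALSE]
  if (nrow(pA) == 0L) {
    empty$mapqs <- I(list()); empty$members <- I(list()); return(empty)
  }
  swap <- pA$chrom > pB$chrom
  o <- data.frame(
    chrom1 = ifelse(swap, pB$chrom, pA$chrom),
    est1 = ifelse(swap, pB$be, pA$be),
    side1 = ifelse(swap, pB$side, pA$side),
    chrom2 = ifelse(swap, pA$chrom, pB$chrom),
    est2 = ifelse(swap, pA$be, pB$be),
    side2 = ifelse(swap, pA$side, pB$side),
    mapq = pri$mapq, stringsAsFactors = FALSE)
  o$ct <- mapply(ct_from_sides, o$chrom1, o$side1, o$chrom2, o$side2)
  out <- list()
  for (key in unique(paste(o$chrom1, o$chrom2, o$ct))) {
    idx <- which(paste(o$chrom1, o$chrom2, o$ct) == key)
    g <- o[idx, , drop = FALSE]; g$.row <- idx
    for (cl in split_by_gap(g, hom_window)) {
      memb <- pri[cl$.row, , drop = FALSE]
      supx <- sup[cl$.row, c("chrom", "pos", "end", "strand", "m",
                             "clip_left", "clip_right"), drop = FALSE]
      names(supx) <- paste0("sup_", names(supx))
      out[[length(out) + 1L]] <- data.frame(
        chrom1 = cl$chrom1[1], chrom2 = cl$chrom2[1], ct = cl$ct[1],
        sr = nrow(cl),
        pos1_lo = min(cl$est1), pos1_hi = max(cl$est1),
        pos2_lo = min(cl$est2), pos2_hi = max(cl$est2),
        side1 = cl$side1[1], side2 = cl$side2[1],
        mapqs = I(list(cl$mapq)),
        members = I(list(cbind(memb, supx))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  ## clipped-read rescue: non-split records whose clip boundary matches
  ## a group breakend on the consistent side
  clip_only <- aln[is.na(aln$sa_chrom) & !aln$is_supp &
                   (aln$clip_left >= min_clip | aln$clip_right >= min_clip), ,
                   drop = FALSE]
  if (nrow(clip_only) > 0L && nrow(res) > 0L) {
    co_be <- ifelse(clip_only$clip_right >= min_clip, clip_only$end,
                    clip_only$pos)
    co_side <- ifelse(clip_only$clip_right >= min_clip, "head", "tail")
    for (i in seq_len(nrow(res))) {
      hit1 <- clip_only$chrom == res$chrom1[i] & co_side == res$side1[i] &
        co_be >= res$pos1_lo[i] - hom_window & co_be <= res$pos1_hi[i] + hom_window
      hit2 <- clip_only$chrom == res$chrom2[i] & co_side == res$side2[i] &
        co_be >= res$pos2_lo[i] - hom_window & co_be <= res$pos2_hi[i] + hom_window
      extra <- hit1 | hit2
      if (any(extra)) {
        res$sr[i] <- res$sr[i] + sum(extra)
        res$mapqs[[i]] <- c(res$mapqs[[i]], clip_only$mapq[extra])
      }
    }
  }
  attr(res, "n_discarded") <- n_discarded
  res
}

sides_from_ct <- function(ct) {
  s <- strsplit(ct, "to")[[1]]
  vapply(s, function(x) if (x == "5") "head" else "tail", character(1),
         USE.NAMES = FALSE)
}

#' Call inter-chromosomal breakends from clustered evidence
#'
#' Discordant-pair clusters are merged with split-read groups on the
#' same chromosome pair and connection type. Positions come from the
#' split-read consensus when split reads exist (PRECISE), otherwise
#' from the midpoint of the pair-support interval (IMPRECISE). MAPQ is
#' the median mapping quality of supporting fragments; SRQ the mean
#' identity of supporting split reads to their assembled consensus.
#' FILTER is PASS iff (PE >= `min_support` or SR >= `min_support`) and
#' MAPQ > `min_mapq`, else LowQual. Microhomology makes the breakend
#' pair ambiguous: both extremal coordinate pairs are kept, the
#' left-most as the canonical POS.
#'
#' @param clusters Output of [collect_discordant_pairs()].
#' @param splits Output of [collect_split_reads()].
#' @param params List: `min_support` (default 3), `min_mapq` (20),
#'   `merge_window` (500), `sample`.
#' @return A `bnd_calls` data frame with two cross-referenced records
#'   per junction (one per breakend).
#' @export
call_breakends <- function(clusters, splits,
                           params = list()) {
  p <- modify_defaults(list(min_support = 3L, min_mapq = 20L,
                            merge_window = 500L, sample = "S1"), params)
  if (p$min_support < 1L) stop("min_support must be >= 1")
  junctions <- list()
  used_cluster <- rep(FALSE, if (is.null(clusters)) 0L else nrow(clusters))
  ns <- if (is.null(splits)) 0L else nrow(splits)
  for (i in seq_len(ns)) {
    sp <- splits[i, , drop = FALSE]
    pe <- 0L; mq <- sp$mapqs[[1]]
    if (length(used_cluster)) {
      cand <- which(!used_cluster &
                    clusters$chrom1 == sp$chrom1 & clusters$chrom2 == sp$chrom2 &
                    clusters$ct == sp$ct &
                    clusters$pos1_lo <= sp$pos1_hi + p$merge_window &
                    clusters$pos1_hi >= sp$pos1_lo - p$merge_window &
                    clusters$pos2_lo <= sp$pos2_hi + p$merge_window &
                    clusters$pos2_hi >= sp$pos2_lo - p$merge_window)
      if (length(cand)) {
        ci <- cand[1]
        used_cluster[ci] <- TRUE
        pe <- clusters$pe[ci]
        mq <- c(mq, clusters$mapqs[[ci]])
      }
    }
    cons <- assemble_junction_consensus(sp$members[[1]], sp)
    junctions[[length(junctions) + 1L]] <- data.frame(
      chrom1 = sp$chrom1, pos1 = sp$pos1_lo, pos1_alt = sp$pos1_hi,
      chrom2 = sp$chrom2, pos2 = sp$pos2_lo, pos2_alt = sp$pos2_hi,
      ct = sp$ct, pe = pe, sr = sp$sr,
      mapq = as.integer(round(median(mq))),
      srq = cons$srq, precise = TRUE, consensus = cons$seq,
      stringsAsFactors = FALSE)
  }
  for (ci in which(!used_cluster)) {
    cl <- clusters[ci, , drop = FALSE]
    junctions[[length(junctions) + 1L]] <- data.frame(
      chrom1 = cl$chrom1,
      pos1 = as.integer(round((cl$pos1_lo + cl$pos1_hi) / 2)),
      pos1_alt = as.integer(round((cl$pos1_lo + cl$pos1_hi) / 2)),
      chrom2 = cl$chrom2,
      pos2 = as.integer(round((cl$pos2_lo + cl$pos2_hi) / 2)),
      pos2_alt = as.integer(round((cl$pos2_lo + cl$pos2_hi) / 2)),
      ct = cl$ct, pe = cl$pe, sr = 0L,
      mapq = as.integer(round(median(cl$mapqs[[1]]))),
      srq = NA_real_, precise = FALSE, consensus = "",
      stringsAsFactors = FALSE)
  }
  if (length(junctions) == 0L) return(empty_bnd_calls())
  jn <- do.call(rbind, junctions)
  jn <- jn[order(jn$chrom1, jn$pos1, jn$chrom2, jn$pos2), , drop = FALSE]
  jn$junction <- sprintf("JUNC%04d", seq_len(nrow(jn)))
  jn$filter <- filter_status(jn$pe, jn$sr, jn$mapq, p$min_support, p$min_mapq)
  expand_junctions(jn, p$sample)
}

#' Caller quality filter status
#'
#' PASS iff (PE or SR support at least `min_support`) and MAPQ above
#' `min_mapq`; LowQual otherwise. A pure function of (PE, SR, MAPQ).
#' @param pe,sr,mapq Support and quality vectors.
#' @param min_support,min_mapq Thresholds (defaults 3 and 20).
#' @export
filter_status <- function(pe, sr, mapq, min_support = 3L, min_mapq = 20L) {
  ifelse((pe >= min_support | sr >= min_support) & mapq > min_mapq,
         "PASS", "LowQual")
}

empty_bnd_calls <- function() {
  df <- data.frame(id = character(0), mate_id = character(0),
                   junction = character(0), sample = character(0),
                   chrom = character(0), pos = integer(0), pos_alt = integer(0),
                   side = character(0), chrom2 = character(0),
                   pos2 = integer(0), pos2_alt = integer(0), side2 = character(0),
                   ct = character(0), pe = integer(0), sr = integer(0),
                   mapq = integer(0), srq = numeric(0), precise = logical(0),
                   filter = character(0), consensus = character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("bnd_calls", "data.frame")
  df
}

## Two BND records per junction, each naming its partner.
expand_junctions <- function(jn, sample) {
  sides <- t(vapply(jn$ct, sides_from_ct, character(2)))
  rec1 <- data.frame(
    id = paste0(jn$junction, "_1"), mate_id = paste0(jn$junction, "_2"),
    junction = jn$junction, sample = sample,
    chrom = jn$chrom1, pos = jn$pos1, pos_alt = jn$pos1_alt, side = sides[, 1],
    chrom2 = jn$chrom2, pos2 = jn$pos2, pos2_alt = jn$pos2_alt, side2 = sides[, 2],
    ct = jn$ct, pe = jn$pe, sr = jn$sr, mapq = jn$mapq, srq = jn$srq,
    precise = jn$precise, filter = jn$filter, consensus = jn$consensus,
    stringsAsFactors = FALSE)
  rec2 <- rec1
  rec2$id <- paste0(jn$junction, "_2"); rec2$mate_id <- paste0(jn$junction, "_1")
  rec2$chrom <- jn$chrom2; rec2$pos <- jn$pos2; rec2$pos_alt <- jn$pos2_alt
  rec2$side <- sides[, 2]
  rec2$chrom2 <- jn$chrom1; rec2$pos2 <- jn$pos1; rec2$pos2_alt <- jn$pos1_alt
  rec2$side2 <- sides[, 1]
  out <- rbind(rec1, rec2)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bnd_calls", "data.frame")
  out
}

#' Call breakends directly from alignment records
#'
#' Convenience wrapper running [collect_discordant_pairs()],
#' [collect_split_reads()] and [call_breakends()].
#' @param aln `rt_aln` records.
#' @param params See [call_breakends()]; additionally `cluster_window`
#'   and `hom_window`.
#' @export
call_breakends_from_aln <- function(aln, params = list()) {
  p <- modify_defaults(list(cluster_window = 500L, hom_window = 15L), params)
  cl <- collect_discordant_pairs(aln, window = p$cluster_window)
  sp <- collect_split_reads(aln, hom_window = p$hom_window)
  call_breakends(cl, sp, params)
}

modify_defaults <- function(defaults, x) {
  defaults[names(x)] <- x
  defaults
}
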