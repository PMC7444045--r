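## Base-pair-resolution junction reconstruction. The junction is always
## handled in "junction orientation": the segment of the
## lexicographically first chromosome (X) read 5'->3' into the
## junction, followed by any inserted bases, followed by the second
## chromosome's segment (Y). A head (5') segment runs along the
## reference, a tail (3') segment is reverse-complemented.

#' Assemble the consensus sequence across one junction from its split
#' reads
#'
#' Reads are oriented onto the junction strand and anchored at their
#' split coordinates (anchoring is by genomic arithmetic, so reads
#' whose aligners chose different but equivalent placements within a
#' microhomology tract still stack correctly); the consensus is the
#' per-position majority.
#'
#' @param members Data frame of split-read members as produced by
#'   [collect_split_reads()] (primary record fields plus `sup_*`
#'   partner fields).
#' @param group The corresponding split-group row (chromosome pair,
#'   sides, breakend extremes).
#' @return List: `seq` (consensus), `junction_idx` (consensus position
#'   of the right-most X retained base), `B1`/`B2` anchor coordinates,
#'   `srq` (mean per-read identity to the consensus) and
#'   `disagreement`.
#' @export
assemble_junction_consensus <- function(members, group) {
  if (nrow(members) == 0L) stop("no split reads to assemble")
  side1 <- group$side1[1]
  chrom1 <- group$chrom1[1]
  B1 <- if (side1 == "head") group$pos1_hi[1] else group$pos1_lo[1]
  B2 <- if (group$side2[1] == "tail") group$pos2_hi[1] else group$pos2_lo[1]

  jreads <- character(nrow(members))
  fstart <- integer(nrow(members))
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    on1 <- m$chrom == chrom1
    if (on1) {
      p <- m$pos; cl <- m$clip_left
      s_fwd <- m$seq
    } else {
      p <- m$sup_pos; cl <- m$sup_clip_left
      s_fwd <- if (m$strand == m$sup_strand) m$seq else revcomp(m$seq)
    }
    Lr <- nchar(s_fwd)
    if (side1 == "head") {
      jreads[i] <- s_fwd
      fstart[i] <- (p - B1) - cl
    } else {
      ## reference-forward index of genomic q is cl + (q - pos) + 1;
      ## after reversal, frame(first j-base) = B1 - pos - Lr + cl + 1
      jreads[i] <- revcomp(s_fwd)
      fstart[i] <- cl + B1 - p - Lr + 1L
    }
  }
  min_f <- min(fstart)
  max_f <- max(fstart + nchar(jreads) - 1L)
  width <- max_f - min_f + 1L
  counts <- matrix(0L, nrow = 4L, ncol = width,
                   dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(jreads)) {
    ch <- strsplit(jreads[i], "", fixed = TRUE)[[1]]
    idx <- (fstart[i] - min_f) + seq_along(ch)
    for (b in DNA_BASES) {
      hit <- idx[ch == b]
      counts[b, hit] <- counts[b, hit] + 1L
    }
  }
  covered <- colSums(counts) > 0L
  if (any(!covered))
    stop("split reads do not overlap into a single contig; offending reads: ",
         paste(members$qname, collapse = ","))
  cons <- DNA_BASES[apply(counts, 2L, which.max)]
  total <- sum(counts); agree <- 0
  ident <- numeric(length(jreads))
  for (i in seq_along(jreads)) {
    ch <- strsplit(jreads[i], "", fixed = TRUE)[[1]]
    idx <- (fstart[i] - min_f) + seq_along(ch)
    mt <- sum(ch == cons[idx])
    ident[i] <- mt / length(ch)
    agree <- agree + mt
  }
  ## trim the sparse single-read edges: with sequencing errors an
  ## unconfirmed edge base would defeat exact flank matching downstream
  depth <- colSums(counts)
  min_cov <- min(3L, length(jreads))
  jpos <- -min_f + 1L
  lo <- jpos; hi <- jpos
  while (lo > 1L && depth[lo - 1L] >= min_cov) lo <- lo - 1L
  while (hi < length(cons) && depth[hi + 1L] >= min_cov) hi <- hi + 1L
  list(seq = paste(cons[lo:hi], collapse = ""),
       junction_idx = jpos - lo + 1L, B1 = B1, B2 = B2,
       srq = mean(ident), disagreement = 1 - agree / total)
}

## Junction-oriented flank of `chrom` covering consensus coordinates,
## aligned so that flank[anchor_idx] sits at genomic `anchor`.
oriented_flank <- function(seqs, chrom, anchor, dir, anchor_idx, n) {
  if (dir > 0)
    oriented_sub(seqs, chrom, anchor - anchor_idx + 1L, anchor + (n - anchor_idx), 1L)
  else
    oriented_sub(seqs, chrom, anchor - (n - anchor_idx), anchor + anchor_idx - 1L, -1L)
}

#' Characterize one junction: type, microhomology, insertion and
#' breakend coordinates
#'
#' Let L be the longest prefix of the junction consensus exactly
#' matching the first chromosome's sequence (continued past the
#' breakend) and R the longest suffix matching the second chromosome's;
#' with g = length(consensus) - L - R, g < 0 means microhomology of
#' h = -g (the junction position is ambiguous within h bases), g = 0 a
#' blunt-end ligation, and g > 0 a micro-insertion of the g unmatched
#' bases. The canonical breakend pair is the left-most consistent
#' placement, the alternate the right-most; the homology-maximal
#' retained boundary on each chromosome is also reported, which is what
#' the bases-lost computation needs.
#'
#' @param cons Consensus object from [assemble_junction_consensus()].
#' @param genome `rt_genome` reference.
#' @param group Split-group (or call) row giving chrom1/2 and sides.
#' @param anchor_k Minimum anchor bases required on each side; below
#'   this the junction is reported unresolved.
#' @return List describing the junction.
#' @export
characterize_junction <- function(cons, genome, group, anchor_k = 20L) {
  seqs <- genome$seq
  n <- nchar(cons$seq)
  jx <- cons$junction_idx
  chrom1 <- group$chrom1[1]; chrom2 <- group$chrom2[1]
  side1 <- group$side1[1]; side2 <- group$side2[1]
  dir1 <- if (side1 == "head") 1L else -1L
  dir2 <- if (side2 == "tail") 1L else -1L

  flank1 <- oriented_flank(seqs, chrom1, cons$B1, dir1, jx, n)
  L <- common_prefix_len(cons$seq, flank1)

  ## anchor the Y side by locating the consensus tail in an extended
  ## flank around the caller's breakend estimate
  k <- min(anchor_k, n)
  tail_probe <- substr(cons$seq, n - k + 1L, n)
  W <- n + 60L
  if (dir2 > 0)
    f2 <- oriented_sub(seqs, chrom2, cons$B2 - 30L, cons$B2 + W, 1L)
  else
    f2 <- oriented_sub(seqs, chrom2, cons$B2 - W, cons$B2 + 30L, -1L)
  hit <- gregexpr(tail_probe, f2, fixed = TRUE)[[1]]
  if (hit[1] == -1L)
    return(list(type = "UNRESOLVED", reason = "consensus tail not found near breakend",
                chrom1 = chrom1, chrom2 = chrom2, side1 = side1, side2 = side2))
  ## expected end-of-consensus location within f2, used to pick among
  ## multiple probe hits
  expected_end <- n - jx + 30L
  hit <- hit[which.min(abs(hit + k - 1L - expected_end))]
  ## genomic coordinate of f2 position i
  f2_gen <- function(i) {
    if (dir2 > 0) (cons$B2 - 30L) + (i - 1L)
    else (cons$B2 + 30L) - (i - 1L)
  }
  ## consensus index n aligns with f2 index hit + k - 1
  off <- (hit + k - 1L) - n   # f2 index = consensus index + off
  R <- 0L
  while (R < n) {
    ci <- n - R
    fi <- ci + off
    if (fi < 1L || fi > nchar(f2)) break
    if (substr(cons$seq, ci, ci) != substr(f2, fi, fi)) break
    R <- R + 1L
  }
  if (L < anchor_k || R < anchor_k)
    return(list(type = "UNRESOLVED", reason = "anchor shorter than required",
                L = L, R = R, chrom1 = chrom1, chrom2 = chrom2,
                side1 = side1, side2 = side2))

  g <- n - L - R
  h <- if (g < 0L) -g else 0L
  insertion <- if (g > 0L) substr(cons$seq, L + 1L, L + g) else ""
  type <- if (g < 0L) "MICROHOMOLOGY" else if (g == 0L) "BLUNT" else "MICROINSERTION"

  gen1 <- function(ci) cons$B1 + dir1 * (ci - jx)      # consensus idx -> chrom1
  gen2 <- function(ci) f2_gen(ci + off)                # consensus idx -> chrom2
  x_end_max <- gen1(L)                 # homology-maximal retained end on chrom1
  y_start_max <- gen2(n - R + 1L)      # homology-maximal retained start on chrom2
  ## the h+1 equivalent placements: X ends at consensus index L - t
  t_range <- 0:h
  p1 <- vapply(t_range, function(t) gen1(L - t), numeric(1))
  p2 <- vapply(t_range, function(t) gen2(L - t + max(g, 0L) + 1L), numeric(1))
  left <- which.min(p1)
  right <- which.max(p1)
  hom1 <- hom2 <- NULL
  if (h > 0L) {
    hom1 <- sort(c(gen1(L - h + 1L), gen1(L)))
    hom2 <- sort(c(gen2(L - h + 1L + g), gen2(L + g)))
  }
  list(type = type, h = h, insertion = insertion, L = L, R = R,
       chrom1 = chrom1, chrom2 = chrom2, side1 = side1, side2 = side2,
       ct = ct_from_sides(chrom1, side1, chrom2, side2),
       canonical = c(pos1 = p1[left], pos2 = p2[left]),
       alternate = c(pos1 = p1[right], pos2 = p2[right]),
       x_end_max = x_end_max, y_start_max = y_start_max,
       hom_interval1 = hom1, hom_interval2 = hom2,
       consensus = cons$seq, srq = cons$srq)
}

#' Bases lost between the retained segments on one chromosome
#'
#' The lost interval is the run of bases strictly between the
#' (homology-maximal) retained head end and the retained tail start of
#' the same chromosome; bases covered by junction microhomology are by
#' construction outside this interval and hence not counted as lost.
#'
#' @param head_end Homology-maximal retained end of the head segment.
#' @param tail_start Homology-maximal retained start of the tail
#'   segment (same chromosome).
#' @return List with `count` and `interval` (NULL when nothing lost).
#' @export
compute_bases_lost <- function(head_end, tail_start) {
  count <- tail_start - head_end - 1L
  if (count < 0L)
    stop("unbalanced reconstruction: retained segments overlap")
  list(count = as.integer(count),
       interval = if (count > 0L) c(head_end + 1L, tail_start - 1L) else NULL)
}

#' Derived-chromosome composition and length arithmetic
#'
#' Computes, for each junction of a reciprocal pair, the lengths of the
#' two joined segments (head = bases 1..bp, tail = bp..chromosome end,
#' 1-based inclusive) and of the derived chromosome they form, in bp
#' and in megabases (rounded half-up to one decimal, reporting only).
#'
#' @param junctions List of two junction descriptions, each a list with
#'   `chrom1`, `pos1`, `side1`, `chrom2`, `pos2`, `side2` and
#'   optionally `ins_len`. For a head segment `pos` is its last base;
#'   for a tail segment `pos` is its first base.
#' @param chrom_lengths Named vector of parent chromosome lengths (bp).
#' @return Data frame, one row per junction / derived chromosome.
#' @export
derive_chromosomes <- function(junctions, chrom_lengths) {
  rows <- lapply(junctions, function(j) {
    seg_len <- function(chrom, pos, side) {
      len <- chrom_lengths[[chrom]]
      out <- if (side == "head") pos else len - pos + 1L
      if (out < 0) stop("segment arithmetic produced negative length")
      out
    }
    ins <- j$ins_len %||% 0L
    s1 <- seg_len(j$chrom1, j$pos1, j$side1)
    s2 <- seg_len(j$chrom2, j$pos2, j$side2)
    tot <- s1 + s2 + ins
    data.frame(chrom1 = j$chrom1, side1 = j$side1, seg1_bp = s1,
               chrom2 = j$chrom2, side2 = j$side2, seg2_bp = s2,
               ins_bp = ins, total_bp = tot,
               seg1_mb = mb(s1), seg2_mb = mb(s2), total_mb = mb(tot),
               vs_parent1 = ifelse(tot > chrom_lengths[[j$chrom1]], "longer",
                                   ifelse(tot < chrom_lengths[[j$chrom1]],
                                          "shorter", "equal")),
               vs_parent2 = ifelse(tot > chrom_lengths[[j$chrom2]], "longer",
                                   ifelse(tot < chrom_lengths[[j$chrom2]],
                                          "shorter", "equal")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene context of a breakpoint
#'
#' @param chrom,pos Breakpoint position (1-based).
#' @param gene_track Data frame with columns `chrom`, `start`, `end`,
#'   `type` ("gene"/"exon"), `id` (see [read_gene_track()]).
#' @return List with `class` in EXON/INTRON/INTERGENIC and the ids of
#'   all overlapping genes.
#' @export
gene_context <- function(chrom, pos, gene_track) {
  ov <- gene_track[gene_track$chrom == chrom & gene_track$start <= pos &
                   gene_track$end >= pos, , drop = FALSE]
  genes <- unique(ov$id[ov$type == "gene"])
  cls <- if (any(ov$type == "exon")) "EXON"
         else if (length(genes)) "INTRON" else "INTERGENIC"
  ids <- if (cls == "EXON") unique(ov$id[ov$type == "exon"]) else genes
  list(class = cls, ids = ids)
}

#' Full base-pair-resolution report for one reciprocal pair
#'
#' Re-collects the split reads of both junctions from the alignments,
#' assembles and characterizes each junction, computes per-chromosome
#' bases lost from the two homology-maximal retained boundaries,
#' derives the rearranged chromosome lengths and annotates gene
#' context.
#'
#' @param pair One row of an `rt_pairs` table (see
#'   [match_reciprocal_pairs()]).
#' @param aln `rt_aln` records of the sample.
#' @param genome `rt_genome` reference.
#' @param gene_track Optional gene track data frame.
#' @param anchor_k Anchor requirement passed to
#'   [characterize_junction()].
#' @return List of class `rt_junction_report`.
#' @export
junction_report <- function(pair, aln, genome, gene_track = NULL,
                            anchor_k = 20L) {
  sp <- collect_split_reads(aln)
  find_group <- function(chrom1, pos1, chrom2, pos2, ct, tol = 50L) {
    i <- which(sp$chrom1 == chrom1 & sp$chrom2 == chrom2 & sp$ct == ct &
               abs(sp$pos1_lo - pos1) <= tol & abs(sp$pos2_lo - pos2) <= tol)
    if (length(i) == 0L) return(NULL)
    sp[i[1], , drop = FALSE]
  }
  chars <- list()
  for (jn in 1:2) {
    pre <- paste0("j", jn, "_")
    grp <- find_group(pair[[paste0(pre, "chrom1")]], pair[[paste0(pre, "pos1")]],
                      pair[[paste0(pre, "chrom2")]], pair[[paste0(pre, "pos2")]],
                      pair[[paste0(pre, "ct")]])
    if (is.null(grp)) {
      chars[[jn]] <- list(type = "UNRESOLVED", reason = "no split reads")
      next
    }
    cons <- assemble_junction_consensus(grp$members[[1]], grp)
    chars[[jn]] <- characterize_junction(cons, genome, grp, anchor_k)
  }
  resolved <- vapply(chars, function(x) x$type != "UNRESOLVED", logical(1))
  lost <- list(); derived <- NULL; genes <- NULL
  if (all(resolved)) {
    ## per chromosome: one junction holds its head boundary, the other
    ## its tail boundary
    for (ch in unique(c(chars[[1]]$chrom1, chars[[1]]$chrom2))) {
      bnd <- lapply(chars, function(x) {
        if (x$chrom1 == ch) list(side = x$side1, b = x$x_end_max)
        else if (x$chrom2 == ch) list(side = x$side2, b = x$y_start_max)
        else NULL
      })
      bnd <- bnd[!vapply(bnd, is.null, logical(1))]
      he <- vapply(bnd, function(b) if (b$side == "head") b$b else NA_real_, numeric(1))
      ts <- vapply(bnd, function(b) if (b$side == "tail") b$b else NA_real_, numeric(1))
      if (any(!is.na(he)) && any(!is.na(ts)))
        lost[[ch]] <- compute_bases_lost(he[!is.na(he)][1], ts[!is.na(ts)][1])
    }
    lens <- setNames(nchar(genome$seq), names(genome$seq))
    derived <- derive_chromosomes(lapply(chars, function(x) list(
      chrom1 = x$chrom1, pos1 = unname(x$canonical["pos1"]), side1 = x$side1,
      chrom2 = x$chrom2, pos2 = unname(x$canonical["pos2"]), side2 = x$side2,
      ins_len = nchar(x$insertion))), lens)
    if (!is.null(gene_track)) {
      genes <- list()
      for (x in chars) {
        genes[[paste0(x$chrom1, ":", x$canonical["pos1"])]] <-
          gene_context(x$chrom1, x$canonical["pos1"], gene_track)
        genes[[paste0(x$chrom2, ":", x$canonical["pos2"])]] <-
          gene_context(x$chrom2, x$canonical["pos2"], gene_track)
      }
    }
  }
  structure(list(junctions = chars, lost = lost, derived = derived,
                 genes = genes), class = "rt_junction_report")
}
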