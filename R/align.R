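## Truth alignment emission: reads simulated from known haplotypes are
## placed at their true reference coordinates. Reads from derived
## chromosomes that cross a junction become split records (primary =
## longer matched segment); pairs with mates on different reference
## chromosomes are flagged discordant. Reads falling inside an
## interspersed repeat copy are treated the way a real aligner treats
## them: mapping quality drops and, with some probability, the read is
## relocated to another copy of the family, which is exactly the
## mechanism that creates translocation-like artifacts (and false
## negatives at breakpoints inside repeats) in real data.

aln_columns <- c("qname", "mate", "chrom", "pos", "end", "strand", "mapq",
                 "cigar", "m", "clip_left", "clip_right", "seq", "is_supp",
                 "sa_chrom", "sa_pos", "sa_strand",
                 "mate_chrom", "mate_pos", "mate_strand",
                 "proper", "discordant")

empty_aln <- function() {
  df <- data.frame(qname = character(0), mate = integer(0),
                   chrom = character(0), pos = integer(0), end = integer(0),
                   strand = character(0), mapq = integer(0),
                   cigar = character(0), m = integer(0),
                   clip_left = integer(0), clip_right = integer(0),
                   seq = character(0), is_supp = logical(0),
                   sa_chrom = NA_character_[0], sa_pos = integer(0),
                   sa_strand = character(0),
                   mate_chrom = character(0), mate_pos = integer(0),
                   mate_strand = character(0),
                   proper = logical(0), discordant = logical(0),
                   stringsAsFactors = FALSE)
  df
}

## Per-derived-contig junction map used to project derived coordinates
## back onto the reference.
derived_maps <- function(planted) {
  tr <- planted$truth
  maps <- list()
  for (j in tr$junctions) {
    maps[[j$der]] <- list(jspec = j$jspec, h = j$h, x_len = j$x_len,
                          g = j$ins_len, y_len = j$y_len, ct = j$ct)
  }
  maps
}

#' Emit truth alignments for simulated reads
#'
#' @param reads `rt_reads` from [simulate_read_pairs()].
#' @param genome The reference `rt_genome` the reads are projected onto.
#' @param planted The `rt_planted` object for carrier haplotypes;
#'   `NULL` for non-carriers.
#' @param min_split Minimum aligned bases on each side of a junction
#'   for a crossing read to be emitted as a split record; a shorter
#'   overhang is soft-clipped without a supplementary alignment.
#' @param mismap_prob Probability that a read lying entirely within a
#'   repeat copy is relocated to another copy of the family.
#' @param split_mismap_prob Probability that a read straddling a repeat
#'   copy boundary gains an artifact supplementary alignment on another
#'   copy.
#' @param seed Seed for the mismapping randomness.
#' @return Object of class `rt_aln`: a data frame of alignment records
#'   (one row per aligned segment, supplementary segments flagged).
#' @export
emit_truth_alignments <- function(reads, genome, planted = NULL,
                                  min_split = 15L, mismap_prob = 0.5,
                                  split_mismap_prob = 0.3,
                                  seed = reads$config$seed + 11L) {
  fr <- reads$frags
  rl <- reads$config$read_len
  maps <- if (!is.null(planted)) derived_maps(planted) else list()
  rows <- vector("list", 64L); nr <- 0L
  add <- function(df) { nr <<- nr + 1L; rows[[nr]] <<- df }

  for (mate in 1:2) {
    seqcol <- c("r1", "r2")[mate]
    der_strand <- c("+", "-")[mate]
    s_all <- if (mate == 1) fr$start else fr$end - rl + 1L
    e_all <- s_all + rl - 1L

    normal <- !(fr$contig %in% names(maps))
    if (any(normal)) {
      i <- which(normal)
      add(data.frame(
        qname = fr$qname[i], mate = mate, chrom = fr$contig[i],
        pos = s_all[i], end = e_all[i], strand = der_strand,
        mapq = 60L, cigar = sprintf("%dM", rl), m = rl,
        clip_left = 0L, clip_right = 0L,
        seq = if (mate == 1) fr$r1[i] else revcomp(fr$r2[i]),
        is_supp = FALSE, sa_chrom = NA_character_, sa_pos = NA_integer_,
        sa_strand = NA_character_, mate_chrom = NA_character_,
        mate_pos = NA_integer_, mate_strand = NA_character_,
        proper = NA, discordant = NA, stringsAsFactors = FALSE))
    }

    for (der in intersect(unique(fr$contig), names(maps))) {
      mp <- maps[[der]]
      i_der <- which(fr$contig == der)
      s <- s_all[i_der]; e <- e_all[i_der]
      x_len <- mp$x_len; g <- mp$g
      in_x <- e <= x_len
      in_y <- s >= x_len + g + 1L
      cross <- !(in_x | in_y)
      seqs_raw <- fr[[seqcol]][i_der]

      if (any(in_x))
        add(map_whole_read(fr$qname[i_der][in_x], mate, s[in_x], e[in_x],
                           seqs_raw[in_x], der_strand, mp, side = "X", rl))
      if (any(in_y))
        add(map_whole_read(fr$qname[i_der][in_y], mate, s[in_y], e[in_y],
                           seqs_raw[in_y], der_strand, mp, side = "Y", rl))
      for (k in which(cross)) {
        idx <- i_der[k]
        add(map_crossing_read(fr$qname[idx], mate, s[k], e[k], seqs_raw[k],
                              der_strand, mp, rl, min_split,
                              placement = idx %% (mp$h + 1L)))
      }
    }
  }
  aln <- do.call(rbind, rows[seq_len(nr)])
  aln <- apply_repeat_model(aln, genome$repeats, mismap_prob,
                            split_mismap_prob, min_split, seed)
  aln <- fill_mate_fields(aln, insert_max = 3L * reads$config$insert_median)
  rownames(aln) <- NULL
  class(aln) <- c("rt_aln", "data.frame")
  aln
}

## Map reads that lie entirely in the X or Y segment of a derived
## chromosome back to reference coordinates.
map_whole_read <- function(qname, mate, s, e, seq_raw, der_strand, mp, side, rl) {
  js <- mp$jspec
  if (side == "X") {
    dir <- js$dir_x
    if (dir > 0) { lo <- js$end_x - mp$x_len + s; hi <- js$end_x - mp$x_len + e }
    else         { lo <- js$end_x + mp$x_len - e; hi <- js$end_x + mp$x_len - s }
    chrom <- js$chrom_x
  } else {
    dir <- js$dir_y
    i1 <- s - mp$x_len - mp$g; i2 <- e - mp$x_len - mp$g
    if (dir > 0) { lo <- js$start_y + i1 - 1L; hi <- js$start_y + i2 - 1L }
    else         { lo <- js$start_y - i2 + 1L; hi <- js$start_y - i1 + 1L }
    chrom <- js$chrom_y
  }
  strand <- if ((der_strand == "+") == (dir > 0)) "+" else "-"
  seq_fwd <- if (mate == 1) seq_raw else revcomp(seq_raw)  # derived-forward
  ## SAM convention: SEQ is stored reference-forward
  stored <- if (dir > 0) seq_fwd else revcomp(seq_fwd)
  data.frame(qname = qname, mate = mate, chrom = chrom, pos = lo, end = hi,
             strand = strand, mapq = 60L, cigar = sprintf("%dM", rl), m = rl,
             clip_left = 0L, clip_right = 0L, seq = stored, is_supp = FALSE,
             sa_chrom = NA_character_, sa_pos = NA_integer_,
             sa_strand = NA_character_, mate_chrom = NA_character_,
             mate_pos = NA_integer_, mate_strand = NA_character_,
             proper = NA, discordant = NA, stringsAsFactors = FALSE)
}

## Map a junction-crossing read: X part + (clipped insertion) + Y part.
## With microhomology h the aligner has h+1 equally valid split
## placements; `placement` selects one, so placements vary across reads
## exactly as real aligners scatter them over the homology interval.
map_crossing_read <- function(qname, mate, s, e, seq_raw, der_strand, mp,
                              rl, min_split, placement = 0L) {
  js <- mp$jspec
  x_len <- mp$x_len; g <- mp$g
  c <- if (mp$h > 0) min(placement, max(0L, x_len - s)) else 0L
  m1 <- max(0L, x_len - c - s + 1L)
  m2 <- max(0L, e - (x_len + g) + c)
  if (g > 0) { c <- 0L; m1 <- max(0L, x_len - s + 1L); m2 <- max(0L, e - x_len - g) }

  ## stored sequence per record orientation
  seq_fwd <- if (mate == 1) seq_raw else revcomp(seq_raw)  # derived-forward

  mk <- function(side, mlen) {
    if (side == "X") {
      dir <- js$dir_x; chrom <- js$chrom_x
      if (dir > 0) { lo <- js$end_x - x_len + s; hi <- js$end_x - c }
      else         { lo <- js$end_x + c;         hi <- js$end_x + x_len - s }
      clip <- rl - mlen
      cl <- if (dir > 0) 0L else clip; cr <- if (dir > 0) clip else 0L
    } else {
      dir <- js$dir_y; chrom <- js$chrom_y
      i1 <- if (g > 0) 1L else 1L - c
      i2 <- e - x_len - g
      if (dir > 0) { lo <- js$start_y + i1 - 1L; hi <- js$start_y + i2 - 1L }
      else         { lo <- js$start_y - i2 + 1L; hi <- js$start_y - i1 + 1L }
      clip <- rl - mlen
      cl <- if (dir > 0) clip else 0L; cr <- if (dir > 0) 0L else clip
    }
    strand <- if ((der_strand == "+") == (dir > 0)) "+" else "-"
    stored <- if (dir > 0) seq_fwd else revcomp(seq_fwd)  # reference-forward
    cigar <- paste0(if (cl > 0) sprintf("%dS", cl) else "",
                    sprintf("%dM", mlen),
                    if (cr > 0) sprintf("%dS", cr) else "")
    data.frame(qname = qname, mate = mate, chrom = chrom, pos = lo, end = hi,
               strand = strand, mapq = 60L, cigar = cigar, m = mlen,
               clip_left = cl, clip_right = cr, seq = stored, is_supp = FALSE,
               sa_chrom = NA_character_, sa_pos = NA_integer_,
               sa_strand = NA_character_, mate_chrom = NA_character_,
               mate_pos = NA_integer_, mate_strand = NA_character_,
               proper = NA, discordant = NA, stringsAsFactors = FALSE)
  }

  if (m1 >= min_split && m2 >= min_split) {
    rx <- mk("X", m1); ry <- mk("Y", m2)
    primary_x <- m1 > m2 ||
      (m1 == m2 && (rx$chrom < ry$chrom ||
                    (rx$chrom == ry$chrom && rx$pos <= ry$pos)))
    pri <- if (primary_x) rx else ry
    sup <- if (primary_x) ry else rx
    sup$is_supp <- TRUE
    pri$sa_chrom <- sup$chrom; pri$sa_pos <- sup$pos; pri$sa_strand <- sup$strand
    sup$sa_chrom <- pri$chrom; sup$sa_pos <- pri$pos; sup$sa_strand <- pri$strand
    rbind(pri, sup)
  } else if (m1 >= m2 && m1 > 0L) {
    mk("X", m1)
  } else if (m2 > 0L) {
    mk("Y", m2)
  } else {
    empty_aln()
  }
}

## Repeat-aware mapping-quality and mismapping model. A record fully
## inside a repeat copy gets MAPQ 12 (family of 2-3 near-identical
## copies) or 0 (>= 4 equally good placements) and may be relocated to
## another copy; a record straddling a copy boundary may gain an
## artifact supplementary alignment on another copy.
apply_repeat_model <- function(aln, repeats, mismap_prob, split_mismap_prob,
                               min_split, seed) {
  if (is.null(repeats) || nrow(repeats) == 0L || nrow(aln) == 0L) return(aln)
  with_seed(seed, {
    extra <- list()
    for (fam in unique(repeats$family)) {
      cp <- repeats[repeats$family == fam, , drop = FALSE]
      if (nrow(cp) < 2L) next
      low_mapq <- if (nrow(cp) >= 4L) 0L else 12L
      for (ci in seq_len(nrow(cp))) {
        inside <- which(aln$chrom == cp$chrom[ci] &
                        aln$pos >= cp$start[ci] & aln$end <= cp$end[ci])
        if (length(inside)) {
          aln$mapq[inside] <- pmin(aln$mapq[inside], low_mapq)
          move <- inside[runif(length(inside)) < mismap_prob]
          for (ri in move) {
            ti <- sample(setdiff(seq_len(nrow(cp)), ci), 1L)
            off_s <- aln$pos[ri] - cp$start[ci]
            off_e <- aln$end[ri] - cp$start[ci]
            if (cp$strand[ti] == cp$strand[ci]) {
              aln$pos[ri] <- cp$start[ti] + off_s
              aln$end[ri] <- cp$start[ti] + off_e
            } else {
              aln$pos[ri] <- cp$end[ti] - off_e
              aln$end[ri] <- cp$end[ti] - off_s
              aln$strand[ri] <- if (aln$strand[ri] == "+") "-" else "+"
              aln$seq[ri] <- revcomp(aln$seq[ri])
            }
            aln$chrom[ri] <- cp$chrom[ti]
          }
        }
        ## boundary-straddling artifact splits (plain full-length
        ## records only)
        straddle <- which(aln$chrom == cp$chrom[ci] & aln$m == nchar(aln$seq) &
                          !aln$is_supp &
                          ((aln$pos < cp$start[ci] & aln$end >= cp$start[ci] + min_split - 1L &
                            aln$pos <= cp$start[ci] - min_split) |
                           (aln$end > cp$end[ci] & aln$pos <= cp$end[ci] - min_split + 1L &
                            aln$end >= cp$end[ci] + min_split)))
        straddle <- straddle[runif(length(straddle)) < split_mismap_prob]
        for (ri in straddle) {
          ti <- sample(setdiff(seq_len(nrow(cp)), ci), 1L)
          left_of <- aln$pos[ri] < cp$start[ci]
          if (left_of) {
            out_m <- cp$start[ci] - aln$pos[ri]
            in_m <- aln$end[ri] - cp$start[ci] + 1L
            in_off <- 0L
          } else {
            in_m <- cp$end[ci] - aln$pos[ri] + 1L
            out_m <- aln$end[ri] - cp$end[ci]
            in_off <- aln$pos[ri] - cp$start[ci]
          }
          rl <- nchar(aln$seq[ri])
          sup <- aln[ri, , drop = FALSE]
          sup$chrom <- cp$chrom[ti]
          sup$pos <- cp$start[ti] + in_off
          sup$end <- sup$pos + in_m - 1L
          sup$m <- in_m; sup$mapq <- low_mapq; sup$is_supp <- TRUE
          if (left_of) { sup$clip_left <- out_m; sup$clip_right <- 0L }
          else         { sup$clip_left <- 0L; sup$clip_right <- out_m }
          sup$cigar <- paste0(if (sup$clip_left > 0) sprintf("%dS", sup$clip_left) else "",
                              sprintf("%dM", in_m),
                              if (sup$clip_right > 0) sprintf("%dS", sup$clip_right) else "")
          ## trim the primary to the outside part
          if (left_of) {
            aln$end[ri] <- cp$start[ci] - 1L
            aln$clip_right[ri] <- in_m
          } else {
            aln$pos[ri] <- cp$end[ci] + 1L
            aln$clip_left[ri] <- in_m
          }
          aln$m[ri] <- out_m
          aln$cigar[ri] <- paste0(if (aln$clip_left[ri] > 0) sprintf("%dS", aln$clip_left[ri]) else "",
                                  sprintf("%dM", out_m),
                                  if (aln$clip_right[ri] > 0) sprintf("%dS", aln$clip_right[ri]) else "")
          aln$sa_chrom[ri] <- sup$chrom; aln$sa_pos[ri] <- sup$pos
          aln$sa_strand[ri] <- sup$strand
          sup$sa_chrom <- aln$chrom[ri]; sup$sa_pos <- aln$pos[ri]
          sup$sa_strand <- aln$strand[ri]
          extra[[length(extra) + 1L]] <- sup
        }
      }
    }
    if (length(extra)) aln <- rbind(aln, do.call(rbind, extra))
    aln
  })
}

## Mate coordinates, proper-pair and discordant flags on primary
## records. A pair is discordant when its mates map to different
## chromosomes; a proper pair is never discordant.
fill_mate_fields <- function(aln, insert_max) {
  pri <- !aln$is_supp
  key <- paste(aln$qname, aln$mate)
  i1 <- which(pri & aln$mate == 1L); i2 <- which(pri & aln$mate == 2L)
  m12 <- match(aln$qname[i1], aln$qname[i2])
  m21 <- match(aln$qname[i2], aln$qname[i1])
  j <- i2[m12]
  aln$mate_chrom[i1] <- aln$chrom[j]; aln$mate_pos[i1] <- aln$pos[j]
  aln$mate_strand[i1] <- aln$strand[j]
  k <- i1[m21]
  aln$mate_chrom[i2] <- aln$chrom[k]; aln$mate_pos[i2] <- aln$pos[k]
  aln$mate_strand[i2] <- aln$strand[k]
  has_mate <- pri & !is.na(aln$mate_chrom)
  aln$discordant[has_mate] <- aln$chrom[has_mate] != aln$mate_chrom[has_mate]
  span_ok <- abs(aln$mate_pos[has_mate] - aln$pos[has_mate]) <= insert_max
  aln$proper[has_mate] <- !aln$discordant[has_mate] &
    aln$strand[has_mate] != aln$mate_strand[has_mate] & span_ok
  aln$proper[is.na(aln$proper) & pri] <- FALSE
  aln$discordant[is.na(aln$discordant) & pri] <- FALSE
  aln
}
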