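#' Describe the junction architecture of one RT junction
#'
#' A junction is the novel adjacency between two chromosome ends. Its
#' architecture is one of three types observed at RT breakpoints:
#' blunt-end ligation, microhomology (a short sequence shared by both
#' breakpoint flanks, making the exact junction position ambiguous
#' within its length), or a micro-insertion of novel bases absent from
#' both flanks.
#'
#' @param type One of `"BLUNT"`, `"MICROHOMOLOGY"`, `"MICROINSERTION"`.
#' @param h Microhomology length in bp (required >= 1 for
#'   `MICROHOMOLOGY`, 0 otherwise).
#' @param insertion Inserted sequence (non-empty only for
#'   `MICROINSERTION`).
#' @export
junction_arch <- function(type = c("BLUNT", "MICROHOMOLOGY", "MICROINSERTION"),
                          h = 0L, insertion = "") {
  type <- match.arg(type)
  h <- as.integer(h)
  insertion <- toupper(insertion)
  if (type == "BLUNT" && (h != 0L || nzchar(insertion)))
    stop("BLUNT junction requires h = 0 and no insertion")
  if (type == "MICROHOMOLOGY" && (h < 1L || nzchar(insertion)))
    stop("MICROHOMOLOGY junction requires h >= 1 and no insertion")
  if (type == "MICROINSERTION" && (!nzchar(insertion) || h != 0L))
    stop("MICROINSERTION junction requires a non-empty insertion and h = 0")
  if (nzchar(insertion) && !grepl("^[ACGT]+$", insertion))
    stop("insertion must be A/C/G/T")
  list(type = type, h = h, insertion = insertion)
}

#' Specify the translocation to plant in a simulated genome
#'
#' Coordinates are 1-based inclusive. The head of a chromosome is bases
#' `1..bp` and the tail is everything after the breakpoint region. The
#' connection configuration states which ends are joined: `"HT/TH"`
#' joins head-to-tail twice (connection types 3' to 5' and 5' to 3'),
#' `"HH/TT"` joins the two heads and the two tails (5' to 5' and
#' 3' to 3'), the latter requiring one segment of each junction to be
#' reverse-complemented so every derived chromosome reads 5' to 3'.
#'
#' `loss` gives the number of bases of each chromosome that are lost at
#' the break (reported convention: bases covered by junction
#' microhomology are not counted as lost, so the physical gap between
#' the retained head and tail is `loss` plus any adjacent homology).
#'
#' @param chrA,chrB Chromosome names (must differ).
#' @param bpA,bpB Breakpoints: last retained base of each head.
#' @param connection `"HT/TH"` or `"HH/TT"`.
#' @param jun1,jun2 [junction_arch()] for the two junctions. For
#'   `HT/TH`, `jun1` joins head(A)+tail(B) and `jun2` head(B)+tail(A);
#'   for `HH/TT`, `jun1` joins the heads and `jun2` the tails.
#' @param loss Length-2 vector: reported bases lost on chrA and chrB.
#' @export
rt_truth <- function(chrA, chrB, bpA, bpB,
                     connection = c("HT/TH", "HH/TT"),
                     jun1 = junction_arch("BLUNT"),
                     jun2 = junction_arch("BLUNT"),
                     loss = c(0L, 0L)) {
  connection <- match.arg(connection)
  if (identical(chrA, chrB)) stop("an RT involves two distinct chromosomes")
  list(chrA = chrA, chrB = chrB, bpA = as.integer(bpA), bpB = as.integer(bpB),
       connection = connection, jun1 = jun1, jun2 = jun2,
       loss = setNames(as.integer(loss), c(chrA, chrB)))
}

## ---- junction-oriented sequence access -------------------------------
## A junction spec (jspec) describes one junction in "junction
## orientation": segment X read 5'->3' ends at genomic position end_x
## walking in direction dir_x (+1 along the reference, -1 means the
## segment is reverse-complemented); segment Y starts at start_y walking
## dir_y. All extraction helpers return sequence in junction
## orientation and silently truncate at chromosome ends.

jspec <- function(chrom_x, end_x, dir_x, chrom_y, start_y, dir_y) {
  list(chrom_x = chrom_x, end_x = as.integer(end_x), dir_x = as.integer(dir_x),
       chrom_y = chrom_y, start_y = as.integer(start_y), dir_y = as.integer(dir_y))
}

oriented_sub <- function(seqs, chrom, lo, hi, dir) {
  len <- nchar(seqs[[chrom]])
  lo <- max(1L, lo); hi <- min(len, hi)
  if (lo > hi) return("")
  s <- substr(seqs[[chrom]], lo, hi)
  if (dir < 0) revcomp(s) else s
}

## Last n retained bases of X, junction-oriented.
x_flank <- function(seqs, js, n) {
  if (js$dir_x > 0) oriented_sub(seqs, js$chrom_x, js$end_x - n + 1L, js$end_x, 1L)
  else oriented_sub(seqs, js$chrom_x, js$end_x, js$end_x + n - 1L, -1L)
}

## Reference continuation beyond X's retained end.
x_cont <- function(seqs, js, n) {
  if (js$dir_x > 0) oriented_sub(seqs, js$chrom_x, js$end_x + 1L, js$end_x + n, 1L)
  else oriented_sub(seqs, js$chrom_x, js$end_x - n, js$end_x - 1L, -1L)
}

## First n retained bases of Y.
y_flank <- function(seqs, js, n) {
  if (js$dir_y > 0) oriented_sub(seqs, js$chrom_y, js$start_y, js$start_y + n - 1L, 1L)
  else oriented_sub(seqs, js$chrom_y, js$start_y - n + 1L, js$start_y, -1L)
}

## Reference bases immediately preceding Y's retained start.
y_prec <- function(seqs, js, n) {
  if (js$dir_y > 0) oriented_sub(seqs, js$chrom_y, js$start_y - n, js$start_y - 1L, 1L)
  else oriented_sub(seqs, js$chrom_y, js$start_y + 1L, js$start_y + n, -1L)
}

## Genomic position of the i-th base beyond X's end / before Y's start.
x_cont_pos <- function(js, i) js$end_x + js$dir_x * i
y_prec_pos <- function(js, i) js$start_y - js$dir_y * i

write_genomic_base <- function(seqs, chrom, pos, oriented_value, dir) {
  v <- if (dir < 0) complement_bases(oriented_value) else oriented_value
  substr(seqs[[chrom]], pos, pos) <- v
  seqs
}

read_oriented_base <- function(seqs, chrom, pos, dir) {
  if (pos < 1L || pos > nchar(seqs[[chrom]])) return("")
  b <- substr(seqs[[chrom]], pos, pos)
  if (dir < 0) complement_bases(b) else b
}

## Write the microhomology block: the h reference bases preceding Y's
## retained start are made identical (in junction orientation) to the
## last h retained bases of X. These positions lie in the unretained gap
## of Y's chromosome, so the write affects neither derived chromosome.
set_homology_block <- function(seqs, js, h) {
  val <- x_flank(seqs, js, h)
  for (k in seq_len(h)) {
    pos <- y_prec_pos(js, h - k + 1L)
    seqs <- write_genomic_base(seqs, js$chrom_y, pos,
                               substr(val, k, k), js$dir_y)
  }
  seqs
}

## Side label of each jspec end: "5" = head (runs 5'->3' into the
## junction along the reference), "3" = tail.
ct_label <- function(js) {
  side_x <- if (js$dir_x > 0) "5" else "3"
  side_y <- if (js$dir_y < 0) "5" else "3"
  if (js$chrom_x <= js$chrom_y) paste0(side_x, "to", side_y)
  else paste0(side_y, "to", side_x)
}

## ---- planting --------------------------------------------------------

#' Plant a balanced reciprocal translocation in a reference genome
#'
#' Produces the two derived chromosome sequences as exact concatenations
#' of the retained head/tail segments (honouring the head/tail
#' orientation of the connection configuration, with reverse
#' complementation where needed so derived sequences read 5' to 3'),
#' inserts micro-insertions, excludes the lost bases, and edits the
#' reference flanks so that every requested microhomology is literally
#' present and no junction carries accidental extra homology. The
#' returned truth records the full junction geometry needed by the
#' truth aligner and by recovery tests.
#'
#' @param genome An `rt_genome` from [make_reference()].
#' @param truth An [rt_truth()] specification.
#' @return An object of class `rt_planted`: list with the (possibly
#'   flank-edited) `genome`, `derived` (named character vector of the
#'   two derived chromosome sequences) and completed `truth`.
#' @export
plant_translocation <- function(genome, truth) {
  seqs <- genome$seq
  chrA <- truth$chrA; chrB <- truth$chrB
  for (ch in c(chrA, chrB))
    if (!ch %in% names(seqs)) stop(sprintf("chromosome '%s' not in genome", ch))
  lenA <- nchar(seqs[[chrA]]); lenB <- nchar(seqs[[chrB]])
  bpA <- truth$bpA; bpB <- truth$bpB
  if (bpA < 1L || bpA >= lenA) stop("bpA outside chrA")
  if (bpB < 1L || bpB >= lenB) stop("bpB outside chrB")
  j1 <- truth$jun1; j2 <- truth$jun2
  lossA <- truth$loss[[chrA]]; lossB <- truth$loss[[chrB]]

  ## physical gap = reported loss + homology accounted on that
  ## chromosome (homology blocks are written into the gap of the Y-side
  ## chromosome of each junction)
  if (truth$connection == "HT/TH") {
    gapA <- lossA + j2$h          # jun2: Y = tail(A)
    gapB <- lossB + j1$h          # jun1: Y = tail(B)
  } else {
    gapA <- lossA                 # neither junction accounts on A
    gapB <- lossB + j1$h + j2$h   # jun1: Y = rc(head(B)); jun2: Y = tail(B)
  }
  tailA <- bpA + gapA + 1L
  tailB <- bpB + gapB + 1L
  if (tailA > lenA) stop("loss/homology exceed chrA tail")
  if (tailB > lenB) stop("loss/homology exceed chrB tail")

  if (truth$connection == "HT/TH") {
    js1 <- jspec(chrA, bpA, +1L, chrB, tailB, +1L)
    js2 <- jspec(chrB, bpB, +1L, chrA, tailA, +1L)
  } else {
    js1 <- jspec(chrA, bpA, +1L, chrB, bpB, -1L)
    js2 <- jspec(chrA, tailA, -1L, chrB, tailB, +1L)
  }
  if (j1$h >= bpA || j2$h >= min(bpA, bpB))
    stop("microhomology longer than a retained segment")

  enf <- enforce_junction_architecture(seqs, list(js1, js2), list(j1, j2))
  seqs <- enf$seqs
  j1 <- enf$archs[[1]]; j2 <- enf$archs[[2]]

  head_of <- function(ch, bp) substr(seqs[[ch]], 1L, bp)
  tail_of <- function(ch, ts) substr(seqs[[ch]], ts, nchar(seqs[[ch]]))
  if (truth$connection == "HT/TH") {
    der1 <- paste0(head_of(chrA, bpA), j1$insertion, tail_of(chrB, tailB))
    der2 <- paste0(head_of(chrB, bpB), j2$insertion, tail_of(chrA, tailA))
    x_len <- c(bpA, bpB)
    y_len <- c(lenB - tailB + 1L, lenA - tailA + 1L)
  } else {
    der1 <- paste0(head_of(chrA, bpA), j1$insertion, revcomp(head_of(chrB, bpB)))
    der2 <- paste0(revcomp(tail_of(chrA, tailA)), j2$insertion, tail_of(chrB, tailB))
    x_len <- c(bpA, lenA - tailA + 1L)
    y_len <- c(bpB, lenB - tailB + 1L)
  }
  der_names <- paste0("der", 1:2, "_", chrA, "_", chrB)
  derived <- setNames(c(der1, der2), der_names)

  jinfo <- list()
  for (i in 1:2) {
    js <- if (i == 1) js1 else js2
    arch <- if (i == 1) j1 else j2
    hom <- NULL
    if (arch$h > 0) {
      p <- sort(c(y_prec_pos(js, 1L), y_prec_pos(js, arch$h)))
      hom <- list(chrom = js$chrom_y, start = p[1], end = p[2])
    }
    jinfo[[i]] <- list(
      name = paste0("J", i), der = der_names[i], ct = ct_label(js),
      jspec = js, type = arch$type, h = arch$h, insertion = arch$insertion,
      hom_interval = hom,
      x_len = x_len[i], ins_len = nchar(arch$insertion), y_len = y_len[i])
  }

  lost <- list()
  lost[[chrA]] <- if (lossA > 0) {
    st <- if (truth$connection == "HT/TH") bpA + 1L else bpA + 1L
    c(st, st + lossA - 1L)
  } else NULL
  lost[[chrB]] <- if (lossB > 0) {
    st <- if (truth$connection == "HT/TH") bpB + 1L else bpB + j1$h + 1L
    c(st, st + lossB - 1L)
  } else NULL

  out_truth <- c(truth, list(
    gap = setNames(c(gapA, gapB), c(chrA, chrB)),
    tail_start = setNames(c(tailA, tailB), c(chrA, chrB)),
    lost = lost, junctions = jinfo,
    lenA = lenA, lenB = lenB))
  genome$seq <- seqs
  structure(list(genome = genome, derived = derived, truth = out_truth),
            class = "rt_planted")
}

## Make each requested architecture literally true and exclusive: write
## homology blocks, then iteratively break any accidental flank
## agreement that would change the detected type or homology length.
enforce_junction_architecture <- function(seqs, jss, archs, max_iter = 80L) {
  locked <- list()
  for (i in 1:2) {
    h <- archs[[i]]$h
    if (h > 0) {
      js <- jss[[i]]
      for (k in seq_len(h)) {
        locked[[length(locked) + 1L]] <- c(js$chrom_y, y_prec_pos(js, k))
        xp <- js$end_x - js$dir_x * (k - 1L)
        locked[[length(locked) + 1L]] <- c(js$chrom_x, xp)
      }
    }
  }
  is_locked <- function(chrom, pos)
    any(vapply(locked, function(l) identical(l[1], chrom) &&
                 as.integer(l[2]) == pos, logical(1)))

  pick_base <- function(avoid) {
    cand <- setdiff(DNA_BASES, avoid)
    if (length(cand) == 0L) stop("cannot satisfy junction flank constraints")
    cand[1L]
  }

  ## The two anti-extension rules per junction, expressed as genomic
  ## "this position must differ from this value" constraints. Both
  ## junctions may constrain the same gap base, so a mutation must
  ## avoid the union of the forbidden values at that position.
  rule_constraints <- function(seqs) {
    cons <- list()
    for (i in 1:2) {
      js <- jss[[i]]; a <- archs[[i]]
      ins <- a$insertion; g <- nchar(ins); h <- a$h
      genomic <- function(v, dir) if (dir < 0) complement_bases(v) else v
      ## L rule: the reference continuation of X must not equal the
      ## base the consensus continues with
      cons_next <- if (g > 0) substr(ins, 1, 1) else y_flank(seqs, js, 1L)
      cons[[length(cons) + 1L]] <- list(
        junction = i, rule = "L", chrom = js$chrom_x,
        pos = x_cont_pos(js, 1L), dir = js$dir_x,
        forbid = genomic(cons_next, js$dir_x),
        ins_idx = if (g > 0) 1L else NA_integer_,
        alt_chrom = js$chrom_y, alt_pos = js$start_y, alt_dir = js$dir_y,
        alt_forbid_oriented = TRUE)
      ## R rule: the reference base before the matched block on Y's
      ## chromosome must not equal the base the consensus carries there
      cons_prev <- if (g > 0) substr(ins, g, g)
                   else substr(x_flank(seqs, js, h + 1L), 1, 1)
      cons[[length(cons) + 1L]] <- list(
        junction = i, rule = "R", chrom = js$chrom_y,
        pos = y_prec_pos(js, h + 1L), dir = js$dir_y,
        forbid = genomic(cons_prev, js$dir_y),
        ins_idx = if (g > 0) nchar(ins) else NA_integer_,
        alt_chrom = js$chrom_x, alt_pos = js$end_x - js$dir_x * h,
        alt_dir = js$dir_x, alt_forbid_oriented = TRUE)
    }
    cons
  }
  in_bounds <- function(chrom, pos) pos >= 1L && pos <= nchar(seqs[[chrom]])
  current_base <- function(chrom, pos) substr(seqs[[chrom]], pos, pos)

  for (iter in seq_len(max_iter)) {
    for (i in 1:2) if (archs[[i]]$h > 0)
      seqs <- set_homology_block(seqs, jss[[i]], archs[[i]]$h)
    rules <- rule_constraints(seqs)
    violated <- Filter(function(r) in_bounds(r$chrom, r$pos) &&
                         current_base(r$chrom, r$pos) == r$forbid, rules)
    if (length(violated) == 0L) return(list(seqs = seqs, archs = archs))
    r <- violated[[1]]
    if (!is_locked(r$chrom, r$pos)) {
      ## forbid every value any rule imposes on this genomic position
      forbid_all <- vapply(Filter(function(q) q$chrom == r$chrom &&
                                    q$pos == r$pos, rules),
                           function(q) q$forbid, character(1))
      substr(seqs[[r$chrom]], r$pos, r$pos) <-
        pick_base(c(forbid_all, current_base(r$chrom, r$pos)))
    } else if (!is.na(r$ins_idx)) {
      ## mutate the free insertion base instead of the locked flank
      cur <- substr(archs[[r$junction]]$insertion, r$ins_idx, r$ins_idx)
      ref_val <- read_oriented_base(seqs, r$chrom, r$pos, r$dir)
      substr(archs[[r$junction]]$insertion, r$ins_idx, r$ins_idx) <-
        pick_base(c(cur, ref_val))
    } else {
      ## last resort: mutate the consensus-side retained base
      if (is_locked(r$alt_chrom, r$alt_pos) || !in_bounds(r$alt_chrom, r$alt_pos))
        stop("cannot satisfy junction flank constraints at ",
             r$chrom, ":", r$pos)
      ref_val <- read_oriented_base(seqs, r$chrom, r$pos, r$dir)
      nb <- pick_base(c(ref_val,
                        read_oriented_base(seqs, r$alt_chrom, r$alt_pos, r$alt_dir)))
      seqs <- write_genomic_base(seqs, r$alt_chrom, r$alt_pos, nb, r$alt_dir)
    }
  }
  stop("junction architecture enforcement did not converge")
}
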