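## Plain-text interchange: headered SAM for alignments (so samtools and
## IGV can consume simulator output), BED for repeat and junction
## tracks, GFF3/BED gene tracks via rtracklayer.

#' Write alignment records as a headered, coordinate-sorted SAM file
#' @param aln `rt_aln` data frame.
#' @param genome `rt_genome` (for the @SQ header lines).
#' @param path Output path.
#' @export
write_sam <- function(aln, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq),
                   nchar(genome$seq)))
  a <- aln[order(aln$chrom, aln$pos), , drop = FALSE]
  flag <- 1L +
    ifelse(!is.na(a$proper) & a$proper, 2L, 0L) +
    ifelse(a$strand == "-", 16L, 0L) +
    ifelse(!is.na(a$mate_strand) & a$mate_strand == "-", 32L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(a$is_supp, 2048L, 0L)
  rnext <- ifelse(is.na(a$mate_chrom), "*",
                  ifelse(a$mate_chrom == a$chrom, "=", a$mate_chrom))
  pnext <- ifelse(is.na(a$mate_pos), 0L, a$mate_pos)
  sa <- ifelse(is.na(a$sa_chrom), "",
               sprintf("\tSA:Z:%s,%d,%s,*,%d,0;", a$sa_chrom, a$sa_pos,
                       a$sa_strand, a$mapq))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                   a$qname, flag, a$chrom, a$pos, a$mapq, a$cigar,
                   rnext, pnext, a$seq, strrep("I", nchar(a$seq)), sa)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into an `rt_aln` data frame
#' @param path SAM file path.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    a <- empty_aln(); class(a) <- c("rt_aln", "data.frame"); return(a)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  parse_cig <- function(cg) {
    ops <- gregexpr("\\d+[MSH]", cg)[[1]]
    parts <- regmatches(cg, gregexpr("\\d+[MSH]", cg))[[1]]
    n <- as.integer(sub("[MSH]", "", parts))
    op <- sub("\\d+", "", parts)
    c(m = sum(n[op == "M"]),
      cl = if (length(n) && op[1] %in% c("S", "H")) n[1] else 0L,
      cr = if (length(n) && op[length(op)] %in% c("S", "H")) n[length(n)] else 0L)
  }
  cp <- t(vapply(cigar, parse_cig, c(m = 0L, cl = 0L, cr = 0L)))
  sa_field <- vapply(f, function(x) {
    hit <- grep("^SA:Z:", x, value = TRUE)
    if (length(hit)) sub("^SA:Z:", "", hit[1]) else NA_character_
  }, character(1))
  sa_parts <- strsplit(ifelse(is.na(sa_field), ",,,", sa_field), ",", fixed = TRUE)
  rnext <- get(7)
  chrom <- get(3)
  a <- data.frame(
    qname = get(1), mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = chrom, pos = as.integer(get(4)),
    end = as.integer(get(4)) + cp[, "m"] - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(get(5)), cigar = cigar,
    m = cp[, "m"], clip_left = cp[, "cl"], clip_right = cp[, "cr"],
    seq = get(10), is_supp = bitwAnd(flag, 2048L) > 0L,
    sa_chrom = vapply(sa_parts, function(x) if (nzchar(x[1])) x[1] else NA_character_, character(1)),
    sa_pos = vapply(sa_parts, function(x) if (length(x) > 1 && nzchar(x[2])) as.integer(x[2]) else NA_integer_, integer(1)),
    sa_strand = vapply(sa_parts, function(x) if (length(x) > 2 && nzchar(x[3])) x[3] else NA_character_, character(1)),
    mate_chrom = ifelse(rnext == "*", NA_character_,
                        ifelse(rnext == "=", chrom, rnext)),
    mate_pos = as.integer(get(8)),
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    proper = bitwAnd(flag, 2L) > 0L,
    discordant = NA, stringsAsFactors = FALSE)
  has_mate <- !a$is_supp & !is.na(a$mate_chrom)
  a$discordant[has_mate] <- a$chrom[has_mate] != a$mate_chrom[has_mate]
  a$discordant[is.na(a$discordant) & !a$is_supp] <- FALSE
  class(a) <- c("rt_aln", "data.frame")
  a
}

#' Write a BED track (0-based half-open on disk; inputs are 1-based)
#' @export
write_bed <- function(df, path, name_col = NULL) {
  nm <- if (!is.null(name_col)) df[[name_col]] else
    if (!is.null(df$family)) df$family else "."
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start - 1L, df$end, nm)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED track into a 1-based data frame
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else ".",
             stringsAsFactors = FALSE)
}

#' Read a gene track (GFF3) into the data frame used by [gene_context()]
#'
#' Keeps `gene` and `exon` features; `ID`/`Name` attributes become the
#' feature identifier.
#' @export
read_gene_track <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  keep <- tolower(as.character(gr$type)) %in% c("gene", "exon")
  gr <- gr[keep]
  id <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  id[is.na(id)] <- as.character(gr$ID)[is.na(id)]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = tolower(as.character(gr$type)),
             id = id, stringsAsFactors = FALSE)
}
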