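#' Generate a toy reference genome, optionally seeded with an
#' interspersed repeat family
#'
#' Builds pseudo-random chromosome sequences and, if requested, writes
#' diverged copies of a repeat monomer at specified placements. The
#' repeat emulates an abundant SINE family (multiple near-identical
#' copies scattered over several chromosomes), the class of element that
#' generates translocation-like mapping artifacts in real short-read
#' data.
#'
#' @param lengths Named integer vector of chromosome lengths (bp).
#'   Names become chromosome names.
#' @param repeats Optional repeat specification created by
#'   [repeat_spec()].
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return An object of class `rt_genome`: a list with `seq` (named
#'   character vector of chromosome sequences) and `repeats` (a
#'   BED-like data frame of the repeat placements actually written,
#'   with zero rows when no repeats were requested).
#' @export
make_reference <- function(lengths, repeats = NULL, seed = 1L) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("`lengths` must be uniquely named by chromosome")
  if (any(lengths < 1)) stop("chromosome lengths must be >= 1")
  lengths <- setNames(as.integer(lengths), names(lengths))
  seqs <- with_seed(seed, vapply(lengths, random_dna, character(1)))
  rep_bed <- empty_repeat_bed()
  if (!is.null(repeats)) {
    pl <- repeats$placements
    mono <- repeats$monomer
    mlen <- nchar(mono)
    for (i in seq_len(nrow(pl))) {
      chrom <- pl$chrom[i]
      start <- pl$start[i]
      if (!chrom %in% names(seqs))
        stop(sprintf("repeat placement on unknown chromosome '%s'", chrom))
      end <- start + mlen - 1L
      if (start < 1L || end > lengths[[chrom]])
        stop(sprintf("repeat placement out of bounds: %s:%d-%d", chrom, start, end))
      copy <- with_seed(seed + 1000L + i,
                        diverge_sequence(mono, repeats$divergence))
      if (identical(pl$strand[i], "-")) copy <- revcomp(copy)
      substr(seqs[[chrom]], start, end) <- copy
      rep_bed <- rbind(rep_bed, data.frame(
        chrom = chrom, start = start, end = end,
        family = repeats$family, strand = pl$strand[i],
        copy = i, n_copies = nrow(pl),
        divergence = repeats$divergence,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(seq = seqs, lengths = lengths, repeats = rep_bed),
            class = "rt_genome")
}

empty_repeat_bed <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             family = character(0), strand = character(0),
             copy = integer(0), n_copies = integer(0),
             divergence = numeric(0), stringsAsFactors = FALSE)
}

#' Specify an interspersed repeat family for the simulated genome
#'
#' @param placements Data frame with columns `chrom`, `start` and
#'   optionally `strand` ("+"/"-", default "+").
#' @param monomer Monomer sequence; generated randomly when `NULL`.
#' @param monomer_length Length of the generated monomer (default 250
#'   bp, a typical SINE size).
#' @param divergence Per-copy substitution rate in \[0, 0.2\].
#' @param family Family label carried into the repeat annotation.
#' @param seed Seed for monomer generation.
#' @export
repeat_spec <- function(placements, monomer = NULL, monomer_length = 250L,
                        divergence = 0.05, family = "SINE_sim", seed = 99L) {
  if (is.null(monomer))
    monomer <- with_seed(seed, random_dna(monomer_length))
  if (nchar(monomer) < 50L) stop("repeat monomer must be >= 50 bp")
  if (divergence < 0 || divergence > 0.2)
    stop("divergence must lie in [0, 0.2]")
  if (is.null(placements$strand)) placements$strand <- "+"
  list(family = family, monomer = monomer,
       placements = placements, divergence = divergence)
}

## Substitute bases independently at the given rate.
diverge_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1))
  paste(ch, collapse = "")
}

#' @export
print.rt_genome <- function(x, ...) {
  cat(sprintf("rt_genome: %d chromosome(s), %s bp total, %d repeat copies\n",
              length(x$seq), format(sum(x$lengths), big.mark = ","),
              nrow(x$repeats)))
  invisible(x)
}
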