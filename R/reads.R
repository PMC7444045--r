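#' Configure the paired-end read simulator
#'
#' Defaults follow a typical 150 bp paired-end short-read run of a
#' diploid sample: 2x150 bp reads, median insert size 307 bp, 30-fold
#' target coverage. Insert sizes are drawn from a lognormal
#' distribution parameterized by its median with a shape giving an IQR
#' of roughly 15% of the median. Sequencing errors are independent
#' uniform substitutions.
#'
#' @param read_len Read length in bp (>= 30).
#' @param insert_median Median insert size (>= 2 x read length).
#' @param insert_sdlog Lognormal shape parameter on the log scale.
#' @param coverage Target fold coverage over both haplotypes combined.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for all simulator randomness.
#' @export
sim_config <- function(read_len = 150L, insert_median = 307L,
                       insert_sdlog = 0.11, coverage = 30,
                       error_rate = 0, seed = 1L) {
  read_len <- as.integer(read_len)
  if (read_len < 30L) stop("read_len must be >= 30")
  if (insert_median < 2L * read_len)
    stop("insert_median must be >= 2 * read_len")
  if (coverage <= 0) stop("coverage must be > 0")
  list(read_len = read_len, insert_median = as.integer(insert_median),
       insert_sdlog = insert_sdlog, coverage = coverage,
       error_rate = error_rate, seed = as.integer(seed))
}

#' Haplotype pair of an RT carrier (or a non-carrier)
#'
#' A carrier is diploid: one haplotype carries the normal chromosomes,
#' the other carries the two derived chromosomes in place of the two
#' chromosomes involved in the translocation.
#'
#' @param planted An `rt_planted` object, or an `rt_genome` for a
#'   non-carrier (both haplotypes normal).
#' @return List of two named character vectors (`hap1`, `hap2`).
#' @export
carrier_haplotypes <- function(planted) {
  if (inherits(planted, "rt_genome"))
    return(list(hap1 = planted$seq, hap2 = planted$seq))
  stopifnot(inherits(planted, "rt_planted"))
  tr <- planted$truth
  hap1 <- planted$genome$seq
  hap2 <- hap1[setdiff(names(hap1), c(tr$chrA, tr$chrB))]
  hap2 <- c(hap2, planted$derived)
  list(hap1 = hap1, hap2 = hap2)
}

#' Simulate paired-end reads from a diploid sample
#'
#' Fragments are drawn uniformly from both haplotypes (each targeted at
#' half the configured coverage), insert sizes from the configured
#' lognormal, and reads of `read_len` bases are taken from both
#' fragment ends (read 2 reverse-complemented). The returned truth
#' table records each fragment's haplotype, source contig and
#' coordinates, from which junction spanning/crossing is derived.
#' Contigs shorter than twice the read length are skipped with a
#' warning.
#'
#' @param haps List of two named character vectors as returned by
#'   [carrier_haplotypes()].
#' @param config A [sim_config()].
#' @return Object of class `rt_reads`: list with `frags` (one row per
#'   fragment: qname, hap, contig, start, end, r1/r2 sequences) and the
#'   config.
#' @export
simulate_read_pairs <- function(haps, config = sim_config()) {
  rl <- config$read_len
  out <- list()
  for (h in 1:2) {
    contigs <- haps[[h]]
    lens <- nchar(contigs)
    ok <- lens >= 2L * rl
    if (any(!ok)) {
      warning(sprintf("skipping contig(s) shorter than one fragment: %s",
                      paste(names(contigs)[!ok], collapse = ", ")))
      contigs <- contigs[ok]; lens <- lens[ok]
    }
    n_frag <- round((config$coverage / 2) * sum(lens) / (2 * rl))
    frags <- with_seed(config$seed + h, {
      contig_idx <- sample.int(length(contigs), n_frag, replace = TRUE,
                               prob = lens)
      insert <- round(rlnorm(n_frag, log(config$insert_median),
                             config$insert_sdlog))
      insert <- pmax(2L * rl, pmin(insert, lens[contig_idx]))
      start <- 1L + floor(runif(n_frag) * (lens[contig_idx] - insert + 1L))
      data.frame(hap = h, contig = names(contigs)[contig_idx],
                 start = as.integer(start),
                 end = as.integer(start + insert - 1L),
                 stringsAsFactors = FALSE)
    })
    out[[h]] <- frags
  }
  frags <- rbind(out[[1]], out[[2]])
  frags$qname <- sprintf("frag%07d", seq_len(nrow(frags)))

  ## extract read sequences per contig (vectorized substring)
  frags$r1 <- NA_character_; frags$r2 <- NA_character_
  for (h in 1:2) {
    contigs <- haps[[h]]
    for (ct in unique(frags$contig[frags$hap == h])) {
      i <- which(frags$hap == h & frags$contig == ct)
      s <- contigs[[ct]]
      frags$r1[i] <- substring(s, frags$start[i], frags$start[i] + rl - 1L)
      frags$r2[i] <- revcomp(substring(s, frags$end[i] - rl + 1L, frags$end[i]))
    }
  }
  if (config$error_rate > 0)
    frags <- with_seed(config$seed + 7L, inject_errors(frags, config$error_rate))
  structure(list(frags = frags, config = config), class = "rt_reads")
}

inject_errors <- function(frags, rate) {
  for (col in c("r1", "r2")) {
    n_err <- rbinom(nrow(frags), nchar(frags[[col]]), rate)
    for (i in which(n_err > 0)) {
      s <- frags[[col]][i]
      pos <- sample.int(nchar(s), n_err[i])
      for (p in pos) {
        b <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(DNA_BASES, b), 1L)
      }
      frags[[col]][i] <- s
    }
  }
  frags
}

#' Annotate fragments with junction span/cross flags
#'
#' Adds to the fragment truth table whether each fragment overlaps a
#' junction of the planted translocation by at least one base
#' (`spans_junction`) and whether each of its reads crosses the
#' junction point itself (`r1_crosses`, `r2_crosses`).
#'
#' @param reads `rt_reads` object.
#' @param planted `rt_planted` carrier description.
#' @export
annotate_fragments <- function(reads, planted) {
  fr <- reads$frags
  rl <- reads$config$read_len
  fr$spans_junction <- FALSE
  fr$r1_crosses <- FALSE
  fr$r2_crosses <- FALSE
  for (mp_name in names(derived_maps(planted))) {
    mp <- derived_maps(planted)[[mp_name]]
    i <- fr$hap == 2L & fr$contig == mp_name
    jlo <- mp$x_len; jhi <- mp$x_len + mp$g + 1L
    fr$spans_junction[i] <- fr$start[i] <= jlo & fr$end[i] >= jhi
    r1e <- fr$start[i] + rl - 1L
    r2s <- fr$end[i] - rl + 1L
    fr$r1_crosses[i] <- fr$start[i] <= jlo & r1e >= jhi
    fr$r2_crosses[i] <- r2s <= jlo & fr$end[i] >= jhi
  }
  reads$frags <- fr
  reads
}

#' Randomly subsample fragments (both mates kept or dropped together)
#'
#' @param reads An `rt_reads` object.
#' @param fraction Fraction of fragments to keep, in (0, 1].
#' @param seed Integer seed.
#' @export
subsample_reads <- function(reads, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(reads)
  n <- nrow(reads$frags)
  keep <- with_seed(seed, sort(sample.int(n, round(fraction * n))))
  reads$frags <- reads$frags[keep, , drop = FALSE]
  reads
}

#' Write simulated reads as a FASTQ pair
#' @param reads An `rt_reads` object.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq <- function(reads, prefix) {
  fr <- reads$frags
  q <- strrep("I", reads$config$read_len)
  for (mate in 1:2) {
    col <- c("r1", "r2")[mate]
    lines <- as.vector(rbind(paste0("@", fr$qname, "/", mate),
                             fr[[col]], "+", q))
    writeLines(lines, sprintf("%s_%d.fastq", prefix, mate))
  }
  invisible(prefix)
}

#' Write a genome (or any named sequence set) as FASTA
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rt_genome")) seqs <- seqs$seq
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
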