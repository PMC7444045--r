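#' Published pig RT worked examples
#'
#' Breakpoint coordinates, connection types and junction architectures
#' of four balanced reciprocal translocations characterized at
#' base-pair resolution in the pig (Sus scrofa 11.1 assembly
#' coordinates): t(2;4), t(6;8), t(7;14) and t(1;16). `pos` is the
#' last retained base for a head segment and the first retained base
#' for a tail segment; `hom_ext1`/`hom_ext2` give the number of
#' microhomology bases by which retention effectively extends beyond
#' `pos` on each side (the homology bases are attributable to either
#' flank and are not lost).
#'
#' @return List with `junctions` (data frame, two rows per RT) and
#'   `chrom_lengths` (named vector of parent chromosome lengths, bp).
#' @export
pig_rt_examples <- function() {
  dir <- system.file("extdata", package = "rtdetect")
  jn <- read.delim(file.path(dir, "pig_rt_junctions.tsv"),
                   colClasses = c(chrom1 = "character",
                                  chrom2 = "character"))
  cl <- read.delim(file.path(dir, "sus_scrofa_11_1_chrom_lengths.tsv"),
                   colClasses = c(chrom = "character"))
  list(junctions = jn, chrom_lengths = setNames(cl$length_bp, cl$chrom))
}
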