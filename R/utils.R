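#' @import Biostrings
#' @importFrom stats median rbinom rlnorm runif setNames aggregate
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Reverse complement of one or more plain character sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Complement without reversing (used for single oriented bases).
complement_bases <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Run `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. All stochastic operations in the package
## route randomness through this helper so a pipeline seed fully
## determines the output.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

## Count mismatching positions between two equal-length sequences.
count_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## Length of the longest common prefix of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- charToRaw(substr(a, 1L, n))
  rb <- charToRaw(substr(b, 1L, n))
  neq <- which(ra != rb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## Round to `digits` decimals with ties away from zero (half-up), the
## convention used for megabase reporting.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Megabases at one decimal, half-up.
mb <- function(bp) round_half_up(bp / 1e6, 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a
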