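## VCF 4.2 BND interchange in the dialect emitted by hybrid structural
## variant callers: bracket ALT notation plus INFO keys CHR2, POS2, CT,
## PE, SR, MAPQ, SRQ and the PRECISE/IMPRECISE flags; FILTER is
## PASS/LowQual. The ALT bracket orientation is derived from the
## connection type so the two encodings can never disagree.

bnd_alt <- function(ref, chrom2, pos2, side, side2) {
  p <- sprintf("%s:%d", chrom2, pos2)
  if (side == "head" && side2 == "head") sprintf("%s]%s]", ref, p)
  else if (side == "head" && side2 == "tail") sprintf("%s[%s[", ref, p)
  else if (side == "tail" && side2 == "head") sprintf("]%s]%s", p, ref)
  else sprintf("[%s[%s", p, ref)
}

#' Write breakend calls as a BND VCF
#' @param calls `bnd_calls` data frame.
#' @param path Output path.
#' @param genome Optional `rt_genome` used for REF bases and contig
#'   header lines (REF is `N` without it).
#' @export
write_vcf <- function(calls, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=BND,Description=\"Breakend\">",
           "##FILTER=<ID=LowQual,Description=\"Low quality call\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner chromosome\">",
           "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Partner position\">",
           "##INFO=<ID=CT,Number=1,Type=String,Description=\"Connection type\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Supporting discordant pairs\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting split reads\">",
           "##INFO=<ID=MAPQ,Number=1,Type=Integer,Description=\"Median mapping quality\">",
           "##INFO=<ID=SRQ,Number=1,Type=Float,Description=\"Split-read consensus identity\">",
           "##INFO=<ID=POSALT,Number=1,Type=Integer,Description=\"Alternate (right-most) breakend position\">",
           "##INFO=<ID=POS2ALT,Number=1,Type=Integer,Description=\"Alternate partner position\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "##INFO=<ID=CONSENSUS,Number=1,Type=String,Description=\"Junction consensus sequence\">",
           "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Split-read refined\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Not split-read refined\">")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome$seq),
                          nchar(genome$seq)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  ref <- rep("N", nrow(calls))
  if (!is.null(genome)) {
    for (i in seq_len(nrow(calls)))
      if (calls$chrom[i] %in% names(genome$seq))
        ref[i] <- substr(genome$seq[[calls$chrom[i]]], calls$pos[i], calls$pos[i])
  }
  info <- sprintf(
    "SVTYPE=BND;%s;MATEID=%s;CHR2=%s;POS2=%d;CT=%s;PE=%d;SR=%d;MAPQ=%d%s;POSALT=%d;POS2ALT=%d;SAMPLE=%s%s%s",
    ifelse(calls$precise, "PRECISE", "IMPRECISE"),
    calls$mate_id, calls$chrom2, calls$pos2, calls$ct, calls$pe, calls$sr,
    calls$mapq,
    ifelse(is.na(calls$srq), "", sprintf(";SRQ=%.6g", calls$srq)),
    calls$pos_alt, calls$pos2_alt, calls$sample,
    ifelse(nzchar(calls$consensus), paste0(";CONSENSUS=", calls$consensus), ""),
    if (!is.null(calls$info_extra)) ifelse(nzchar(calls$info_extra),
                                           paste0(";", calls$info_extra), "")
    else "")
  alt <- character(nrow(calls))
  for (i in seq_len(nrow(calls)))
    alt[i] <- bnd_alt(ref[i], calls$chrom2[i], calls$pos2[i],
                      calls$side[i], calls$side2[i])
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s",
                   calls$chrom, calls$pos, calls$id, ref, alt,
                   calls$filter, info)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a BND VCF into a `bnd_calls` data frame
#'
#' Understands the caller dialect written by [write_vcf()] and the
#' corresponding fields of raw DELLY-style output (CHR2/CT/PE/SR/MAPQ/
#' SRQ, PRECISE/IMPRECISE, PASS/LowQual). Unknown INFO keys are kept
#' opaquely in `info_extra`. Records violating the precision invariant
#' (PRECISE with SR = 0) are demoted to imprecise with a warning;
#' records lacking partner coordinates are skipped with a warning.
#' @param path VCF path.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty_bnd_calls())
  known <- c("SVTYPE", "MATEID", "CHR2", "POS2", "CT", "PE", "SR", "MAPQ",
             "SRQ", "POSALT", "POS2ALT", "SAMPLE", "CONSENSUS",
             "PRECISE", "IMPRECISE")
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed VCF record at line %d",
                   which(lines == body[i])[1]))
    kv <- strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
    gi <- function(k, default = NA) {
      j <- match(k, keys); if (is.na(j)) default else vals[j]
    }
    chr2 <- gi("CHR2")
    pos2 <- gi("POS2")
    ## fall back to the bracket ALT for partner coordinates
    if (is.na(chr2) || is.na(pos2)) {
      mm <- regmatches(f[5], regexec("[][]([^:]+):([0-9]+)[][]", f[5]))[[1]]
      if (length(mm) == 3L) { chr2 <- chr2 %|NA|% mm[2]; pos2 <- pos2 %|NA|% mm[3] }
    }
    if (is.na(chr2) || is.na(pos2)) {
      warning(sprintf("skipping BND record '%s' without partner coordinates", f[3]))
      next
    }
    precise <- "PRECISE" %in% keys
    sr <- as.integer(gi("SR", "0"))
    if (precise && sr < 1L) {
      warning(sprintf("record '%s' flagged PRECISE without split reads; demoted to imprecise", f[3]))
      precise <- FALSE
    }
    ct <- gi("CT", NA)
    side <- side2 <- NA_character_
    if (!is.na(ct)) {
      s <- sides_from_ct(ct)
      if (f[1] <= chr2) { side <- s[1]; side2 <- s[2] }
      else { side <- s[2]; side2 <- s[1] }
    } else {
      ## derive CT from the ALT bracket
      alt <- f[5]
      side <- if (grepl("^[][]", alt)) "tail" else "head"
      side2 <- if (grepl("\\]", alt, fixed = FALSE)) "head" else "tail"
      ct <- if (f[1] <= chr2) ct_from_sides(f[1], side, chr2, side2)
            else ct_from_sides(chr2, side2, f[1], side)
    }
    extra <- keys[!(keys %in% known)]
    extra_s <- paste(vapply(which(!(keys %in% known)), function(j)
      if (nzchar(vals[j])) paste0(keys[j], "=", vals[j]) else keys[j],
      character(1)), collapse = ";")
    out[[i]] <- data.frame(
      id = f[3], mate_id = gi("MATEID", NA_character_),
      junction = sub("_[12]$", "", f[3]), sample = gi("SAMPLE", "S1"),
      chrom = f[1], pos = as.integer(f[2]),
      pos_alt = as.integer(gi("POSALT", f[2])), side = side,
      chrom2 = chr2, pos2 = as.integer(pos2),
      pos2_alt = as.integer(gi("POS2ALT", pos2)), side2 = side2,
      ct = ct, pe = as.integer(gi("PE", "0")), sr = sr,
      mapq = as.integer(gi("MAPQ", "0")),
      srq = as.numeric(gi("SRQ", NA)), precise = precise,
      filter = f[7], consensus = gi("CONSENSUS", ""),
      info_extra = extra_s, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_bnd_calls())
  rownames(res) <- NULL
  class(res) <- c("bnd_calls", "data.frame")
  res
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
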