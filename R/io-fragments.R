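# Fragment-record readers/writers. Two on-disk dialects:
#  * BEDPE (10 columns): chrom1 start1 end1 chrom2 start2 end2 name flagword
#    nm1 nm2. Mate 1 occupies [start1, start1+read_length) on chrom1, mate 2
#    [end2-read_length, end2) on chrom2; the template interval is
#    [start1, end2) and flagword bit 1 = concordant, bit 2 = ambiguous.
#  * BAM: coordinate-sorted, proper-pair flag = concordance, TLEN = insert,
#    NM tag = per-mate mismatch count, MAPQ 0 = ambiguous. Written via an
#    intermediate SAM text file.

bedpe_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "flagword", "nm1", "nm2")

#' Write fragment records to BEDPE or BAM
#'
#' @param fragments Fragment-record tibble, coordinate-sorted.
#' @param path Output file path.
#' @param format `"bedpe"` or `"bam"` (default guessed from the extension).
#' @param chrom_lengths Named integer vector; required for BAM (SAM header).
#' @param read_length Mate length used to lay out mate intervals, bp.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path,
                            format = c("auto", "bedpe", "bam"),
                            chrom_lengths = NULL, read_length = 50L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bedpe"
  }
  rl <- as.integer(read_length)
  if (format == "bedpe") {
    out <- tibble(
      chrom1 = fragments$chrom,
      start1 = fragments$start,
      end1 = pmin.int(fragments$start + rl, fragments$end),
      chrom2 = fragments$chrom2,
      start2 = pmax.int(fragments$end - rl, fragments$start),
      end2 = fragments$end,
      name = fragments$name,
      flagword = as.integer(fragments$concordant) +
        2L * as.integer(fragments$ambiguous),
      nm1 = fragments$nm1,
      nm2 = fragments$nm2
    )
    readr::write_tsv(out, path, col_names = TRUE)
    return(invisible(path))
  }
  # BAM via SAM text
  if (is.null(chrom_lengths)) {
    abort("chrom_lengths is required to write BAM (SAM header @SQ lines)")
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(fragments)) {
    mapq <- ifelse(fragments$ambiguous, 0L, 60L)
    proper <- ifelse(fragments$concordant, 2L, 0L)
    cigar <- sprintf("%dM", rl)
    pos1 <- fragments$start + 1L
    pos2 <- pmax.int(fragments$end - rl, fragments$start) + 1L
    l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*\tNM:i:%d",
                  fragments$name, 1L + proper + 32L + 64L, fragments$chrom,
                  pos1, mapq, cigar, fragments$chrom2, pos2,
                  fragments$template_length, fragments$nm1)
    l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*\tNM:i:%d",
                  fragments$name, 1L + proper + 16L + 128L, fragments$chrom2,
                  pos2, mapq, cigar, fragments$chrom, pos1,
                  -fragments$template_length, fragments$nm2)
    writeLines(as.vector(rbind(l1, l2)), con)
  }
  close(con)
  dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(path)
}

#' Read fragment records from BEDPE or BAM
#'
#' Records are returned sorted by (chrom, start, name); the tibble layout
#' matches [simulate_fragments()] output, so writing and re-reading a sample
#' is an identity on every field.
#'
#' @param path Input file.
#' @param format `"auto"` (from extension), `"bedpe"` or `"bam"`.
#' @param mapq_ambiguous BAM only: mates with MAPQ at or below this value are
#'   flagged as ambiguously mapped. Default 0.
#' @return Fragment-record tibble.
#' @export
read_fragments <- function(path, format = c("auto", "bedpe", "bam"),
                           mapq_ambiguous = 0L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bedpe"
  }
  if (format == "bedpe") {
    raw <- readr::read_tsv(path, col_types = "ciiciiciii", progress = FALSE)
    if (!identical(names(raw), bedpe_cols)) {
      abort(paste0("not a nucshift BEDPE file (expected columns: ",
                   paste(bedpe_cols, collapse = ", "), "): ", path))
    }
    bad <- which(raw$end2 <= raw$start1)
    if (length(bad)) {
      abort(paste0("malformed BEDPE: template end <= start at data line ",
                   bad[1], " of ", path))
    }
    out <- tibble(
      chrom = raw$chrom1,
      start = as.integer(raw$start1),
      end = as.integer(raw$end2),
      chrom2 = raw$chrom2,
      name = raw$name,
      concordant = bitwAnd(as.integer(raw$flagword), 1L) > 0L,
      ambiguous = bitwAnd(as.integer(raw$flagword), 2L) > 0L,
      nm1 = as.integer(raw$nm1),
      nm2 = as.integer(raw$nm2),
      template_length = as.integer(raw$end2 - raw$start1)
    )
  } else {
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "mrnm", "isize"),
      tag = "NM")
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    if (!length(b$qname)) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    chrom2 = character(), name = character(),
                    concordant = logical(), ambiguous = logical(),
                    nm1 = integer(), nm2 = integer(),
                    template_length = integer()))
    }
    first <- bitwAnd(b$flag, 64L) > 0L
    nm <- b$tag$NM
    nm2_map <- stats::setNames(nm[!first], b$qname[!first])
    qn <- b$qname[first]
    out <- tibble(
      chrom = as.character(b$rname[first]),
      start = b$pos[first] - 1L,
      end = b$pos[first] - 1L + b$isize[first],
      chrom2 = as.character(b$mrnm[first]),
      name = qn,
      concordant = bitwAnd(b$flag[first], 2L) > 0L,
      ambiguous = b$mapq[first] <= mapq_ambiguous,
      nm1 = as.integer(nm[first]),
      nm2 = as.integer(unname(nm2_map[qn])),
      template_length = as.integer(b$isize[first])
    )
  }
  arrange(out, .data$chrom, .data$start, .data$name)
}
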