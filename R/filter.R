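# Read-pair filtering: remove pairs that are discordant, inter-chromosomal,
# ambiguously mapped, have an insert size outside 120-200 bp, or more than 4
# mismatches in either mate. Removal is attributed to the FIRST failing class
# in that order, so per-class counts are deterministic.

FILTER_CLASSES <- c("discordant", "inter_chromosomal", "ambiguous",
                    "insert_out_of_range", "excess_mismatch")

# Per-record outcome: "kept" or the first failing removal class.
classify_pairs <- function(fragments, min_insert = 120L, max_insert = 200L,
                           max_mismatch = 4L) {
  bad <- fragments$concordant & fragments$end <= fragments$start
  if (any(bad)) {
    abort(paste0("malformed record(s): end <= start on concordant pair at ",
                 "index ", paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  dplyr::case_when(
    !fragments$concordant ~ "discordant",
    fragments$chrom != fragments$chrom2 ~ "inter_chromosomal",
    fragments$ambiguous ~ "ambiguous",
    fragments$template_length < min_insert |
      fragments$template_length > max_insert ~ "insert_out_of_range",
    fragments$nm1 > max_mismatch | fragments$nm2 > max_mismatch ~
      "excess_mismatch",
    TRUE ~ "kept"
  )
}

#' Filter aligned read pairs for nucleosome analysis
#'
#' Keeps a pair iff it is concordant, both mates map to the same chromosome,
#' it is not ambiguously mapped, its insert (template) length lies within
#' `[min_insert, max_insert]` (bounds inclusive), and neither mate has more
#' than `max_mismatch` mismatches. Removed pairs are attributed to the first
#' failing class, in the order discordant, inter-chromosomal, ambiguous,
#' insert out of range, excess mismatch. Kept records preserve input order.
#'
#' @param fragments A fragment-record tibble (see [simulate_fragments()] or
#'   [read_fragments()]).
#' @param min_insert,max_insert Retained insert-size range, bp (inclusive).
#' @param max_mismatch Maximum tolerated per-mate mismatch count.
#' @return The kept records, with a `filter_report` attribute; retrieve it
#'   with [filter_report()] or [glance()].
#' @export
filter_fragments <- function(fragments, min_insert = 120L, max_insert = 200L,
                             max_mismatch = 4L) {
  cls <- classify_pairs(fragments, min_insert, max_insert, max_mismatch)
  kept <- fragments[cls == "kept", , drop = FALSE]
  counts <- vapply(FILTER_CLASSES, function(k) sum(cls == k), integer(1))
  report <- tibble(
    input_pairs = nrow(fragments),
    kept_pairs = nrow(kept),
    discordant = counts[["discordant"]],
    inter_chromosomal = counts[["inter_chromosomal"]],
    ambiguous = counts[["ambiguous"]],
    insert_out_of_range = counts[["insert_out_of_range"]],
    excess_mismatch = counts[["excess_mismatch"]],
    min_insert_retained = if (nrow(kept)) min(kept$template_length) else NA_integer_,
    max_insert_retained = if (nrow(kept)) max(kept$template_length) else NA_integer_
  )
  attr(kept, "filter_report") <- report
  class(kept) <- c("filtered_fragments", class(kept))
  kept
}

#' Per-class removal statistics of a filtered fragment set
#'
#' @param x The result of [filter_fragments()].
#' @return A one-row tibble: input/kept pair counts, removed count per class,
#'   and the min/max retained insert size.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) abort("no filter_report attribute; was this produced by filter_fragments()?")
  rep
}

#' @rdname filter_report
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.filtered_fragments <- function(x, ...) filter_report(x)

#' Write a filter report as a tab-separated summary
#'
#' @param report A [filter_report()] tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
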