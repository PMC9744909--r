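# Per-gene promoter-window occupancy-difference statistics relative to the
# +1 nucleosome dyad, blacklist / merge / ordering / top-N logic.

# Strand-oriented genomic positions (0-based) for relative offsets:
# offset o maps to dyad + o on "+", dyad - o on "-", so index 1 is always
# the most upstream (most distal from the gene body) position.
oriented_positions <- function(dyad, strand, offsets) {
  s <- if (strand == "+") 1L else -1L
  dyad + s * offsets
}

#' Track values in a window relative to a +1 dyad
#'
#' For a `(-150, -50)` window the values cover the nucleosome-depleted
#' region upstream of the +1 nucleosome, inclusive bounds (101 values),
#' strand-oriented so the first value is always the most upstream position.
#'
#' @param track An `occupancy_track`.
#' @param anchors Gene-anchor tibble (`gene_id`, `chrom`, `strand`, `dyad`).
#' @param window Integer pair of inclusive offsets relative to the +1 dyad;
#'   negative = upstream on the gene's strand.
#' @return Long tibble: `gene_id`, `offset`, `pos` (genomic, 0-based),
#'   `value`. Genes whose window leaves the chromosome are dropped with a
#'   warning.
#' @export
relative_window_values <- function(track, anchors, window = c(-150L, -50L)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  offsets <- seq(as.integer(window[1]), as.integer(window[2]))
  res <- lapply(seq_len(nrow(anchors)), function(i) {
    ch <- anchors$chrom[i]
    if (!ch %in% names(track$chrom_lengths)) {
      abort(paste0("anchor chromosome not in track: ", ch))
    }
    pos <- oriented_positions(anchors$dyad[i], anchors$strand[i], offsets)
    if (min(pos) < 0L || max(pos) >= track$chrom_lengths[[ch]]) return(NULL)
    tibble(gene_id = anchors$gene_id[i], offset = offsets, pos = pos,
           value = track$score[[ch]][pos + 1L])
  })
  dropped <- anchors$gene_id[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    warn(paste0("window out of chromosome for ", length(dropped),
                " gene(s): ", paste(utils::head(dropped, 5), collapse = ", ")))
  }
  bind_rows(res)
}

#' Per-gene promoter-window occupancy difference
#'
#' For each gene, the mean over the strand-oriented relative window of
#' (test - reference) occupancy. Both tracks must be built with identical
#' parameters. Genes whose window leaves the chromosome are flagged
#' `excluded` with an `NA` statistic.
#'
#' @param test_track,ref_track `occupancy_track`s on the same chromosomes.
#' @param anchors Gene-anchor tibble.
#' @param window Inclusive offsets relative to the +1 dyad; default
#'   `c(-150, -50)`, the NDR interval scored for occupancy gain.
#' @param comparison Optional label stored in the result.
#' @return A `gene_stat` tibble: `gene_id`, `chrom`, `strand`, `dyad`,
#'   `stat`, `excluded`, `excluded_reason`, `comparison`.
#' @export
window_stat <- function(test_track, ref_track, anchors,
                        window = c(-150L, -50L), comparison = NA_character_) {
  if (!setequal(names(test_track$chrom_lengths),
                names(ref_track$chrom_lengths)) ||
      !identical(test_track$chrom_lengths[names(ref_track$chrom_lengths)],
                 ref_track$chrom_lengths)) {
    abort("test and reference tracks cover different chromosome sets")
  }
  offsets <- seq(as.integer(window[1]), as.integer(window[2]))
  stat <- rep(NA_real_, nrow(anchors))
  excluded <- logical(nrow(anchors))
  reason <- rep(NA_character_, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    if (!ch %in% names(test_track$chrom_lengths)) {
      abort(paste0("anchor chromosome not in tracks: ", ch))
    }
    pos <- oriented_positions(anchors$dyad[i], anchors$strand[i], offsets)
    if (min(pos) < 0L || max(pos) >= test_track$chrom_lengths[[ch]]) {
      excluded[i] <- TRUE
      reason[i] <- "window_out_of_chromosome"
      next
    }
    idx <- pos + 1L
    stat[i] <- mean(test_track$score[[ch]][idx] -
                      ref_track$score[[ch]][idx])
  }
  if (any(excluded)) {
    warn(paste0(sum(excluded), " gene(s) excluded: window out of chromosome"))
  }
  out <- tibble(gene_id = anchors$gene_id, chrom = anchors$chrom,
                strand = anchors$strand, dyad = anchors$dyad,
                stat = stat, excluded = excluded, excluded_reason = reason,
                comparison = comparison)
  class(out) <- c("gene_stat", class(out))
  out
}

#' Blacklist genes below an occupancy-gain threshold
#'
#' Returns the genes that did not achieve more than `threshold` mean
#' occupancy difference (statistic <= threshold, strict "more than"
#' retained for keeping), plus any excluded genes. These rows are removed
#' from heatmaps.
#'
#' @param stats A [window_stat()] table.
#' @param threshold Occupancy-difference threshold, normalized units.
#' @return Sorted character vector of blacklisted gene ids.
#' @export
blacklist_genes <- function(stats, threshold = 0.6) {
  sort(stats$gene_id[stats$excluded | !(stats$stat > threshold)])
}

#' Merge blacklists without duplication
#'
#' @param ... Character vectors of gene ids, or a single list of them.
#' @return Sorted set union.
#' @export
merge_blacklists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  sort(unique(unlist(lists, use.names = FALSE)))
}

#' Order genes by decreasing occupancy difference
#'
#' Descending by statistic; ties broken by gene id (lexicographic, stable),
#' so orderings are reproducible and can be applied to matrices from other
#' comparisons. Excluded genes are dropped.
#'
#' @param stats A [window_stat()] table.
#' @return Character vector of gene ids, best (largest gain) first.
#' @export
order_genes <- function(stats) {
  s <- stats[!stats$excluded, , drop = FALSE]
  s$gene_id[order(-s$stat, s$gene_id, method = "radix")]
}

#' Top-N genes by occupancy gain, with optional baseline subtraction
#'
#' Ranks genes by the window statistic, after subtracting a per-gene
#' baseline statistic (a control comparison) when one is given, and returns
#' the first `n`.
#'
#' @param stats A [window_stat()] table for the comparison of interest.
#' @param n Number of genes to return.
#' @param baseline_stats Optional [window_stat()] table whose per-gene
#'   statistic is subtracted before ranking.
#' @return Character vector of at most `n` gene ids.
#' @export
top_n_genes <- function(stats, n = 500L, baseline_stats = NULL) {
  if (n <= 0) abort("n must be positive")
  s <- stats[!stats$excluded, , drop = FALSE]
  if (!is.null(baseline_stats)) {
    missing <- setdiff(s$gene_id,
                       baseline_stats$gene_id[!baseline_stats$excluded])
    if (length(missing)) {
      abort(paste0("baseline_stats missing gene(s): ",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    base <- stats::setNames(baseline_stats$stat, baseline_stats$gene_id)
    s$stat <- s$stat - unname(base[s$gene_id])
  }
  ordered <- s$gene_id[order(-s$stat, s$gene_id, method = "radix")]
  if (length(ordered) < n) {
    warn(paste0("only ", length(ordered), " genes available for top-", n))
    return(ordered)
  }
  ordered[seq_len(n)]
}

#' Write / read a gene statistic table
#'
#' @param stats A [window_stat()] table (optionally with rank / blacklist
#'   columns added).
#' @param path TSV path.
#' @return `path` (write) or the tibble (read), invisibly for write.
#' @export
write_gene_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}
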