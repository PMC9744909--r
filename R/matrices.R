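# +1-dyad-anchored per-gene signal matrices, differential log2 matrices,
# heatmap assembly (blacklist + ordering) and average profiles.

new_anchored_matrix <- function(values, flank, label = NA_character_,
                                pseudocount = NA_real_) {
  colnames(values) <- as.character(seq(-flank, flank))
  structure(values, class = c("anchored_matrix", class(values)),
            flank = as.integer(flank), label = label,
            pseudocount = pseudocount)
}

#' +1-dyad-anchored signal matrix
#'
#' Row `g`, column `j` holds the track value at `dyad + j` for a `+` strand
#' gene and `dyad - j` for a `-` strand gene, so rows are strand-oriented
#' with upstream (the NDR side) on the left. Genes whose window overruns a
#' chromosome end are excluded with a warning.
#'
#' @param track An `occupancy_track`.
#' @param anchors Gene-anchor tibble.
#' @param flank Half-width of the window around the dyad, bp.
#' @param label Optional condition/comparison label.
#' @return An `anchored_matrix` (genes x `2 * flank + 1` positions) with the
#'   gene ids as row names.
#' @export
anchored_matrix <- function(track, anchors, flank = 500L,
                            label = NA_character_) {
  if (flank <= 0) abort("flank must be positive")
  flank <- as.integer(flank)
  offsets <- seq(-flank, flank)
  keep <- logical(nrow(anchors))
  rows <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    if (!ch %in% names(track$chrom_lengths)) {
      abort(paste0("anchor chromosome not in track: ", ch))
    }
    pos <- oriented_positions(anchors$dyad[i], anchors$strand[i], offsets)
    if (min(pos) < 0L || max(pos) >= track$chrom_lengths[[ch]]) next
    keep[i] <- TRUE
    rows[[i]] <- track$score[[ch]][pos + 1L]
  }
  if (any(!keep)) {
    warn(paste0(sum(!keep), " gene(s) excluded from anchored matrix: ",
                "window overruns chromosome end"))
  }
  m <- do.call(rbind, rows[keep])
  if (is.null(m)) m <- matrix(numeric(), nrow = 0, ncol = length(offsets))
  rownames(m) <- anchors$gene_id[keep]
  new_anchored_matrix(m, flank, label)
}

#' @export
print.anchored_matrix <- function(x, ...) {
  cat("<anchored_matrix> ", nrow(x), " genes x ", ncol(x),
      " positions (flank ", attr(x, "flank"), " bp)",
      if (!is.na(attr(x, "label"))) paste0(" [", attr(x, "label"), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname anchored_matrix
#' @param x An `anchored_matrix`.
#' @param ... Unused.
#' @return `tidy()`: long tibble (`gene_id`, `position`, `value`).
#' @exportS3Method generics::tidy
tidy.anchored_matrix <- function(x, ...) {
  flank <- attr(x, "flank")
  tibble(gene_id = rep(rownames(x), each = ncol(x)),
         position = rep(seq(-flank, flank), times = nrow(x)),
         value = as.vector(t(unclass(x))))
}

#' Entrywise log2 ratio of two anchored matrices
#'
#' `log2((test + pseudocount) / (ref + pseudocount))`; the display scale of
#' differential heatmaps. Statistics stay on the linear occupancy scale.
#'
#' @param test,ref `anchored_matrix` objects with identical genes and flank.
#' @param pseudocount Added to both matrices before the ratio; guards
#'   zero-occupancy positions.
#' @param label Optional comparison label.
#' @return An `anchored_matrix` of log2 ratios.
#' @export
log2_ratio_matrix <- function(test, ref, pseudocount = 1, label = NA_character_) {
  if (!identical(dim(test), dim(ref)) ||
      !identical(rownames(test), rownames(ref)) ||
      !identical(attr(test, "flank"), attr(ref, "flank"))) {
    abort("test and ref matrices differ in genes, shape or flank")
  }
  vals <- log2((unclass(test) + pseudocount) / (unclass(ref) + pseudocount))
  new_anchored_matrix(vals, attr(test, "flank"), label, pseudocount)
}

#' Assemble a heatmap matrix: apply blacklist and gene ordering
#'
#' Selects the rows of `ordering` that are not blacklisted, in that order;
#' values are untouched (pure row selection), so an ordering computed on one
#' comparison can be applied to the matrices of all others.
#'
#' @param mat An `anchored_matrix` (typically a log2 ratio matrix).
#' @param ordering Character vector of gene ids, e.g. from [order_genes()].
#' @param blacklist Gene ids to drop, e.g. from [merge_blacklists()].
#' @return The reordered `anchored_matrix`.
#' @export
assemble_heatmap <- function(mat, ordering, blacklist = character()) {
  rows <- setdiff(ordering, blacklist)
  missing <- setdiff(setdiff(rownames(mat), blacklist), ordering)
  if (length(missing)) {
    abort(paste0("ordering is missing gene(s) present in the matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  rows <- rows[rows %in% rownames(mat)]
  if (!length(rows)) {
    warn("all genes blacklisted: empty heatmap")
  }
  out <- unclass(mat)[rows, , drop = FALSE]
  new_anchored_matrix(out, attr(mat, "flank"), attr(mat, "label"),
                      attr(mat, "pseudocount"))
}

#' Average occupancy profile over a gene set
#'
#' Column-wise mean of the strand-oriented anchored signal over a gene
#' subset, one curve per condition.
#'
#' @param tracks A named list of `occupancy_track`s (names = condition
#'   labels), or a single track.
#' @param anchors Gene-anchor tibble.
#' @param gene_set Gene ids to average over; must be a subset of the
#'   anchors.
#' @param flank Half-width around the dyad, bp.
#' @return Long tibble: `position` (relative to +1 dyad), `condition`,
#'   `occupancy`.
#' @export
average_profile <- function(tracks, anchors, gene_set = anchors$gene_id,
                            flank = 500L) {
  if (!length(gene_set)) abort("gene_set is empty")
  if (inherits(tracks, "occupancy_track")) tracks <- list(track = tracks)
  missing <- setdiff(gene_set, anchors$gene_id)
  if (length(missing)) {
    abort(paste0("gene_set contains unknown gene(s): ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  sub <- anchors[anchors$gene_id %in% gene_set, , drop = FALSE]
  bind_rows(lapply(names(tracks), function(cond) {
    m <- anchored_matrix(tracks[[cond]], sub, flank = flank, label = cond)
    tibble(position = seq(-attr(m, "flank"), attr(m, "flank")),
           condition = cond,
           occupancy = unname(colMeans(unclass(m))))
  }))
}

#' Write an anchored matrix as TSV
#'
#' Gene ids in the first column, one column per relative position (header
#' row gives the offsets). The numeric matrix is the testable artifact; any
#' rendered image is decorative.
#'
#' @param mat An `anchored_matrix`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- as.data.frame(unclass(mat), check.names = FALSE)
  df <- cbind(gene_id = rownames(mat), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
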