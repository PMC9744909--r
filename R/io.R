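# Shared readers/writers: BED6 gene anchors, one-id-per-line gene lists,
# FASTA genomes. BED semantics are 0-based half-open throughout.

#' Write / read +1-dyad gene anchors as BED6
#'
#' Columns: chrom, dyadStart, dyadStart + 1, geneID, 0, strand (0-based
#' half-open single-bp interval at the +1 nucleosome dyad).
#'
#' @param anchors Gene-anchor tibble (`gene_id`, `chrom`, `strand`, `dyad`).
#' @param path BED file path.
#' @return `path` invisibly (write); anchors tibble (read).
#' @export
write_anchors <- function(anchors, path) {
  out <- tibble(chrom = anchors$chrom, start = anchors$dyad,
                end = anchors$dyad + 1L, name = anchors$gene_id,
                score = 0L, strand = anchors$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": expected >= 6 tab-separated fields"))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": non-integer coordinates"))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": start >= end"))
  }
  bad <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad)) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": strand must be + or -"))
  }
  anchors <- tibble(gene_id = m[, 4], chrom = m[, 1], strand = m[, 6],
                    dyad = start)
  if (anyDuplicated(anchors$gene_id)) {
    abort(paste0("duplicate gene ids in ", path))
  }
  anchors
}

#' Write / read a gene list (one id per line)
#'
#' @param gene_ids Character vector.
#' @param path Text file path.
#' @return `path` invisibly (write); character vector with set semantics,
#'   duplicates dropped with a warning (read).
#' @export
write_gene_list <- function(gene_ids, path) {
  readr::write_lines(gene_ids, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  ids <- readr::read_lines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warn(paste0("duplicate gene ids in ", path, "; de-duplicating"))
    ids <- unique(ids)
  }
  ids
}

#' Write a simulated genome as FASTA
#'
#' @param annotation A [simulate_annotation()] result with sequences.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(annotation, path) {
  if (is.null(annotation$genome)) {
    abort("annotation carries no sequence; rerun simulate_annotation(emit_sequence = TRUE)")
  }
  Biostrings::writeXStringSet(annotation$genome, path)
  invisible(path)
}
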