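# Count-normalized, smoothed fragment-midpoint occupancy tracks at 1-bp
# resolution. Semantics: each fragment midpoint is extended to a `width`-bp
# footprint window, the raw coverage is scaled to a common effective library
# size (`target_count`), then smoothed with a centered moving average of
# `smooth_width` bp. Order of operations is extend -> scale -> smooth;
# scaling and smoothing commute, extension does not.

#' Fragment midpoints (dyad positions)
#'
#' The midpoint of the 0-based half-open template interval `[start, end)`,
#' `floor((start + end) / 2)`; for MNase-protected fragments this
#' approximates the nucleosome dyad.
#'
#' @param fragments Filtered fragment-record tibble.
#' @return Tibble with `chrom` and `midpoint` (0-based).
#' @export
fragment_midpoints <- function(fragments) {
  tibble(chrom = fragments$chrom,
         midpoint = as.integer((fragments$start + fragments$end) %/% 2L))
}

# Centered moving average of window `sw` with truncated edge windows (mean
# over the available positions). For even sw the window is
# [i - sw/2, i + sw/2 - 1].
moving_average <- function(x, sw) {
  sw <- as.integer(sw)
  if (sw <= 1L) return(x)
  n <- length(x)
  lo_off <- sw %/% 2L
  hi_off <- sw - lo_off - 1L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax.int(1L, i - lo_off)
  hi <- pmin.int(n, i + hi_off)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Footprint extension: position p receives one count per midpoint m with
# p in [m - width%/%2, m - width%/%2 + width - 1].
extend_counts <- function(midpoint_counts, width) {
  n <- length(midpoint_counts)
  hw <- width %/% 2L
  cs <- c(0, cumsum(midpoint_counts))
  i <- seq_len(n)
  lo <- pmax.int(1L, i - (width - hw - 1L))
  hi <- pmin.int(n, i + hw)
  cs[hi + 1L] - cs[lo]
}

#' Build a normalized smoothed occupancy track
#'
#' Each midpoint contributes 1 to every position of the `width`-bp window
#' `[m - width/2, m + width/2)` (truncated at chromosome ends); the raw track
#' is scaled by `target_count / n_fragments_used` and then smoothed with a
#' centered `smooth_width`-bp moving average (edge windows truncated). The
#' output has 1-bp span. `smooth_width = 1` disables smoothing.
#'
#' @param midpoints Tibble from [fragment_midpoints()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Footprint extension around each midpoint, bp.
#' @param smooth_width Moving-average window, bp.
#' @param target_count Effective library size the track is scaled to.
#' @return An `occupancy_track`: per-chromosome numeric vectors plus the
#'   parameters used, in normalized effective-fragments-per-bp units.
#' @export
build_track <- function(midpoints, chrom_lengths, width = 40L,
                        smooth_width = 20L, target_count = 1e7) {
  stopifnot(width >= 1, smooth_width >= 1, target_count > 0,
            !is.null(names(chrom_lengths)))
  unknown <- setdiff(unique(midpoints$chrom), names(chrom_lengths))
  if (length(unknown)) {
    abort(paste0("midpoints on chromosome(s) absent from chrom_lengths: ",
                 paste(unknown, collapse = ", ")))
  }
  oob <- which(midpoints$midpoint < 0L |
                 midpoints$midpoint >= chrom_lengths[midpoints$chrom])
  if (length(oob)) {
    abort(paste0("midpoint outside chromosome at record ", oob[1], " (",
                 midpoints$chrom[oob[1]], ":", midpoints$midpoint[oob[1]], ")"))
  }
  n_used <- nrow(midpoints)
  scale_f <- if (n_used > 0) target_count / n_used else 0
  if (n_used == 0) {
    warn("no fragments used; returning an all-zero track")
  }
  score <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    pos <- midpoints$midpoint[midpoints$chrom == ch]
    if (!length(pos)) return(numeric(L))
    cnt <- tabulate(pos + 1L, nbins = L)
    ext <- extend_counts(cnt, as.integer(width))
    moving_average(ext * scale_f, as.integer(smooth_width))
  })
  names(score) <- names(chrom_lengths)
  structure(list(score = score,
                 chrom_lengths = stats::setNames(as.integer(chrom_lengths),
                                                 names(chrom_lengths)),
                 width = as.integer(width),
                 smooth_width = as.integer(smooth_width),
                 target_count = target_count,
                 n_fragments_used = n_used),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat("<occupancy_track> ", length(x$score), " chromosome(s), ",
      sum(as.numeric(x$chrom_lengths)), " bp; ", x$n_fragments_used,
      " fragments, width ", x$width, ", smooth ", x$smooth_width,
      ", target count ", format(x$target_count, scientific = FALSE),
      "\n", sep = "")
  invisible(x)
}

#' @rdname build_track
#' @param x An `occupancy_track`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`chrom`, `pos` 0-based, `score`);
#'   `glance()`: a one-row tibble of the track parameters.
#' @exportS3Method generics::tidy
tidy.occupancy_track <- function(x, ...) {
  bind_rows(lapply(names(x$score), function(ch) {
    tibble(chrom = ch, pos = seq_along(x$score[[ch]]) - 1L,
           score = x$score[[ch]])
  }))
}

#' @rdname build_track
#' @exportS3Method generics::glance
glance.occupancy_track <- function(x, ...) {
  tibble(n_chromosomes = length(x$score),
         genome_bp = sum(as.numeric(x$chrom_lengths)),
         width = x$width, smooth_width = x$smooth_width,
         target_count = x$target_count,
         n_fragments_used = x$n_fragments_used)
}

track_to_granges <- function(track) {
  si <- GenomeInfoDb::Seqinfo(names(track$chrom_lengths),
                              unname(track$chrom_lengths))
  grl <- lapply(names(track$score), function(ch) {
    r <- S4Vectors::Rle(track$score[[ch]])
    len <- S4Vectors::runLength(r)
    ends <- cumsum(len)
    GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = ends - len + 1L, end = ends),
      score = S4Vectors::runValue(r),
      seqinfo = si)
  })
  do.call(c, grl)
}

#' Write / read an occupancy track
#'
#' Tracks are serialized as run-length-encoded 0-based half-open intervals,
#' in bedGraph (text) or bigWig (binary) form.
#'
#' @param track An `occupancy_track`.
#' @param path Output file.
#' @param format `"auto"` (from extension), `"bedGraph"` or `"bigWig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("auto", "bedGraph", "bigWig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig" else "bedGraph"
  }
  gr <- track_to_granges(track)
  if (format == "bedGraph") {
    rtracklayer::export.bedGraph(gr, path)
  } else {
    rtracklayer::export.bw(gr, path)
  }
  invisible(path)
}

#' @rdname write_track
#' @param chrom_lengths Named integer vector giving the full chromosome
#'   lengths of the track being read.
#' @export
read_track <- function(path, chrom_lengths,
                       format = c("auto", "bedGraph", "bigWig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = if (format == "bigWig") "bigWig"
                            else "bedGraph")
  score <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(sel)) {
      st <- GenomicRanges::start(sel)
      en <- GenomicRanges::end(sel)
      sc <- sel$score
      for (i in seq_along(sel)) v[st[i]:en[i]] <- sc[i]
    }
    v
  })
  names(score) <- names(chrom_lengths)
  structure(list(score = score,
                 chrom_lengths = stats::setNames(as.integer(chrom_lengths),
                                                 names(chrom_lengths)),
                 width = NA_integer_, smooth_width = NA_integer_,
                 target_count = NA_real_, n_fragments_used = NA_integer_),
            class = "occupancy_track")
}
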