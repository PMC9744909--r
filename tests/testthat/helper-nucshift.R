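# Shared fixtures, all built in code.

# A compact two-chromosome design that runs in well under a second.
small_config <- function(...) {
  defaults <- list(n_chromosomes = 2L, chrom_length = 60000L, n_genes = 40L,
                   n_fragments_per_sample = 8000L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# One fragment record with overridable fields.
make_frag <- function(start = 1000L, len = 150L, chrom = "chrA",
                      chrom2 = chrom, concordant = TRUE, ambiguous = FALSE,
                      nm1 = 0L, nm2 = 0L, name = "f1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + len), chrom2 = chrom2,
                 name = name, concordant = concordant, ambiguous = ambiguous,
                 nm1 = as.integer(nm1), nm2 = as.integer(nm2),
                 template_length = as.integer(len))
}

# Hand-built occupancy track from explicit per-chromosome value vectors.
manual_track <- function(score_list, width = 40L, smooth_width = 20L,
                         target_count = 1e7, n_fragments_used = 1L) {
  structure(list(
    score = score_list,
    chrom_lengths = stats::setNames(as.integer(lengths(score_list)),
                                    names(score_list)),
    width = as.integer(width), smooth_width = as.integer(smooth_width),
    target_count = target_count, n_fragments_used = n_fragments_used),
    class = "occupancy_track")
}

constant_track <- function(value, chrom_lengths) {
  manual_track(lapply(chrom_lengths, function(L) rep(value, L)))
}

# Independent one-record-at-a-time re-check of the five filter predicates,
# in the documented attribution order. Deliberately scalar.
naive_filter_class <- function(rec) {
  if (!rec$concordant) return("discordant")
  if (rec$chrom != rec$chrom2) return("inter_chromosomal")
  if (rec$ambiguous) return("ambiguous")
  if (rec$template_length < 120 || rec$template_length > 200) {
    return("insert_out_of_range")
  }
  if (rec$nm1 > 4 || rec$nm2 > 4) return("excess_mismatch")
  "kept"
}

# Per-gene count of clean fragments whose midpoint falls in the genomic NDR
# window, by direct counting over emitted records.
ndr_counts_by_gene <- function(sample, anchors, ndr_window = c(-160L, -20L)) {
  frag <- sample$fragments
  clean <- sample$truth$fragment_sources$class == "clean"
  mid <- (frag$start + frag$end) %/% 2L
  vapply(seq_len(nrow(anchors)), function(i) {
    s <- if (anchors$strand[i] == "+") 1L else -1L
    w <- sort(anchors$dyad[i] + s * ndr_window)
    sum(clean & frag$chrom == anchors$chrom[i] & mid >= w[1] & mid <= w[2])
  }, numeric(1))
}
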