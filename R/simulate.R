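# Synthetic paired-end MNase-seq generator: toy genome, +1-dyad annotation,
# and aligned fragment records with phased nucleosome arrays, promoter NDRs,
# a conditional NDR-filling perturbation, and injected filter-failing pairs.

#' Configuration for the synthetic MNase-seq generator
#'
#' Bundles and validates every knob of the simulator. The defaults describe a
#' compact genome with the statistical structure the downstream analysis
#' assumes: phased ~165-bp nucleosome arrays downstream of each gene's +1
#' dyad, a nucleosome-depleted region (NDR) upstream of the +1 dyad, and a
#' perturbed ("degron") condition in which the NDRs of an affected gene
#' subset gain occupancy.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of every chromosome, bp.
#' @param n_genes Total number of genes, distributed round-robin over
#'   chromosomes.
#' @param ndr_window Two integers, the NDR interval relative to the +1 dyad
#'   on the gene's strand (negative = upstream). Default `c(-160, -20)`.
#' @param nucleosome_spacing Dyad-to-dyad spacing of the phased array, bp.
#' @param n_nucleosomes Nucleosomes per array (the +1 and its successors).
#' @param dyad_jitter_sd Gaussian positional jitter of fragment midpoints
#'   around each nucleosome dyad, bp.
#' @param fragment_length_mean,fragment_length_sd Clean fragment length
#'   distribution (normal, truncated to 121..199 bp so that only injected
#'   contaminants probe the 120/200 filter boundaries).
#' @param n_fragments_per_sample Total records emitted per sample, clean plus
#'   contaminants.
#' @param affected_gene_fraction Fraction of genes whose NDR gains occupancy
#'   in the perturbed condition.
#' @param ndr_baseline_weight Source weight of the NDR relative to a single
#'   nucleosome (weight 1) in the baseline condition.
#' @param ndr_fill_effect Weight added to the NDR source of affected genes in
#'   the perturbed condition only. The default fills the NDR to 5x its
#'   baseline weight.
#' @param background_fraction Fraction of clean fragments drawn uniformly
#'   from the genome rather than from gene sources.
#' @param contaminant_rates Named proportions of filter-failing pairs:
#'   `discordant`, `inter_chromosomal`, `short_insert` (< 120 bp),
#'   `long_insert` (> 200 bp), `high_mismatch` (> 4 mismatches in one mate).
#'   Each contaminant class fails exactly one filter predicate.
#' @param gene_footprint Minimum dyad-to-dyad distance between neighbouring
#'   genes, bp.
#' @param edge_flank Minimum distance of any +1 dyad from a chromosome end, bp.
#' @param read_length Mate read length recorded in emitted alignments, bp.
#' @param strands `"alternate"`, `"plus"` or `"minus"` gene strand layout.
#' @param seed Integer seed; identical configs give bitwise-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 300000L,
                       n_genes = 200L,
                       ndr_window = c(-160L, -20L),
                       nucleosome_spacing = 165L,
                       n_nucleosomes = 5L,
                       dyad_jitter_sd = 20,
                       fragment_length_mean = 150,
                       fragment_length_sd = 15,
                       n_fragments_per_sample = 50000L,
                       affected_gene_fraction = 0.1,
                       ndr_baseline_weight = 0.2,
                       ndr_fill_effect = 0.8,
                       background_fraction = 0.1,
                       contaminant_rates = c(discordant = 0, inter_chromosomal = 0,
                                             short_insert = 0, long_insert = 0,
                                             high_mismatch = 0),
                       gene_footprint = 1000L,
                       edge_flank = 1000L,
                       read_length = 50L,
                       strands = c("alternate", "plus", "minus"),
                       seed = 1L) {
  strands <- match.arg(strands)
  cls <- c("discordant", "inter_chromosomal", "short_insert", "long_insert",
           "high_mismatch")
  rates <- c(discordant = 0, inter_chromosomal = 0, short_insert = 0,
             long_insert = 0, high_mismatch = 0)
  if (length(contaminant_rates)) {
    if (is.null(names(contaminant_rates)) ||
        !all(names(contaminant_rates) %in% cls)) {
      abort(paste0("contaminant_rates must be named among: ",
                   paste(cls, collapse = ", ")))
    }
    rates[names(contaminant_rates)] <- contaminant_rates
  }
  stopifnot(
    n_chromosomes >= 1, chrom_length >= 1, n_genes >= 0,
    length(ndr_window) == 2, ndr_window[1] < ndr_window[2],
    nucleosome_spacing > 0, n_nucleosomes >= 1,
    dyad_jitter_sd >= 0, fragment_length_sd > 0,
    n_fragments_per_sample >= 0,
    affected_gene_fraction >= 0, affected_gene_fraction <= 1,
    ndr_baseline_weight >= 0, ndr_fill_effect >= 0,
    background_fraction >= 0, background_fraction < 1,
    all(rates >= 0), all(rates <= 1),
    gene_footprint > 0, edge_flank >= 0, read_length >= 1
  )
  if (sum(rates) >= 1) {
    abort("sum of contaminant rates must be < 1")
  }
  if (rates[["inter_chromosomal"]] > 0 && n_chromosomes < 2) {
    abort("inter_chromosomal contaminants need at least 2 chromosomes")
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    ndr_window = as.integer(ndr_window),
    nucleosome_spacing = as.integer(nucleosome_spacing),
    n_nucleosomes = as.integer(n_nucleosomes),
    dyad_jitter_sd = dyad_jitter_sd,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    n_fragments_per_sample = as.integer(n_fragments_per_sample),
    affected_gene_fraction = affected_gene_fraction,
    ndr_baseline_weight = ndr_baseline_weight,
    ndr_fill_effect = ndr_fill_effect,
    background_fraction = background_fraction,
    contaminant_rates = rates,
    gene_footprint = as.integer(gene_footprint),
    edge_flank = as.integer(edge_flank),
    read_length = as.integer(read_length),
    strands = strands,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes on ", x$n_chromosomes,
      " x ", x$chrom_length, " bp; ", x$n_fragments_per_sample,
      " fragments/sample; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

chrom_names <- function(config) {
  sprintf("chrSim%d", seq_len(config$n_chromosomes))
}

#' Generate a toy genome and +1-dyad gene annotation
#'
#' Places `n_genes` non-overlapping genes round-robin over the chromosomes,
#' each represented by its +1 nucleosome dyad coordinate and strand. Dyads
#' are laid out on a regular grid so neighbouring dyads are at least
#' `gene_footprint` apart and every dyad is at least `edge_flank` from a
#' chromosome end. Optionally emits a random nucleotide sequence per
#' chromosome (the pipeline itself only consumes coordinates).
#'
#' @param config A [sim_config()].
#' @param emit_sequence Generate random chromosome sequences? Set `FALSE`
#'   for large genomes where only coordinates are needed.
#' @return A list of class `mnase_annotation` with elements `anchors` (a
#'   tibble: `gene_id`, `chrom`, `strand`, `dyad`; 0-based dyad coordinate),
#'   `chrom_lengths` (named integer vector) and `genome`
#'   (a [Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_annotation <- function(config, emit_sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- chrom_names(config)
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                                   chroms)
  n <- config$n_genes
  if (n > 0) {
    gene_chrom_idx <- ((seq_len(n) - 1L) %% config$n_chromosomes) + 1L
    per_chrom <- tabulate(gene_chrom_idx, nbins = config$n_chromosomes)
    usable <- config$chrom_length - 2L * config$edge_flank
    need <- max(per_chrom) * config$gene_footprint
    if (usable <= 0 || need > usable) {
      abort(paste0(
        "genome too small for n_genes: ", max(per_chrom), " genes per ",
        config$chrom_length, " bp chromosome need ", need,
        " usable bp (gene_footprint ", config$gene_footprint,
        ", edge_flank ", config$edge_flank, ") but only ",
        max(0L, usable), " available"))
    }
    within_idx <- stats::ave(seq_len(n), gene_chrom_idx, FUN = seq_along)
    slot <- usable %/% per_chrom[gene_chrom_idx]
    dyad <- config$edge_flank + (within_idx - 1L) * slot + slot %/% 2L
    strand <- switch(config$strands,
      alternate = rep_len(c("+", "-"), n),
      plus = rep("+", n),
      minus = rep("-", n))
    anchors <- tibble(
      gene_id = sprintf("gene%04d", seq_len(n)),
      chrom = chroms[gene_chrom_idx],
      strand = strand,
      dyad = as.integer(dyad)
    )
    anchors <- arrange(anchors, .data$chrom, .data$dyad)
  } else {
    anchors <- tibble(gene_id = character(), chrom = character(),
                      strand = character(), dyad = integer())
  }
  genome <- NULL
  if (emit_sequence) {
    genome <- withr::with_seed(config$seed, {
      seqs <- vapply(chroms, function(ch) {
        paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                     replace = TRUE), collapse = "")
      }, character(1))
      Biostrings::DNAStringSet(seqs)
    })
    names(genome) <- chroms
  }
  structure(list(anchors = anchors, chrom_lengths = chrom_lengths,
                 genome = genome),
            class = "mnase_annotation")
}

#' @export
print.mnase_annotation <- function(x, ...) {
  cat("<mnase_annotation> ", nrow(x$anchors), " genes on ",
      length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  invisible(x)
}

# Genes whose NDR fills in the perturbed condition; drawn once from the
# config seed so baseline and perturbed samples share the same set.
affected_genes <- function(anchors, config) {
  k <- round(config$affected_gene_fraction * nrow(anchors))
  if (k == 0) return(character())
  withr::with_seed(config$seed + 7L,
                   sort(sample(anchors$gene_id, k)))
}

# Per-gene NDR source weights per condition; the exact table the effect-
# monotonicity property is checked on.
ndr_weight_table <- function(anchors, config) {
  aff <- affected_genes(anchors, config)
  tibble(
    gene_id = anchors$gene_id,
    affected = anchors$gene_id %in% aff,
    ndr_weight_baseline = config$ndr_baseline_weight,
    ndr_weight_perturbed = config$ndr_baseline_weight +
      ifelse(anchors$gene_id %in% aff, config$ndr_fill_effect, 0)
  )
}

# Normal lengths truncated to [lo, hi] by inverse-CDF sampling (exact, no
# rejection loop).
rtrunc_len <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(integer())
  p <- runif(n, pnorm(lo - 0.5, mean, sd), pnorm(hi + 0.5, mean, sd))
  pmin.int(hi, pmax.int(lo, as.integer(round(qnorm(p, mean, sd)))))
}

#' Simulate aligned MNase fragment records for one sample
#'
#' Emits `n_fragments_per_sample` aligned read-pair records. Clean pairs are
#' drawn from a weighted source mixture: per gene, `n_nucleosomes` phased
#' dyad sources (weight 1 each, Gaussian midpoint jitter) plus one NDR
#' source (uniform midpoints over the strand-oriented `ndr_window`); plus a
#' uniform genomic background. In the perturbed condition the NDR source of
#' each affected gene gains `ndr_fill_effect` weight. Contaminant pairs are
#' emitted at the configured rates, each failing exactly one downstream
#' filter predicate. Records are coordinate-sorted.
#'
#' @param annotation An [simulate_annotation()] result (or its `anchors`
#'   tibble plus a `chrom_lengths` attribute-compatible list).
#' @param config The [sim_config()] used for the annotation.
#' @param condition `"baseline"` or `"perturbed"`.
#' @param sample_seed Seed for this sample's fragment draw; defaults to a
#'   value derived from `config$seed` and the condition, so the two default
#'   conditions are independent draws but each is reproducible.
#' @return A list with `fragments` (tibble of aligned pair records: `chrom`,
#'   `start`, `end` 0-based half-open template interval, `chrom2`, `name`,
#'   `concordant`, `ambiguous`, `nm1`, `nm2`, `template_length`) and `truth`
#'   (ground truth: `affected_gene_ids`, `ndr_weights` table, and
#'   `fragment_sources`, a per-record tibble of `name`, `class`,
#'   `source_gene`, `source_type`).
#' @export
simulate_fragments <- function(annotation, config,
                               condition = c("baseline", "perturbed"),
                               sample_seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_config"))
  anchors <- if (inherits(annotation, "mnase_annotation")) annotation$anchors
             else annotation
  chrom_lengths <- if (inherits(annotation, "mnase_annotation"))
    annotation$chrom_lengths
  else stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                       chrom_names(config))
  if (is.null(sample_seed)) {
    sample_seed <- config$seed + 1000L * match(condition,
                                               c("baseline", "perturbed"))
  }

  n <- config$n_fragments_per_sample
  wt <- ndr_weight_table(anchors, config)
  ndr_w <- if (condition == "perturbed") wt$ndr_weight_perturbed
           else wt$ndr_weight_baseline

  # Source table: one row per (gene x nucleosome), per (gene x NDR), per
  # background chromosome.
  n_genes <- nrow(anchors)
  sgn <- ifelse(anchors$strand == "+", 1L, -1L)
  src <- list()
  if (n_genes > 0) {
    k <- rep(seq_len(config$n_nucleosomes) - 1L, times = n_genes)
    gi <- rep(seq_len(n_genes), each = config$n_nucleosomes)
    src$nuc <- tibble(
      chrom = anchors$chrom[gi],
      center = anchors$dyad[gi] + sgn[gi] * k * config$nucleosome_spacing,
      type = "nucleosome",
      gene_id = anchors$gene_id[gi],
      strand = anchors$strand[gi],
      weight = 1
    )
    src$ndr <- tibble(
      chrom = anchors$chrom,
      center = anchors$dyad,
      type = "ndr",
      gene_id = anchors$gene_id,
      strand = anchors$strand,
      weight = ndr_w
    )
  }
  gene_weight <- sum(c(0, src$nuc$weight, src$ndr$weight))
  bg_total <- if (config$background_fraction > 0 && gene_weight > 0) {
    config$background_fraction / (1 - config$background_fraction) * gene_weight
  } else if (gene_weight == 0) 1 else 0
  if (bg_total > 0) {
    src$bg <- tibble(
      chrom = names(chrom_lengths),
      center = NA_integer_,
      type = "background",
      gene_id = NA_character_,
      strand = "+",
      weight = bg_total * as.numeric(chrom_lengths) / sum(as.numeric(chrom_lengths))
    )
  }
  sources <- bind_rows(src)

  rates <- config$contaminant_rates
  classes <- c(names(rates), "clean")
  probs <- c(unname(rates), 1 - sum(rates))

  out <- withr::with_seed(sample_seed, {
    cls <- sample(classes, n, replace = TRUE, prob = probs)
    si <- sample.int(nrow(sources), n, replace = TRUE, prob = sources$weight)
    chrom <- sources$chrom[si]
    type <- sources$type[si]
    gene <- sources$gene_id[si]
    strand <- sources$strand[si]
    center <- sources$center[si]
    L <- unname(chrom_lengths[chrom])

    mid <- integer(n)
    is_nuc <- type == "nucleosome"
    is_ndr <- type == "ndr"
    is_bg <- type == "background"
    mid[is_nuc] <- as.integer(round(center[is_nuc] +
      rnorm(sum(is_nuc), 0, config$dyad_jitter_sd)))
    if (any(is_ndr)) {
      s <- ifelse(strand[is_ndr] == "+", 1L, -1L)
      off <- sample(seq(config$ndr_window[1], config$ndr_window[2]),
                    sum(is_ndr), replace = TRUE)
      mid[is_ndr] <- center[is_ndr] + s * off
    }
    if (any(is_bg)) {
      mid[is_bg] <- as.integer(floor(runif(sum(is_bg), 150,
                                           L[is_bg] - 150)))
    }

    len <- rtrunc_len(n, config$fragment_length_mean,
                      config$fragment_length_sd, 121L, 199L)
    len[cls == "short_insert"] <- sample(60:119, sum(cls == "short_insert"),
                                         replace = TRUE)
    len[cls == "long_insert"] <- sample(201:280, sum(cls == "long_insert"),
                                        replace = TRUE)

    nm1 <- integer(n)
    nm2 <- integer(n)
    hm <- which(cls == "high_mismatch")
    if (length(hm)) {
      which_mate <- sample(c(1L, 2L), length(hm), replace = TRUE)
      nm_val <- sample(5:8, length(hm), replace = TRUE)
      nm1[hm[which_mate == 1L]] <- nm_val[which_mate == 1L]
      nm2[hm[which_mate == 2L]] <- nm_val[which_mate == 2L]
    }

    start <- mid - len %/% 2L
    # keep templates inside the chromosome
    start <- pmax.int(0L, pmin.int(start, L - len))
    end <- start + len

    chrom2 <- chrom
    inter <- which(cls == "inter_chromosomal")
    if (length(inter)) {
      idx <- match(chrom[inter], names(chrom_lengths))
      chrom2[inter] <- names(chrom_lengths)[(idx %% length(chrom_lengths)) + 1L]
    }

    tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      chrom2 = chrom2,
      name = sprintf("frag%08d", seq_len(n)),
      concordant = cls != "discordant",
      ambiguous = FALSE,
      nm1 = nm1, nm2 = nm2,
      template_length = as.integer(len),
      class = cls, source_gene = gene, source_type = type
    )
  })

  ord <- order(out$chrom, out$start, out$name)
  out <- out[ord, ]
  truth <- list(
    affected_gene_ids = affected_genes(anchors, config),
    ndr_weights = wt,
    fragment_sources = select(out, "name", "class", "source_gene",
                              "source_type"),
    condition = condition,
    sample_seed = sample_seed
  )
  fragments <- select(out, -"class", -"source_gene", -"source_type")
  list(fragments = fragments, truth = truth)
}
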