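test_that("anchored matrices index the track exactly, strand-oriented", {
  ct <- constant_track(2.25, c(chrA = 10000L))
  anchors <- tibble::tibble(gene_id = c("a", "b"), chrom = "chrA",
                            strand = c("+", "-"), dyad = c(3000L, 7000L))
  m <- anchored_matrix(ct, anchors, flank = 100L)
  expect_equal(dim(m), c(2L, 201L))
  expect_true(all(m == 2.25))
  expect_equal(colnames(m)[1], "-100")

  set.seed(41)
  tr <- manual_track(list(chrA = runif(10000)))
  m <- anchored_matrix(tr, anchors, flank = 50L)
  for (i in 1:2) {
    s <- if (anchors$strand[i] == "+") 1 else -1
    oracle <- vapply(-50:50, function(j)
      tr$score$chrA[anchors$dyad[i] + s * j + 1], numeric(1))
    expect_equal(unname(unclass(m)[anchors$gene_id[i], ]), oracle)
  }
  expect_error(anchored_matrix(tr, anchors, flank = 0L), "positive")
})

test_that("minus-strand rows mirror plus-strand rows on a palindromic track", {
  L <- 2001L
  pal <- abs(seq_len(L) - 1001)  # symmetric around 0-based position 1000
  tr <- manual_track(list(chrA = as.numeric(pal)))
  anchors <- tibble::tibble(gene_id = c("p", "m"), chrom = "chrA",
                            strand = c("+", "-"), dyad = c(1000L, 1000L))
  m <- anchored_matrix(tr, anchors, flank = 300L)
  expect_equal(unname(unclass(m)["p", ]), unname(unclass(m)["m", ]))
})

test_that("genes overrunning chromosome ends are dropped with a warning", {
  tr <- constant_track(1, c(chrA = 1000L))
  anchors <- tibble::tibble(gene_id = c("edge", "ok"), chrom = "chrA",
                            strand = "+", dyad = c(50L, 500L))
  expect_warning(m <- anchored_matrix(tr, anchors, flank = 200L), "excluded")
  expect_equal(rownames(m), "ok")
})

test_that("log2 ratio matrices match identities and a scalar-loop oracle", {
  set.seed(51)
  tr1 <- manual_track(list(chrA = runif(5000, 0.1, 4)))
  tr2 <- manual_track(list(chrA = runif(5000, 0.1, 4)))
  anchors <- tibble::tibble(gene_id = c("a", "b", "c"), chrom = "chrA",
                            strand = c("+", "-", "+"),
                            dyad = c(1000L, 2500L, 4000L))
  m1 <- anchored_matrix(tr1, anchors, flank = 100L)
  m2 <- anchored_matrix(tr2, anchors, flank = 100L)
  # identity: any pseudocount > 0
  expect_true(all(log2_ratio_matrix(m1, m1, pseudocount = 0.7) == 0))
  # doubling with pseudocount 0 gives exactly 1
  dbl <- nucshift:::new_anchored_matrix(unclass(m1) * 2, 100L)
  expect_equal(unname(unclass(log2_ratio_matrix(dbl, m1, pseudocount = 0))),
               matrix(1, nrow(m1), ncol(m1)), ignore_attr = TRUE)
  lr <- log2_ratio_matrix(m1, m2, pseudocount = 1)
  oracle <- unclass(m1)
  for (i in seq_len(nrow(oracle))) {
    for (j in seq_len(ncol(oracle))) {
      oracle[i, j] <- log2((unclass(m1)[i, j] + 1) / (unclass(m2)[i, j] + 1))
    }
  }
  expect_equal(unclass(lr), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(log2_ratio_matrix(m1, nucshift:::new_anchored_matrix(
    unclass(m2)[1:2, ], 100L)), "differ")
})

test_that("heatmap assembly is pure row selection under ordering/blacklist", {
  vals <- matrix(as.numeric(1:15), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  m <- nucshift:::new_anchored_matrix(vals, flank = 2L)
  # ordering = matrix order, no blacklist: unchanged
  hm <- assemble_heatmap(m, c("g1", "g2", "g3"))
  expect_equal(unclass(hm), unclass(m), ignore_attr = TRUE)
  # reorder + blacklist
  hm <- assemble_heatmap(m, c("g2", "g1", "g3"), blacklist = "g1")
  expect_equal(rownames(hm), c("g2", "g3"))
  expect_equal(unname(unclass(hm)["g2", ]), as.numeric(6:10))
  expect_equal(unname(unclass(hm)["g3", ]), as.numeric(11:15))
  # all blacklisted: empty with warning
  expect_warning(hm0 <- assemble_heatmap(m, c("g1", "g2", "g3"),
                                         blacklist = c("g1", "g2", "g3")),
                 "empty")
  expect_equal(nrow(hm0), 0L)
  expect_error(assemble_heatmap(m, c("g1", "g2")), "missing")
})

test_that("average profiles equal row means and single-gene rows", {
  set.seed(61)
  tr <- manual_track(list(chrA = runif(8000)))
  anchors <- tibble::tibble(gene_id = sprintf("g%d", 1:6), chrom = "chrA",
                            strand = rep_len(c("+", "-"), 6),
                            dyad = as.integer(seq(1000, 7000,
                                                  length.out = 6)))
  m <- anchored_matrix(tr, anchors, flank = 200L)
  pr <- average_profile(tr, anchors, anchors$gene_id, flank = 200L)
  expect_equal(pr$occupancy, unname(colMeans(unclass(m))))
  expect_equal(pr$position, -200:200)
  # single gene: the profile is that gene's row
  pr1 <- average_profile(tr, anchors, "g3", flank = 200L)
  expect_equal(pr1$occupancy, unname(unclass(m)["g3", ]))
  # constant track: flat profile
  ct <- constant_track(1.5, c(chrA = 8000L))
  prc <- average_profile(ct, anchors, anchors$gene_id, flank = 200L)
  expect_true(all(prc$occupancy == 1.5))
  expect_error(average_profile(tr, anchors, character()), "empty")
  expect_error(average_profile(tr, anchors, "nope"), "unknown")
})

test_that("perturbed profiles gain occupancy in the NDR of affected genes", {
  cfg <- small_config(n_genes = 30L, affected_gene_fraction = 0.3,
                      n_fragments_per_sample = 60000L, seed = 17L)
  ann <- simulate_annotation(cfg, emit_sequence = FALSE)
  sb <- simulate_fragments(ann, cfg, "baseline")
  sp <- simulate_fragments(ann, cfg, "perturbed")
  mk <- function(s) build_track(
    fragment_midpoints(filter_fragments(s$fragments)), ann$chrom_lengths)
  pr <- average_profile(list(baseline = mk(sb), perturbed = mk(sp)),
                        ann$anchors, sb$truth$affected_gene_ids,
                        flank = 300L)
  wide <- tidyr::pivot_wider(pr, names_from = "condition",
                             values_from = "occupancy")
  ndr <- wide[wide$position >= -150 & wide$position <= -50, ]
  expect_gt(max(ndr$perturbed - ndr$baseline), 0)
  expect_gt(mean(ndr$perturbed), mean(ndr$baseline))
})

test_that("tidy and autoplot views agree with the underlying objects", {
  vals <- matrix(as.numeric(1:10), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  m <- nucshift:::new_anchored_matrix(vals, flank = 2L)
  td <- tidy(m)
  expect_equal(nrow(td), 10L)
  expect_equal(td$value[td$gene_id == "a"], as.numeric(1:5))
  expect_equal(unique(td$position), -2:2)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  tr <- constant_track(1, c(chrA = 50L))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(plot_profile(average_profile(
    tr, tibble::tibble(gene_id = "g", chrom = "chrA", strand = "+",
                       dyad = 25L), "g", flank = 10L)), "ggplot")
})
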