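# index-valued track: score at 0-based position p equals p, so window
# contents are readable off the coordinates
index_track <- function(L = 20000L) {
  manual_track(list(chrA = as.numeric(0:(L - 1))))
}

test_that("relative windows are strand-oriented with inclusive bounds", {
  tr <- index_track()
  anchors <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chrA",
                            strand = c("+", "-"), dyad = c(10000L, 10000L))
  w <- relative_window_values(tr, anchors)
  wp <- w[w$gene_id == "gp", ]
  wm <- w[w$gene_id == "gm", ]
  expect_equal(nrow(wp), 101L)
  expect_equal(wp$pos, 9850:9950)
  expect_equal(wp$value, as.numeric(9850:9950))
  # minus strand: genomic 10150 down to 10050, most upstream first
  expect_equal(wm$pos, 10150:10050)
  expect_equal(wm$value[1], 10150)
  # constant track: all values c on either strand
  ct <- constant_track(3.5, c(chrA = 20000L))
  wc <- relative_window_values(ct, anchors)
  expect_true(all(wc$value == 3.5))
})

test_that("window statistics match identities and a scalar-loop oracle", {
  set.seed(21)
  L <- 30000L
  sc <- runif(L)
  t_ref <- manual_track(list(chrA = sc))
  t_same <- manual_track(list(chrA = sc))
  t_plus1 <- manual_track(list(chrA = sc + 1))
  anchors <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), chrom = "chrA",
    strand = rep_len(c("+", "-"), 20),
    dyad = as.integer(seq(1000, 29000, length.out = 20)))
  expect_true(all(window_stat(t_same, t_ref, anchors)$stat == 0))
  expect_equal(window_stat(t_plus1, t_ref, anchors)$stat, rep(1, 20))

  t_test <- manual_track(list(chrA = runif(L)))
  st <- window_stat(t_test, t_ref, anchors)
  oracle <- vapply(seq_len(20), function(i) {
    s <- if (anchors$strand[i] == "+") 1 else -1
    tot <- 0
    for (o in -150:-50) {
      p <- anchors$dyad[i] + s * o
      tot <- tot + (t_test$score$chrA[p + 1] - t_ref$score$chrA[p + 1])
    }
    tot / 101
  }, numeric(1))
  expect_equal(st$stat, oracle, tolerance = 1e-12)
})

test_that("genes whose window leaves the chromosome are excluded, not fatal", {
  tr <- constant_track(1, c(chrA = 1000L))
  anchors <- tibble::tibble(gene_id = c("edge", "ok"), chrom = "chrA",
                            strand = "+", dyad = c(100L, 500L))
  expect_warning(st <- window_stat(tr, tr, anchors), "excluded")
  expect_true(st$excluded[st$gene_id == "edge"])
  expect_equal(st$excluded_reason[st$gene_id == "edge"],
               "window_out_of_chromosome")
  expect_false(st$excluded[st$gene_id == "ok"])
})

test_that("blacklisting keeps only genes strictly above the threshold", {
  st <- tibble::tibble(gene_id = c("g059", "g060", "g061"),
                       stat = c(0.59, 0.60, 0.61), excluded = FALSE)
  expect_equal(blacklist_genes(st, 0.6), c("g059", "g060"))
  st$stat <- rep(1.0, 3)
  expect_equal(blacklist_genes(st, 0.6), character())
  expect_equal(blacklist_genes(st, -Inf), character())
  expect_equal(blacklist_genes(st, Inf), st$gene_id)
})

test_that("blacklist merging is set union without duplication", {
  expect_equal(merge_blacklists(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  expect_equal(merge_blacklists(character(), character()), character())
  # three lists of 403 / 634 / 506 sharing 473 memberships in total
  ids <- sprintf("y%04d", 1:1070)
  l1 <- ids[1:403]
  l2 <- ids[c(1:237, 404:800)]
  l3 <- ids[c(801:1070, 1:236)]
  expect_equal(length(l1), 403L)
  expect_equal(length(l2), 634L)
  expect_equal(length(l3), 506L)
  merged <- merge_blacklists(list(l1, l2, l3))
  expect_equal(length(merged), 403L + 634L + 506L - 473L)
  expect_equal(length(merged), 1070L)
  expect_setequal(merged, ids)
})

test_that("gene ordering is by decreasing statistic with lexicographic ties", {
  st <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       stat = c(2.0, 0.5, 1.0), excluded = FALSE)
  expect_equal(order_genes(st), c("g1", "g3", "g2"))
  st$stat <- rep(1, 3)
  expect_equal(order_genes(st), c("g1", "g2", "g3"))
  # independent oracle: repeatedly extract the max, ties by smallest id
  set.seed(8)
  big <- tibble::tibble(gene_id = sprintf("g%03d", sample(100)),
                        stat = sample(round(runif(100), 1)),  # forces ties
                        excluded = FALSE)
  got <- order_genes(big)
  pool <- big
  oracle <- character(0)
  while (nrow(pool)) {
    cand <- pool[pool$stat == max(pool$stat), ]
    pick <- sort(cand$gene_id)[1]
    oracle <- c(oracle, pick)
    pool <- pool[pool$gene_id != pick, ]
  }
  expect_equal(got, oracle)
})

test_that("top-N selection ranks after baseline subtraction", {
  st <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       stat = c(2, 1, 0), excluded = FALSE)
  expect_equal(top_n_genes(st, 2), c("g1", "g2"))
  # baseline equal to stats: all adjusted 0, tie rule, first n
  expect_equal(top_n_genes(st, 2, baseline_stats = st), c("g1", "g2"))
  # baseline reorders: g3 has the largest adjusted gain
  base <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         stat = c(3, 1, -2), excluded = FALSE)
  expect_equal(top_n_genes(st, 2, baseline_stats = base), c("g3", "g2"))
  expect_error(top_n_genes(st, 0), "positive")
  expect_warning(all3 <- top_n_genes(st, 10), "only 3")
  expect_equal(all3, c("g1", "g2", "g3"))
  expect_error(top_n_genes(st, 2, baseline_stats = base[1:2, ]), "missing")
})

test_that("statistics are shift-invariant and strand-mirror-invariant", {
  set.seed(31)
  L <- 20000L
  sc_t <- runif(L)
  sc_r <- runif(L)
  anchors <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), chrom = "chrA",
                            strand = rep_len(c("+", "-"), 10),
                            dyad = as.integer(seq(2000, 18000,
                                                  length.out = 10)))
  st <- window_stat(manual_track(list(chrA = sc_t)),
                    manual_track(list(chrA = sc_r)), anchors)
  # adding a constant to both tracks changes nothing
  st_both <- window_stat(manual_track(list(chrA = sc_t + 5)),
                         manual_track(list(chrA = sc_r + 5)), anchors)
  expect_equal(st_both$stat, st$stat, tolerance = 1e-12)
  # adding c only to test shifts every statistic by exactly c
  st_test <- window_stat(manual_track(list(chrA = sc_t + 2.5)),
                         manual_track(list(chrA = sc_r)), anchors)
  expect_equal(st_test$stat, st$stat + 2.5, tolerance = 1e-12)
  # mirroring the genome and flipping strands leaves statistics unchanged
  mirror <- function(v) rev(v)
  anchors_m <- dplyr::mutate(anchors,
                             strand = ifelse(strand == "+", "-", "+"),
                             dyad = L - 1L - dyad)
  st_m <- window_stat(manual_track(list(chrA = mirror(sc_t))),
                      manual_track(list(chrA = mirror(sc_r))), anchors_m)
  expect_equal(st_m$stat, st$stat, tolerance = 1e-12)
})
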