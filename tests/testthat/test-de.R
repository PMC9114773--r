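test_that("hurdle test handles degenerate and identity inputs per contract", {
  # no signal: identical vectors
  x <- c(0, 0, 1.2, 2.5, 3.1, 0, 4.2)
  res <- hurdle_test(x, x)
  expect_equal(res$lrt_stat, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # undetected in both groups
  res0 <- hurdle_test(rep(0, 10), rep(0, 20))
  expect_equal(res0$p, 1)
  expect_equal(res0$lrt_stat, 0)
  expect_equal(res0$df, 0L)

  # all values positive in both groups: discrete component dropped
  resc <- hurdle_test(c(1.1, 2.3, 3.2), c(2.2, 2.8, 1.9, 3.5))
  expect_equal(resc$df, 1L)

  # constant positive values: continuous component dropped
  resd <- hurdle_test(c(0, 0, 2, 2), c(0, 2, 2, 2))
  expect_equal(resd$df, 1L)

  expect_error(hurdle_test(numeric(0), x), "nonempty")
})

test_that("hurdle power is nondecreasing in the planted effect size", {
  reject_rate <- function(lfc, n_reps = 60, seed0 = 100) {
    planted <- if (lfc > 0)
      data.frame(gene = "gene001", cell_type = "A", sample_id = "all",
                 log2fc = lfc) else NULL
    mean(vapply(seq_len(n_reps), function(r) {
      cfg <- sim_config(n_genes = 30, cell_types = c("A", "B"),
                        groups = list(G = "s1"),
                        cells_per_type_per_sample = 100,
                        planted_effects = planted, mito_gene_count = 0,
                        seed = seed0 + r)
      sim <- simulate_counts(cfg)
      nm <- as.matrix(normalize_counts(sim$counts))
      ia <- sim$annotation$cell_type == "A"
      hurdle_test(nm[1, ia], nm[1, !ia])$p < 0.05
    }, logical(1)))
  }
  rates <- vapply(c(0, 0.5, 1, 2), reject_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[4], 0.9)
})

test_that("log fold change matches the arithmetic oracle and is antisymmetric", {
  fg <- rep(log2(4), 5)   # linear mean 3
  bg <- rep(log2(2), 7)   # linear mean 1
  expect_equal(log_fold_change(fg, bg), 1, tolerance = 1e-12)
  expect_equal(log_fold_change(bg, fg), -1, tolerance = 1e-12)

  set.seed(1)
  a <- abs(rnorm(50)); b <- abs(rnorm(60))
  expect_equal(log_fold_change(a, b), -log_fold_change(b, a), tolerance = 1e-12)
  expect_error(log_fold_change(numeric(0), a), "nonempty")
})

test_that("detection fraction counts strictly positive entries", {
  expect_equal(detection_fraction(c(0, 0, 1.2, 3.4)), 0.5)
  expect_equal(detection_fraction(rep(0, 5)), 0)
  expect_equal(detection_fraction(c(0.1, 2)), 1)
  expect_error(detection_fraction(numeric(0)), "empty")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_pvalues(0.037), 0.037)
  expect_equal(adjust_pvalues(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- adjust_pvalues(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("stratum-vs-background DE recovers planted effects and flags tiny strata", {
  planted <- data.frame(gene = "gene001", cell_type = "CAF1",
                        sample_id = "s1", log2fc = 2)
  res <- tiny_sim(seed = 21L, planted = planted, cells = 150)
  nm <- normalize_counts(res$sim$counts)
  de <- de_by_celltype_sample(nm, res$sim$annotation,
                              sprintf("gene%03d", 1:10))
  hit <- de[de$gene == "gene001" & de$cell_type == "CAF1" & de$sample_id == "s1", ]
  expect_lt(abs(hit$log2fc - 2), 0.3)
  expect_lt(hit$p_adj, 0.01)
  # one record per (gene, cell_type, sample)
  expect_equal(nrow(de), 10 * 3 * 3)
  expect_false(any(duplicated(de[, c("gene", "cell_type", "sample_id")])))

  # a 2-cell stratum is emitted flagged with p = 1
  ann2 <- res$sim$annotation
  drop <- which(ann2$cell_type == "other" & ann2$sample_id == "s3")
  keep <- setdiff(seq_len(nrow(ann2)), drop[-(1:2)])
  de2 <- de_by_celltype_sample(nm[, ann2$cell_id[keep]], ann2[keep, ],
                               "gene002")
  tiny <- de2[de2$cell_type == "other" & de2$sample_id == "s3", ]
  expect_equal(tiny$status, "too_few_cells")
  expect_equal(tiny$p, 1)
})

test_that("DE on disjoint gene sets differs from the union only in p_adj", {
  sim <- tiny_sim(seed = 31L)$sim
  nm <- normalize_counts(sim$counts)
  gs_a <- sprintf("gene%03d", 1:4)
  gs_b <- sprintf("gene%03d", 5:8)
  de_a <- de_by_celltype_sample(nm, sim$annotation, gs_a)
  de_b <- de_by_celltype_sample(nm, sim$annotation, gs_b)
  de_u <- de_by_celltype_sample(nm, sim$annotation, c(gs_a, gs_b))
  cat_ab <- rbind(de_a, de_b)
  key <- function(d) paste(d$gene, d$cell_type, d$sample_id)
  m <- match(key(de_u), key(cat_ab))
  expect_equal(de_u$p, cat_ab$p[m], tolerance = 1e-12)
  expect_equal(de_u$log2fc, cat_ab$log2fc[m], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(de_u$p_adj, cat_ab$p_adj[m])))
})

test_that("within-group background restricts the pool to the stratum's group", {
  sim <- tiny_sim(seed = 41L)$sim
  nm <- normalize_counts(sim$counts)
  de_wg <- de_by_celltype_sample(nm, sim$annotation, "gene001",
                                 background = "within_group")
  de_all <- de_by_celltype_sample(nm, sim$annotation, "gene001")
  # G2 has a single sample: its strata keep the same foreground but a smaller
  # background, so detection fractions generally differ
  r_wg <- de_wg[de_wg$group_id == "G2", ]
  r_all <- de_all[de_all$group_id == "G2", ]
  expect_equal(r_wg$pct_fg, r_all$pct_fg)
  expect_false(isTRUE(all.equal(r_wg$pct_bg, r_all$pct_bg)))
})
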