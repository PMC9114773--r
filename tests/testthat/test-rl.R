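test_that("prior loading subsets to directed edges with known mode and dedups", {
  raw <- data.frame(
    ligand = c("L1", "L2", "L3", "L3", "L4", "L5"),
    receptor = c("R1", "R2", "R3", "R3", "R4", "R5"),
    directed = c(1, 1, 1, 1, 0, 1),
    mode = c("stimulation", "inhibition", "stimulation", "stimulation", "stimulation", NA))
  f <- tempfile(fileext = ".tsv")
  write_interaction_prior(raw, f)
  prior <- load_interaction_prior(f)
  expect_equal(nrow(prior), 3)  # L4 undirected, L5 modeless, L3 duplicated
  expect_setequal(prior$ligand, c("L1", "L2", "L3"))
  dropped <- attr(prior, "dropped")
  expect_equal(unname(dropped["undirected_or_modeless"]), 2)
  expect_equal(unname(dropped["duplicated"]), 1)

  expect_error(load_interaction_prior(data.frame(ligand = "a", receptor = "b")),
               "directed, mode")
  empty <- data.frame(ligand = "a", receptor = "b", directed = 0,
                      mode = "stimulation")
  expect_warning(load_interaction_prior(empty), "no edges")
})

test_that("a simulated prior round-trips through write and load edge-for-edge", {
  cfg <- tiny_sim()$cfg
  te <- data.frame(ligand = sprintf("gene%03d", 1:2),
                   receptor = sprintf("gene%03d", 3:4))
  prior <- simulate_interaction_prior(cfg, te, n_decoys = 6, n_modeless = 2)
  f <- tempfile(fileext = ".tsv")
  write_interaction_prior(prior, f)
  loaded <- load_interaction_prior(f)
  kept <- prior[!is.na(prior$mode), ]
  expect_setequal(paste(loaded$ligand, loaded$receptor),
                  paste(kept$ligand, kept$receptor))
})

test_that("interaction scores are the sum of partner log2 fold changes", {
  de <- manual_de(list(
    list(gene = "L", cell_type = "CAF1", sample_id = "s1", group_id = "G",
         log2fc = 0.7, p_adj = 1e-4),
    list(gene = "R", cell_type = "tumor", sample_id = "s1", group_id = "G",
         log2fc = 0.3, p_adj = 1e-4),
    list(gene = "L", cell_type = "CAF1", sample_id = "s2", group_id = "G",
         log2fc = 1, p_adj = 1e-4),
    list(gene = "R", cell_type = "tumor", sample_id = "s2", group_id = "G",
         log2fc = 1, p_adj = 1e-4)))
  prior <- data.frame(ligand = "L", receptor = "R", directed = 1,
                      mode = "stimulation")
  recs <- score_interactions(de, prior, "CAF1", "tumor", "G")
  s1 <- recs[recs$sample_id == "s1", ]
  expect_equal(s1$rl_score, 1.0, tolerance = 1e-12)     # 0.7 + 0.3
  s2 <- recs[recs$sample_id == "s2", ]
  expect_equal(s2$rl_score, 2, tolerance = 1e-12)       # linear FC 2 x 2
  grp <- recs[recs$level == "group", ]
  expect_equal(grp$rl_score, mean(c(1, 2)))
  # additivity identity holds for every record
  expect_equal(recs$rl_score, recs$ligand_log2fc + recs$receptor_log2fc,
               tolerance = 1e-12)

  # edges with genes absent from the DE table are skipped with a count
  prior2 <- rbind(prior, data.frame(ligand = "ghost", receptor = "R",
                                    directed = 1, mode = "stimulation"))
  recs2 <- score_interactions(de, prior2, "CAF1", "tumor", "G")
  expect_equal(attr(recs2, "skipped_edges"), 1)
})

test_that("the consistency filter demands every condition in every sample", {
  mk_de <- function(l_lfc, r_lfc, l_p = rep(1e-4, 3), r_p = rep(1e-4, 3)) {
    manual_de(c(
      lapply(1:3, function(i)
        list(gene = "L", cell_type = "CAF1", sample_id = paste0("s", i),
             group_id = "G", log2fc = l_lfc[i], p_adj = l_p[i])),
      lapply(1:3, function(i)
        list(gene = "R", cell_type = "tumor", sample_id = paste0("s", i),
             group_id = "G", log2fc = r_lfc[i], p_adj = r_p[i]))))
  }
  prior <- data.frame(ligand = "L", receptor = "R", directed = 1,
                      mode = "stimulation")
  run <- function(de) {
    recs <- score_interactions(de, prior, "CAF1", "tumor", "G")
    flag_significant(recs, filter_config(), samples = paste0("s", 1:3))
  }
  # all conditions met in 3/3 samples
  expect_true(all(run(mk_de(c(1, 1, 1), c(0.5, 0.5, 0.5)))$significant))
  # ligand log2 FC 0.49 in one sample
  expect_false(any(run(mk_de(c(1, 0.49, 1), c(0.5, 0.5, 0.5)))$significant))
  # ligand exactly at the inclusive 0.5 cutoff
  expect_true(all(run(mk_de(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)))$significant))
  # receptor log2 FC 0 in one sample: exclusive cutoff
  expect_false(any(run(mk_de(c(1, 1, 1), c(0.5, 0, 0.5)))$significant))
  # adjusted p at the threshold in one sample
  expect_false(any(run(mk_de(c(1, 1, 1), c(0.5, 0.5, 0.5),
                             l_p = c(1e-4, 0.01, 1e-4)))$significant))
  # a missing sample record blocks the flag
  de_m <- mk_de(c(1, 1, 1), c(0.5, 0.5, 0.5))
  de_m <- de_m[!(de_m$gene == "L" & de_m$sample_id == "s3"), ]
  out_m <- run(de_m)
  expect_false(any(out_m$significant))
  expect_equal(attr(out_m, "incomplete_edges"), 1L)
})

test_that("relaxing filter thresholds never unsets a significant flag", {
  set.seed(5)
  rows <- list()
  for (g in 1:8) for (i in 1:3) {
    rows[[length(rows) + 1]] <- list(
      gene = paste0(c("L", "R")[1 + g %% 2], g),
      cell_type = c("CAF1", "tumor")[1 + g %% 2],
      sample_id = paste0("s", i), group_id = "G",
      log2fc = rnorm(1, 0.5, 0.5), p_adj = runif(1, 0, 0.02))
  }
  de <- manual_de(rows)
  prior <- data.frame(ligand = paste0("L", c(2, 4, 6, 8)),
                      receptor = paste0("R", c(1, 3, 5, 7)),
                      directed = 1, mode = "stimulation")
  recs <- score_interactions(de, prior, "CAF1", "tumor", "G")
  strict <- flag_significant(recs, filter_config(0.01, 0.5, 0),
                             samples = paste0("s", 1:3))
  loose <- flag_significant(recs, filter_config(0.05, 0.2, -0.5),
                            samples = paste0("s", 1:3))
  expect_true(all(loose$significant[strict$significant]))
})

test_that("the full pipeline recovers planted edges and respects consistency", {
  design <- rl_study_design(cells_per_type_per_sample = 120, seed = 17L)
  res <- study_rl_recovery(design)
  expect_gte(res$precision, 0.9)
  expect_gte(res$recall, 0.9)
  recs <- res$records
  expect_equal(recs$rl_score, recs$ligand_log2fc + recs$receptor_log2fc,
               tolerance = 1e-12)

  # removing one sample's planted ligand effect unsets the flags
  pe <- design$config$planted_effects
  design$config$planted_effects <-
    pe[!(pe$sample_id == "AOM3" & pe$cell_type == design$sender), ]
  res2 <- study_rl_recovery(design)
  expect_equal(res2$recall, 0)
})

test_that("permuting cell-type labels within samples destroys the flags", {
  design <- rl_study_design(cells_per_type_per_sample = 120, seed = 23L)
  sim <- simulate_counts(design$config)
  prior <- simulate_interaction_prior(design$config, design$true_edges,
                                      n_decoys = design$n_decoys)
  for (r in 1:3) {
    set.seed(1000 + r)
    ann <- sim$annotation
    for (s in unique(ann$sample_id)) {
      idx <- ann$sample_id == s
      ann$cell_type[idx] <- sample(ann$cell_type[idx])
    }
    res <- run_rl_pipeline(sim$counts, ann, prior, design$sender,
                           design$receiver, design$group, qc = design$qc)
    recs <- res$records[[design$receiver]]
    expect_equal(sum(recs$significant[recs$level == "group"]), 0)
  }
})

test_that("an empty prior yields an empty report with a warning", {
  sim <- tiny_sim()$sim
  empty_prior <- structure(
    data.frame(ligand = character(), receptor = character(),
               directed = integer(), mode = character()),
    class = c("interaction_prior", "data.frame"))
  expect_warning(
    res <- run_rl_pipeline(sim$counts, sim$annotation, empty_prior,
                           "CAF1", "tumor", "G1",
                           qc = qc_thresholds(min_genes_detected = 5)),
    "no prior gene")
  expect_length(res$records, 0)
})
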