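# small deterministic fixtures shared across test files

# tiny simulation: 3 cell types, 2 groups (2 + 1 samples), 40 cells/stratum
tiny_sim <- function(seed = 42L, planted = NULL, cells = 40L) {
  cfg <- sim_config(n_genes = 30, cell_types = c("CAF1", "tumor", "other"),
                    groups = list(G1 = c("s1", "s2"), G2 = "s3"),
                    cells_per_type_per_sample = cells,
                    planted_effects = planted, mito_gene_count = 3, seed = seed)
  list(cfg = cfg, sim = simulate_counts(cfg))
}

# dense count matrix built by hand with controllable per-cell content
manual_counts <- function(cells) {
  genes <- unique(unlist(lapply(cells, names)))
  m <- matrix(0, length(genes), length(cells),
              dimnames = list(genes, names(cells)))
  for (cid in names(cells)) m[names(cells[[cid]]), cid] <- cells[[cid]]
  m
}

# brute-force Benjamini-Hochberg step-up, the independent oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# minimal hand-built DE table for scoring tests
manual_de <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  defaults <- data.frame(pct_fg = 1, pct_bg = 1, lrt_stat = 10, df = 2L, p = 1e-6,
                         status = "ok")
  cbind(df, defaults[rep(1, nrow(df)), , drop = FALSE], row.names = NULL)
}
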