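#' Load a ligand-receptor interaction prior
#'
#' Reads a tab-separated edge list with columns `ligand`, `receptor`,
#' `directed` (0/1) and `mode` (`stimulation`, `inhibition`, or blank/NA).
#' Mirroring the construction of curated intercellular networks, edges are
#' subset to those with known directionality and a known mode of action;
#' duplicate (ligand, receptor) pairs are collapsed to one edge. Counts of
#' dropped rows are attached as attribute `dropped` (named vector:
#' `undirected_or_modeless`, `duplicated`).
#'
#' @param path path to the TSV file, or a data.frame with the same columns.
#' @return data.frame of class `interaction_prior` with columns `ligand`,
#'   `receptor`, `directed`, `mode`; warns if no edge survives the filter.
#' @export
load_interaction_prior <- function(path) {
  raw <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "directed", "mode")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("interaction prior is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mode_known <- !is.na(raw$mode) & nzchar(trimws(raw$mode))
  directed <- !is.na(raw$directed) & raw$directed == 1
  keep <- mode_known & directed
  edges <- raw[keep, need, drop = FALSE]
  dup <- duplicated(edges[, c("ligand", "receptor")])
  out <- edges[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(undirected_or_modeless = sum(!keep),
                            duplicated = sum(dup))
  class(out) <- c("interaction_prior", "data.frame")
  if (nrow(out) == 0)
    warning("no edges with known mode and directionality in the prior",
            call. = FALSE)
  out
}

#' Filter configuration for receptor-ligand significance
#'
#' An interaction is called significant only when, in every sample of the
#' group, both partners are differentially expressed below the adjusted
#' p-value threshold, the ligand's log2 fold change is at least
#' `ligand_log2fc_min` (inclusive), and the receptor's log2 fold change
#' exceeds `receptor_log2fc_min` (exclusive, i.e. strictly positive by
#' default).
#'
#' @param p_adj_threshold adjusted p-value threshold (default 0.01).
#' @param ligand_log2fc_min inclusive ligand log2 FC cutoff (default 0.5).
#' @param receptor_log2fc_min exclusive receptor log2 FC cutoff (default 0).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(p_adj_threshold = 0.01, ligand_log2fc_min = 0.5,
                          receptor_log2fc_min = 0) {
  if (!is.finite(p_adj_threshold) || p_adj_threshold <= 0 || p_adj_threshold >= 1)
    stop("p_adj_threshold must lie in (0, 1)", call. = FALSE)
  if (!is.finite(ligand_log2fc_min) || !is.finite(receptor_log2fc_min))
    stop("fold-change thresholds must be finite", call. = FALSE)
  structure(list(p_adj_threshold = p_adj_threshold,
                 ligand_log2fc_min = ligand_log2fc_min,
                 receptor_log2fc_min = receptor_log2fc_min),
            class = "filter_config")
}

#' Score receptor-ligand interactions between a sender and a receiver cell type
#'
#' For every prior edge (L, R) and every sample of the group, pairs the
#' ligand's differential-expression record in the sender cell type with the
#' receptor's record in the receiver cell type and computes
#' `rl_score = ligand_log2fc + receptor_log2fc`, i.e. the log2 of the product
#' of linear fold changes. One group-level aggregate record per edge carries
#' the mean of the per-sample scores (and mean fold changes; its p-value
#' columns hold the worst — maximum — adjusted p over the samples). Edges
#' whose ligand or receptor is absent from the DE table are skipped; their
#' count is attached as attribute `skipped_edges`.
#'
#' @param de DE table from [de_by_celltype_sample()].
#' @param prior interaction prior (data.frame from
#'   [load_interaction_prior()]).
#' @param sender_type cell type expressing the ligand.
#' @param receiver_type cell type expressing the receptor.
#' @param group_id condition group whose samples are scored.
#' @return data.frame with columns `ligand`, `receptor`, `sender`, `receiver`,
#'   `sample_id`, `level` ("sample" or "group"), `rl_score`, `ligand_log2fc`,
#'   `receptor_log2fc`, `ligand_p_adj`, `receptor_p_adj`, `mode`,
#'   `significant` (initialized NA; see [flag_significant()]).
#' @export
score_interactions <- function(de, prior, sender_type, receiver_type, group_id) {
  samples <- unique(de$sample_id[de$group_id == group_id])
  if (length(samples) == 0)
    stop("no samples found for group '", group_id, "' in the DE table",
         call. = FALSE)
  de_genes <- unique(de$gene)
  have <- prior$ligand %in% de_genes & prior$receptor %in% de_genes
  skipped <- sum(!have)
  prior <- prior[have, , drop = FALSE]
  recs <- list()
  lkey <- paste(de$gene, de$cell_type, de$sample_id)
  for (i in seq_len(nrow(prior))) {
    L <- prior$ligand[i]; R <- prior$receptor[i]
    li <- match(paste(L, sender_type, samples), lkey)
    ri <- match(paste(R, receiver_type, samples), lkey)
    ok <- !is.na(li) & !is.na(ri)
    if (!any(ok)) next
    samp <- data.frame(
      ligand = L, receptor = R, sender = sender_type, receiver = receiver_type,
      sample_id = samples[ok], level = "sample",
      rl_score = de$log2fc[li[ok]] + de$log2fc[ri[ok]],
      ligand_log2fc = de$log2fc[li[ok]], receptor_log2fc = de$log2fc[ri[ok]],
      ligand_p_adj = de$p_adj[li[ok]], receptor_p_adj = de$p_adj[ri[ok]],
      mode = prior$mode[i], significant = NA, stringsAsFactors = FALSE)
    agg <- samp[1, ]
    agg$sample_id <- group_id; agg$level <- "group"
    agg$rl_score <- mean(samp$rl_score)
    agg$ligand_log2fc <- mean(samp$ligand_log2fc)
    agg$receptor_log2fc <- mean(samp$receptor_log2fc)
    agg$ligand_p_adj <- max(samp$ligand_p_adj)
    agg$receptor_p_adj <- max(samp$receptor_p_adj)
    recs[[length(recs) + 1]] <- rbind(samp, agg)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(ligand = character(), receptor = character(), sender = character(),
               receiver = character(), sample_id = character(), level = character(),
               rl_score = numeric(), ligand_log2fc = numeric(),
               receptor_log2fc = numeric(), ligand_p_adj = numeric(),
               receptor_p_adj = numeric(), mode = character(),
               significant = logical())
  rownames(out) <- NULL
  attr(out, "skipped_edges") <- skipped
  out
}

#' Apply the replicate-consistency significance filter
#'
#' Sets `significant = TRUE` for an edge only when in EVERY sample of the
#' group the ligand and receptor adjusted p-values are below the threshold,
#' the ligand log2 FC is at least the ligand cutoff, and the receptor log2 FC
#' is strictly above the receptor cutoff. Edges with a sample-level record
#' missing for any group sample can never be flagged; their count is attached
#' as attribute `incomplete_edges`. All records are retained — scores are
#' reported whether or not they are flagged.
#'
#' @param records output of [score_interactions()].
#' @param fc a [filter_config()].
#' @param samples character vector of all sample ids of the group; defaults
#'   to the samples present in `records`, but passing the full design is
#'   safer when strata could be missing.
#' @return `records` with the `significant` column filled (edge-level flag,
#'   identical on the sample and group records of an edge).
#' @export
flag_significant <- function(records, fc = filter_config(), samples = NULL) {
  if (nrow(records) == 0) return(records)
  if (is.null(samples))
    samples <- unique(records$sample_id[records$level == "sample"])
  edge_key <- paste(records$ligand, records$receptor)
  incomplete <- 0L
  for (e in unique(edge_key)) {
    idx <- edge_key == e
    s <- records[idx & records$level == "sample", , drop = FALSE]
    complete <- all(samples %in% s$sample_id)
    if (!complete) incomplete <- incomplete + 1L
    pass <- complete && all(
      s$ligand_p_adj < fc$p_adj_threshold &
      s$receptor_p_adj < fc$p_adj_threshold &
      s$ligand_log2fc >= fc$ligand_log2fc_min &
      s$receptor_log2fc > fc$receptor_log2fc_min)
    records$significant[idx] <- pass
  }
  attr(records, "incomplete_edges") <- incomplete
  records
}

#' End-to-end receptor-ligand communication pipeline
#'
#' Runs QC filtering, per-cell log2 normalization, restriction of the gene
#' universe to the prior's ligands and receptors, stratum-vs-background
#' differential expression, interaction scoring for each receiver cell type,
#' and the replicate-consistency significance filter. Returns per-receiver
#' record tables and heatmap-ready score matrices (edges x samples, with a
#' parallel logical star matrix).
#'
#' @param counts raw gene x cell count matrix.
#' @param annotation cell annotation data.frame.
#' @param prior interaction prior: a path to a TSV or a data.frame; loaded
#'   through [load_interaction_prior()].
#' @param sender_type cell type expressing ligands.
#' @param receiver_types character vector of receiving cell types.
#' @param group_id condition group to score.
#' @param qc [qc_thresholds()] applied before normalization.
#' @param filters [filter_config()] for the significance flag.
#' @param min_cells minimum stratum size for the DE step.
#' @param background background definition passed to
#'   [de_by_celltype_sample()].
#' @return list with `records` (one data.frame per receiver type), `matrices`
#'   (per receiver: list of `rl_score` matrix edges x samples and logical
#'   `significant` matrix), `de` (the DE table), and `report` (stage-by-stage
#'   counts).
#' @export
run_rl_pipeline <- function(counts, annotation, prior, sender_type,
                            receiver_types, group_id,
                            qc = qc_thresholds(), filters = filter_config(),
                            min_cells = 3, background = c("all", "within_group")) {
  background <- match.arg(background)
  if (!inherits(prior, "interaction_prior")) prior <- load_interaction_prior(prior)
  validate_inputs(counts, annotation, sender_type, receiver_types, group_id)

  n_in <- ncol(counts)
  filtered <- filter_cells(counts, qc)
  if (ncol(filtered) == 0) {
    warning("no cells left after QC; empty report", call. = FALSE)
    return(list(records = list(), matrices = list(), de = NULL,
                report = list(cells_in = n_in, cells_after_qc = 0)))
  }
  ann <- annotation[annotation$cell_id %in% colnames(filtered), , drop = FALSE]
  nm <- normalize_counts(filtered)

  universe <- intersect(unique(c(prior$ligand, prior$receptor)), rownames(nm))
  if (length(universe) == 0 || nrow(prior) == 0) {
    warning("no prior gene present in the matrix; empty report", call. = FALSE)
    return(list(records = list(), matrices = list(), de = NULL,
                report = list(cells_in = n_in, cells_after_qc = ncol(filtered),
                              edges_loaded = nrow(prior), genes_tested = 0)))
  }
  de <- de_by_celltype_sample(nm, ann, universe, min_cells = min_cells,
                              background = background)
  group_samples <- unique(ann$sample_id[ann$group_id == group_id])

  records <- list(); matrices <- list()
  for (rt in receiver_types) {
    recs <- score_interactions(de, prior, sender_type, rt, group_id)
    recs <- flag_significant(recs, filters, samples = group_samples)
    records[[rt]] <- recs
    samp <- recs[recs$level == "sample", , drop = FALSE]
    if (nrow(samp)) {
      edges <- unique(paste(samp$ligand, samp$receptor, sep = "->"))
      m <- matrix(NA_real_, length(edges), length(group_samples),
                  dimnames = list(edges, group_samples))
      star <- matrix(FALSE, length(edges), length(group_samples),
                     dimnames = list(edges, group_samples))
      ij <- cbind(match(paste(samp$ligand, samp$receptor, sep = "->"), edges),
                  match(samp$sample_id, group_samples))
      m[ij] <- samp$rl_score
      star[ij] <- samp$significant
      matrices[[rt]] <- list(rl_score = m, significant = star)
    } else {
      matrices[[rt]] <- list(rl_score = matrix(NA_real_, 0, length(group_samples)),
                             significant = matrix(FALSE, 0, length(group_samples)))
    }
  }
  list(records = records, matrices = matrices, de = de,
       report = list(cells_in = n_in, cells_after_qc = ncol(filtered),
                     qc_removed = attr(filtered, "qc_removed"),
                     edges_loaded = nrow(prior), genes_tested = length(universe),
                     group_samples = group_samples))
}
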