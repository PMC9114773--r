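#' Quality-control thresholds for cell filtering
#'
#' Cells are removed when they have strictly fewer than `min_genes_detected`
#' genes detected, or a mitochondrial count fraction strictly greater than
#' `max_mito_fraction`. Ties are retained.
#'
#' @param min_genes_detected minimum genes with count > 0 (default 500).
#' @param max_mito_fraction maximum fraction of counts on mitochondrial genes
#'   (default 0.15).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"mt-"`, mouse nomenclature).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes_detected = 500, max_mito_fraction = 0.15,
                          mito_prefix = "mt-") {
  if (min_genes_detected < 0) stop("min_genes_detected must be >= 0", call. = FALSE)
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]", call. = FALSE)
  structure(list(min_genes_detected = min_genes_detected,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs gene rownames and cell colnames", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids", call. = FALSE)
  if (min(m) < 0) stop("count matrix has negative entries", call. = FALSE)
  invisible(m)
}

#' Remove low-quality cells from a count matrix
#'
#' Retains exactly the cells with `genes_detected >= min_genes_detected` and
#' `mito_fraction <= max_mito_fraction`; the gene set is unchanged. The
#' number of cells failing each criterion is attached as attribute
#' `qc_removed` (a named vector: `low_genes`, `high_mito`, `total_removed`).
#' The operation is idempotent.
#'
#' @param m gene x cell count matrix (dense or `Matrix` sparse) with
#'   rownames/colnames.
#' @param qc a [qc_thresholds()].
#' @return the filtered matrix; warns (does not error) if no cell survives.
#' @export
filter_cells <- function(m, qc = qc_thresholds()) {
  validate_counts(m)
  genes_detected <- Matrix::colSums(m > 0)
  totals <- Matrix::colSums(m)
  mito <- startsWith(rownames(m), qc$mito_prefix)
  mito_frac <- if (any(mito)) {
    f <- Matrix::colSums(m[mito, , drop = FALSE]) / totals
    f[totals == 0] <- 0
    f
  } else rep(0, ncol(m))
  low_genes <- genes_detected < qc$min_genes_detected
  high_mito <- mito_frac > qc$max_mito_fraction
  keep <- !(low_genes | high_mito)
  if (!any(keep)) warning("no cells pass QC; returning an empty matrix", call. = FALSE)
  out <- m[, keep, drop = FALSE]
  attr(out, "qc_removed") <- c(low_genes = sum(low_genes),
                               high_mito = sum(high_mito),
                               total_removed = sum(!keep))
  out
}

#' Per-cell log2 normalization
#'
#' Divides each cell's counts by the cell total, multiplies by 10,000 and
#' applies log2(x + 1). Cells with zero total counts map to all-zero columns.
#' For every cell with nonzero total, the inverse transform conserves the
#' 10,000 scale: sum over genes of (2^value - 1) equals 10,000.
#'
#' @param m gene x cell count matrix (dense or sparse).
#' @return matrix of the same class and dimnames on the log2 scale.
#' @export
normalize_counts <- function(m) {
  validate_counts(m)
  totals <- Matrix::colSums(m)
  scale <- ifelse(totals > 0, 1e4 / totals, 0)
  if (methods::is(m, "sparseMatrix")) {
    nm <- methods::as(m, "CsparseMatrix") %*% Matrix::Diagonal(x = scale)
    nm@x <- log2(nm@x + 1)
    dimnames(nm) <- dimnames(m)
    nm <- Matrix::drop0(nm)
  } else {
    nm <- log2(sweep(m, 2, scale, "*") + 1)
  }
  nm
}

#' Cell-type composition per sample and per group
#'
#' Computes the fraction of cells of each cell type within every sample and
#' every group. When `subset` is given, fractions are taken over cells of the
#' subset types only (e.g. "% of total epithelial cells"); a stratum with no
#' subset member cells gets NA fractions.
#'
#' @param ann cell annotation data.frame (`cell_id`, `cell_type`, `sample_id`,
#'   `group_id`).
#' @param subset optional character vector of cell types to restrict to.
#' @return data.frame with columns `level` ("sample" or "group"), `stratum`,
#'   `cell_type`, `n`, `fraction`.
#' @export
cell_composition <- function(ann, subset = NULL) {
  stopifnot(all(c("cell_type", "sample_id", "group_id") %in% names(ann)))
  types <- if (is.null(subset)) sort(unique(ann$cell_type)) else subset
  if (!is.null(subset)) {
    bad <- setdiff(subset, unique(ann$cell_type))
    if (length(bad)) warning("subset type(s) absent from annotation: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  }
  sub <- ann[ann$cell_type %in% types, , drop = FALSE]
  one_level <- function(level, strat_col) {
    strata <- unique(ann[[strat_col]])
    do.call(rbind, lapply(strata, function(s) {
      cells <- sub[sub[[strat_col]] == s, "cell_type"]
      n <- vapply(types, function(tp) sum(cells == tp), integer(1))
      total <- length(cells)
      data.frame(level = level, stratum = s, cell_type = types, n = n,
                 fraction = if (total > 0) n / total else NA_real_,
                 row.names = NULL)
    }))
  }
  rbind(one_level("sample", "sample_id"), one_level("group", "group_id"))
}
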