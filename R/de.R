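#' Two-part (hurdle) likelihood-ratio test for zero-inflated expression
#'
#' Tests whether a foreground cell population differs from a background
#' population in log-normalized expression of one gene, using the standard
#' hurdle construction for zero-inflated single-cell data: a discrete
#' component models detection (value > 0) with a binomial likelihood, and a
#' continuous component models the positive values with a Gaussian likelihood
#' (common variance), each with versus without the group indicator. The two
#' likelihood-ratio statistics are summed and referred to a chi-square
#' distribution with one degree of freedom per component actually fitted.
#'
#' Degenerate inputs are handled explicitly: a gene undetected in both
#' groups gives `p = 1`, `lrt_stat = 0`, `df = 0`; when every value is
#' positive in both groups the discrete component is dropped; the continuous
#' component is dropped when either group has no positive values, when fewer
#' than three positive values exist in total, or when the positive values are
#' constant within groups.
#'
#' @param fg,bg numeric vectors of log-normalized expression values for the
#'   foreground and background cells (both nonempty).
#' @return list with `lrt_stat`, `df`, `p`.
#' @export
hurdle_test <- function(fg, bg) {
  n1 <- length(fg); n2 <- length(bg)
  if (n1 == 0 || n2 == 0) stop("fg and bg must both be nonempty", call. = FALSE)
  k1 <- sum(fg > 0); k2 <- sum(bg > 0)
  stat <- 0; df <- 0L

  # discrete component: binomial LRT on detection
  K <- k1 + k2; N <- n1 + n2
  if (K > 0 && K < N) {
    ll <- function(k, n) {
      p <- k / n
      (if (k > 0) k * log(p) else 0) + (if (k < n) (n - k) * log(1 - p) else 0)
    }
    stat <- stat + max(0, 2 * (ll(k1, n1) + ll(k2, n2) - ll(K, N)))
    df <- df + 1L
  }

  # continuous component: Gaussian LRT on positive values, common variance
  x1 <- fg[fg > 0]; x2 <- bg[bg > 0]
  m1 <- length(x1); m2 <- length(x2)
  if (m1 >= 1 && m2 >= 1 && m1 + m2 >= 3) {
    rss1 <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    rss0 <- sum((c(x1, x2) - mean(c(x1, x2)))^2)
    if (rss1 > 0) {
      stat <- stat + max(0, (m1 + m2) * log(rss0 / rss1))
      df <- df + 1L
    }
  }

  if (df == 0L) return(list(lrt_stat = 0, df = 0L, p = 1))
  list(lrt_stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Log2 fold change between foreground and background on the linear scale
#'
#' Back-transforms log2-normalized values to the linear scale, takes group
#' means, adds a pseudocount and returns the log2 ratio:
#' `log2(mean(2^fg - 1) + pseudocount) - log2(mean(2^bg - 1) + pseudocount)`.
#' The pseudocount keeps the fold change finite for undetected genes; fold
#' changes are exactly antisymmetric under swapping the groups.
#'
#' @param fg,bg nonempty numeric vectors of log2-normalized values.
#' @param pseudocount added to both linear means (default 1).
#' @return the log2 fold change (foreground over background).
#' @export
log_fold_change <- function(fg, bg, pseudocount = 1) {
  if (length(fg) == 0 || length(bg) == 0)
    stop("fg and bg must both be nonempty", call. = FALSE)
  log2(mean(2^fg - 1) + pseudocount) - log2(mean(2^bg - 1) + pseudocount)
}

#' Fraction of cells detecting a gene
#'
#' @param v nonempty numeric vector of expression values.
#' @return fraction of entries strictly greater than 0.
#' @export
detection_fraction <- function(v) {
  if (length(v) == 0) stop("empty vector", call. = FALSE)
  mean(v > 0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over one family of tests; a thin
#' validating wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw p-values, all in \[0, 1\].
#' @return adjusted p-values in the original order, elementwise >= `p`.
#' @export
adjust_pvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Stratum-vs-background differential expression across all cell types and samples
#'
#' For every gene of `gene_set` and every (cell type, sample) stratum present
#' in the annotation, compares the cells of that stratum (foreground) against
#' the pooled background and records the hurdle-test p-value, the log2 fold
#' change, and detection fractions. The default background is every other
#' cell — all other cell types and all other samples pooled; with
#' `background = "within_group"` the pool is restricted to cells from samples
#' of the stratum's own group. Adjusted p-values are computed over the whole
#' table as one family (`family = "pooled"`) or within each stratum
#' (`family = "per_stratum"`). No fold-change or detection pre-filter is
#' applied: every requested gene is tested in every stratum.
#'
#' Strata with fewer than `min_cells` cells are not tested: their records are
#' emitted with `p = 1`, `lrt_stat = 0` and `status = "too_few_cells"`.
#'
#' @param nm gene x cell log2-normalized matrix (see [normalize_counts()]).
#' @param ann cell annotation data.frame covering every column of `nm`.
#' @param gene_set nonempty character vector of genes to test (must exist in
#'   `nm`).
#' @param min_cells minimum foreground stratum size (default 3).
#' @param family p-value adjustment family, `"pooled"` or `"per_stratum"`.
#' @param background `"all"` (complement of the stratum) or `"within_group"`.
#' @return data.frame with one row per (gene, cell_type, sample): `gene`,
#'   `cell_type`, `sample_id`, `group_id`, `log2fc`, `pct_fg`, `pct_bg`,
#'   `lrt_stat`, `df`, `p`, `p_adj`, `status`.
#' @export
de_by_celltype_sample <- function(nm, ann, gene_set, min_cells = 3,
                                  family = c("pooled", "per_stratum"),
                                  background = c("all", "within_group")) {
  family <- match.arg(family)
  background <- match.arg(background)
  if (length(gene_set) == 0) stop("gene_set must be nonempty", call. = FALSE)
  missing_genes <- setdiff(gene_set, rownames(nm))
  if (length(missing_genes))
    stop("gene(s) absent from matrix: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  if (!all(colnames(nm) %in% ann$cell_id))
    stop("annotation does not cover all cells in the matrix", call. = FALSE)
  ann <- ann[match(colnames(nm), ann$cell_id), , drop = FALSE]

  strata <- unique(ann[, c("cell_type", "sample_id", "group_id")])
  rows <- vector("list", nrow(strata))
  sub <- as.matrix(nm[gene_set, , drop = FALSE])
  for (i in seq_len(nrow(strata))) {
    ct <- strata$cell_type[i]; s <- strata$sample_id[i]; g <- strata$group_id[i]
    fg_idx <- ann$cell_type == ct & ann$sample_id == s
    bg_idx <- !fg_idx
    if (background == "within_group") bg_idx <- bg_idx & ann$group_id == g
    fg_m <- sub[, fg_idx, drop = FALSE]
    bg_m <- sub[, bg_idx, drop = FALSE]
    res <- data.frame(gene = gene_set, cell_type = ct, sample_id = s, group_id = g,
                      log2fc = NA_real_, pct_fg = NA_real_, pct_bg = NA_real_,
                      lrt_stat = 0, df = 0L, p = 1, p_adj = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    for (j in seq_along(gene_set)) {
      fg <- fg_m[j, ]; bg <- bg_m[j, ]
      res$pct_fg[j] <- detection_fraction(fg)
      res$pct_bg[j] <- detection_fraction(bg)
      res$log2fc[j] <- log_fold_change(fg, bg)
      if (sum(fg_idx) < min_cells || sum(bg_idx) < min_cells) {
        res$status[j] <- "too_few_cells"
      } else {
        ht <- hurdle_test(fg, bg)
        res$lrt_stat[j] <- ht$lrt_stat; res$df[j] <- ht$df; res$p[j] <- ht$p
      }
    }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (family == "pooled") {
    out$p_adj <- adjust_pvalues(out$p)
  } else {
    key <- paste(out$cell_type, out$sample_id)
    for (k in unique(key)) {
      idx <- key == k
      out$p_adj[idx] <- adjust_pvalues(out$p[idx])
    }
  }
  rownames(out) <- NULL
  out
}
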