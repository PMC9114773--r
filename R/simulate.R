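#' Simulation configuration for synthetic scRNA-seq counts
#'
#' Describes a negative-binomial count generator with per-cell library-size
#' variation, gene-level logistic dropout, a (cell type x sample x group)
#' design, and planted log2 fold changes on designated genes. The default
#' design mirrors a two-condition mouse study: one condition with three
#' biological replicates and one with two, five cell types including two
#' fibroblast subtypes, tumor, and squamous cells.
#'
#' Gene baseline means are drawn log-normal around `baseline_mean`, except
#' genes named in `planted_effects`, whose baseline is fixed at
#' `baseline_mean` so the planted contrast is not confounded with the
#' expression tail. Dropout is a gene-level property: each gene is assigned a
#' zeroing probability from a logistic curve in its log2 baseline mean, and
#' that probability is applied uniformly across cells, leaving linear-mean
#' ratios between cell populations unbiased.
#'
#' @param n_genes total number of genes (including mitochondrial genes).
#' @param cell_types character vector of cell-type labels.
#' @param groups named list mapping group id to a character vector of sample
#'   ids (each group needs at least one sample; sample ids must be globally
#'   unique).
#' @param cells_per_type_per_sample cells simulated for every
#'   (cell type, sample) stratum.
#' @param baseline_mean scalar NB mean around which gene baselines are drawn.
#' @param baseline_sdlog log-normal sd (natural-log scale) of gene baselines.
#' @param dispersion NB size parameter (variance = mu + mu^2 / dispersion).
#' @param library_size_spread sd (natural-log scale) of the per-cell
#'   log-normal scaling factor; 0 disables library-size variation.
#' @param dropout_midpoint,dropout_slope logistic dropout curve in log2
#'   (baseline mean + 1): P(zeroed) = plogis(slope * (midpoint - log2(mu+1))).
#'   A non-positive slope disables dropout only if midpoint is -Inf; use
#'   `dropout_slope = 0, dropout_midpoint = -Inf` for no dropout, or set
#'   the convenience `dropout = FALSE` in [simulate_counts()].
#' @param planted_effects data.frame with columns `gene`, `cell_type`,
#'   `sample_id` (a sample id or `"all"`), `log2fc`; NULL for none.
#' @param mito_gene_count number of genes named with the `mt-` prefix so the
#'   QC filter can recognize them.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60,
                       cell_types = c("CAF1", "CAF2", "tumor", "squamous", "other"),
                       groups = list(AOMDSS = c("AOM1", "AOM2", "AOM3"),
                                     APC = c("APC1", "APC2")),
                       cells_per_type_per_sample = 100,
                       baseline_mean = 2,
                       baseline_sdlog = 1,
                       dispersion = 2,
                       library_size_spread = 0.3,
                       dropout_midpoint = 1,
                       dropout_slope = 1,
                       planted_effects = NULL,
                       mito_gene_count = 5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cell_types = as.character(cell_types),
              groups = groups,
              cells_per_type_per_sample = as.integer(cells_per_type_per_sample),
              baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
              dispersion = dispersion, library_size_spread = library_size_spread,
              dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
              planted_effects = planted_effects,
              mito_gene_count = as.integer(mito_gene_count), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) stop("invalid sim_config field '", field, "': ", msg,
                                   call. = FALSE)
  if (cfg$n_genes < 1) err("n_genes", "must be a positive integer")
  if (length(cfg$cell_types) < 1 || anyDuplicated(cfg$cell_types))
    err("cell_types", "must be a non-empty set of unique labels")
  if (!is.list(cfg$groups) || is.null(names(cfg$groups)) ||
      any(!nzchar(names(cfg$groups))))
    err("groups", "must be a named list of sample-id vectors")
  samples <- unlist(cfg$groups, use.names = FALSE)
  if (any(lengths(cfg$groups) < 1)) err("groups", "every group needs >= 1 sample")
  if (anyDuplicated(samples)) err("groups", "sample ids must be globally unique")
  if (cfg$cells_per_type_per_sample < 1)
    err("cells_per_type_per_sample", "must be positive")
  for (f in c("baseline_mean", "baseline_sdlog", "dispersion")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        (f != "baseline_sdlog" && v <= 0) || (f == "baseline_sdlog" && v < 0))
      err(f, "must be a positive finite scalar")
  }
  if (cfg$library_size_spread < 0) err("library_size_spread", "must be >= 0")
  if (cfg$mito_gene_count < 0 || cfg$mito_gene_count > cfg$n_genes)
    err("mito_gene_count", "must be between 0 and n_genes")
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    need <- c("gene", "cell_type", "sample_id", "log2fc")
    if (!is.data.frame(pe) || !all(need %in% names(pe)))
      err("planted_effects", paste("must be a data.frame with columns",
                                   paste(need, collapse = ", ")))
    genes <- sim_gene_names(cfg)
    bad <- setdiff(pe$gene, genes)
    if (length(bad))
      err("planted_effects", paste("unknown gene(s):", paste(bad, collapse = ", ")))
    bad <- setdiff(pe$cell_type, cfg$cell_types)
    if (length(bad))
      err("planted_effects", paste("unknown cell_type(s):", paste(bad, collapse = ", ")))
    bad <- setdiff(pe$sample_id, c("all", samples))
    if (length(bad))
      err("planted_effects", paste("unknown sample_id(s):", paste(bad, collapse = ", ")))
    if (any(!is.finite(pe$log2fc))) err("planted_effects", "log2fc must be finite")
  }
  invisible(cfg)
}

#' @keywords internal
sim_gene_names <- function(cfg) {
  n_reg <- cfg$n_genes - cfg$mito_gene_count
  c(if (n_reg > 0) sprintf("gene%03d", seq_len(n_reg)),
    if (cfg$mito_gene_count > 0) sprintf("mt-gene%02d", seq_len(cfg$mito_gene_count)))
}

# expand "all" planted effects to one row per sample of the configured design
expand_planted <- function(cfg) {
  pe <- cfg$planted_effects
  samples <- unlist(cfg$groups, use.names = FALSE)
  if (is.null(pe) || nrow(pe) == 0)
    return(data.frame(gene = character(), cell_type = character(),
                      sample_id = character(), log2fc = numeric()))
  rows <- lapply(seq_len(nrow(pe)), function(i) {
    s <- if (pe$sample_id[i] == "all") samples else pe$sample_id[i]
    data.frame(gene = pe$gene[i], cell_type = pe$cell_type[i],
               sample_id = s, log2fc = pe$log2fc[i])
  })
  do.call(rbind, rows)
}

#' Simulate a gene x cell count matrix with planted fold changes
#'
#' Draws counts from NB(mean = baseline x cell scaling x 2^planted_log2fc,
#' size = dispersion), then zeroes entries with the gene-level dropout
#' probability. Cells are laid out as `cells_per_type_per_sample` cells for
#' every (cell type, sample) stratum of the configured design.
#'
#' @param config a [sim_config()].
#' @param dropout logical; set FALSE to disable the dropout step entirely
#'   (used e.g. when checking NB moments).
#' @return list with `counts` (sparse dgCMatrix, genes x cells),
#'   `annotation` (data.frame: cell_id, cell_type, sample_id, group_id) and
#'   `ground_truth` (list: `planted_log2fc` data.frame expanded to sample
#'   level, `gene_baseline` named vector, `dropout_prob` named vector).
#' @export
simulate_counts <- function(config, dropout = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_gene_names(config)
  samples <- unlist(config$groups, use.names = FALSE)
  sample_group <- rep(names(config$groups), lengths(config$groups))
  names(sample_group) <- samples

  planted <- expand_planted(config)
  baseline <- stats::rlnorm(config$n_genes, meanlog = log(config$baseline_mean),
                            sdlog = config$baseline_sdlog)
  names(baseline) <- genes
  if (nrow(planted)) baseline[unique(planted$gene)] <- config$baseline_mean

  # gene-level dropout probability (capture efficiency), constant across cells
  p_drop <- stats::plogis(config$dropout_slope *
                            (config$dropout_midpoint - log2(baseline + 1)))
  names(p_drop) <- genes
  if (!dropout) p_drop[] <- 0

  strata <- expand.grid(cell_type = config$cell_types, sample_id = samples,
                        stringsAsFactors = FALSE)
  n_per <- config$cells_per_type_per_sample
  n_cells <- nrow(strata) * n_per
  ann <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    cell_type = rep(strata$cell_type, each = n_per),
    sample_id = rep(strata$sample_id, each = n_per),
    stringsAsFactors = FALSE)
  ann$group_id <- unname(sample_group[ann$sample_id])

  scaling <- stats::rlnorm(n_cells, 0, config$library_size_spread)

  # per-stratum log2fc matrix (genes x strata), default 0
  lfc <- matrix(0, config$n_genes, nrow(strata),
                dimnames = list(genes, paste(strata$cell_type, strata$sample_id)))
  if (nrow(planted)) {
    key <- paste(planted$cell_type, planted$sample_id)
    for (i in seq_len(nrow(planted)))
      lfc[planted$gene[i], key[i]] <- lfc[planted$gene[i], key[i]] + planted$log2fc[i]
  }

  counts <- matrix(0L, config$n_genes, n_cells, dimnames = list(genes, ann$cell_id))
  for (j in seq_len(nrow(strata))) {
    idx <- ((j - 1) * n_per + 1):(j * n_per)
    mu <- outer(baseline * 2^lfc[, j], scaling[idx])
    x <- stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
    if (any(p_drop > 0)) {
      keep <- stats::runif(length(mu)) >= rep(p_drop, times = length(idx))
      x <- x * keep
    }
    counts[, idx] <- x
  }
  gt <- list(planted_log2fc = planted, gene_baseline = baseline,
             dropout_prob = p_drop)
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       annotation = ann, ground_truth = gt)
}

#' Simulate a ligand-receptor interaction prior
#'
#' Builds an edge list containing the designated true interactions plus decoy
#' edges between unperturbed genes, all directed with a known mode of action,
#' and optionally extra rows with a missing mode to exercise the loader's
#' subsetting filter.
#'
#' @param config the [sim_config()] that defines the gene universe.
#' @param true_edges data.frame with columns `ligand`, `receptor` (and
#'   optionally `sender`, `receiver`, carried through as ground truth).
#' @param n_decoys number of decoy ligand-receptor edges drawn from genes
#'   without planted effects.
#' @param n_modeless number of extra edges emitted with a missing mode (these
#'   should be dropped by [load_interaction_prior()]).
#' @param mode mode-of-action label for true and decoy edges.
#' @param seed integer seed for decoy sampling.
#' @return data.frame with columns `ligand`, `receptor`, `directed`, `mode`;
#'   attribute `decoy_edges` holds the decoy subset.
#' @export
simulate_interaction_prior <- function(config, true_edges, n_decoys,
                                       n_modeless = 0, mode = "stimulation",
                                       seed = config$seed) {
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  if (n_modeless < 0) stop("n_modeless must be >= 0", call. = FALSE)
  genes <- sim_gene_names(config)
  bad <- setdiff(c(true_edges$ligand, true_edges$receptor), genes)
  if (length(bad))
    stop("true_edges reference genes outside the configured universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  planted_genes <- unique(config$planted_effects$gene)
  free <- setdiff(genes, c(planted_genes, true_edges$ligand, true_edges$receptor))
  need <- 2 * (n_decoys + n_modeless)
  if (length(free) < need)
    stop("not enough unperturbed genes (", length(free), ") for ", n_decoys,
         " decoys and ", n_modeless, " modeless extras", call. = FALSE)
  picks <- matrix(sample(free, need), ncol = 2)
  decoys <- data.frame(ligand = character(), receptor = character())
  extras <- decoys
  if (n_decoys > 0)
    decoys <- data.frame(ligand = picks[seq_len(n_decoys), 1],
                         receptor = picks[seq_len(n_decoys), 2])
  if (n_modeless > 0)
    extras <- data.frame(ligand = picks[n_decoys + seq_len(n_modeless), 1],
                         receptor = picks[n_decoys + seq_len(n_modeless), 2])
  prior <- rbind(
    data.frame(ligand = true_edges$ligand, receptor = true_edges$receptor,
               directed = 1L, mode = mode),
    if (nrow(decoys)) data.frame(ligand = decoys$ligand, receptor = decoys$receptor,
                                 directed = 1L, mode = mode),
    if (nrow(extras)) data.frame(ligand = extras$ligand, receptor = extras$receptor,
                                 directed = 1L, mode = NA_character_))
  attr(prior, "decoy_edges") <- decoys
  prior
}

#' Multichannel-image simulation configuration
#'
#' Describes a synthetic multiplex immunofluorescence image: a stack of marker
#' channels into which geometric regions are painted at stated intensities,
#' plus Gaussian background noise. A channel map designates the tumor marker
#' and the marker pairs defining the two fibroblast subtypes, so ground-truth
#' normalized abundances can be computed analytically.
#'
#' @param height,width image size in pixels.
#' @param channels marker names, one per channel.
#' @param regions list of regions; each is a list with `shape` ("rect" or
#'   "disc"), its geometry (`x`, `y`, `w`, `h` for rect; `cx`, `cy`, `r` for
#'   disc; 1-based pixel coordinates), and `intensity`, a named vector of
#'   per-channel intensities (markers not named are untouched).
#' @param channel_map list with entries `tumor` (one marker), `caf1`, `caf2`
#'   (each >= 1 marker) used for ground-truth abundance.
#' @param background_noise_sd sd of additive Gaussian noise (clamped at 0).
#' @param seed integer seed.
#' @return validated list of class `image_config`.
#' @export
image_config <- function(height = 128, width = 128,
                         channels = c("Hoechst", "VIM", "SMA", "PDGFRa",
                                      "TNC", "bcatenin"),
                         regions = list(),
                         channel_map = list(tumor = "bcatenin",
                                            caf1 = c("VIM", "SMA"),
                                            caf2 = c("PDGFRa", "TNC")),
                         background_noise_sd = 0, seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              channels = as.character(channels), regions = regions,
              channel_map = channel_map,
              background_noise_sd = background_noise_sd, seed = as.integer(seed))
  class(cfg) <- "image_config"
  err <- function(msg) stop("invalid image_config: ", msg, call. = FALSE)
  if (cfg$height < 1 || cfg$width < 1) err("height and width must be positive")
  if (anyDuplicated(cfg$channels)) err("channel names must be unique")
  if (cfg$background_noise_sd < 0) err("background_noise_sd must be >= 0")
  cm <- cfg$channel_map
  if (!all(c("tumor", "caf1", "caf2") %in% names(cm)))
    err("channel_map needs entries tumor, caf1, caf2")
  bad <- setdiff(unlist(cm), cfg$channels)
  if (length(bad)) err(paste("channel_map markers not in channels:",
                             paste(bad, collapse = ", ")))
  if (length(cm$caf1) < 1 || length(cm$caf2) < 1)
    err("caf1 and caf2 need at least one marker each")
  for (i in seq_along(cfg$regions)) {
    r <- cfg$regions[[i]]
    if (is.null(r$shape) || !r$shape %in% c("rect", "disc"))
      err(paste0("region ", i, ": shape must be 'rect' or 'disc'"))
    if (any(r$intensity < 0)) err(paste0("region ", i, ": intensities must be >= 0"))
    bad <- setdiff(names(r$intensity), cfg$channels)
    if (length(bad)) err(paste0("region ", i, ": unknown channel(s) ",
                                paste(bad, collapse = ", ")))
    m <- region_mask(r, cfg$height, cfg$width, check = TRUE)
    if (!any(m)) err(paste0("region ", i, ": zero area"))
  }
  cfg
}

region_mask <- function(r, h, w, check = FALSE) {
  m <- matrix(FALSE, h, w)
  if (r$shape == "rect") {
    if (check && (r$w < 1 || r$h < 1))
      stop("invalid image_config: rect region has zero area", call. = FALSE)
    if (check && (r$x < 1 || r$y < 1 || r$x + r$w - 1 > w || r$y + r$h - 1 > h))
      stop("invalid image_config: rect region out of bounds", call. = FALSE)
    m[r$y:(r$y + r$h - 1), r$x:(r$x + r$w - 1)] <- TRUE
  } else {
    if (check && (r$cx - r$r < 1 || r$cy - r$r < 1 ||
                  r$cx + r$r > w || r$cy + r$r > h))
      stop("invalid image_config: disc region out of bounds", call. = FALSE)
    d2 <- outer((seq_len(h) - r$cy)^2, (seq_len(w) - r$cx)^2, "+")
    m[d2 <= r$r^2] <- TRUE
  }
  m
}

#' Simulate a multichannel immunofluorescence image with ground truth
#'
#' Paints each configured region into its mapped channels at the stated
#' intensity (overlapping regions take the pixelwise maximum), adds Gaussian
#' background noise clamped at zero, and records the exact pixel set of each
#' marker-positive region plus the analytic normalized abundances.
#'
#' @param config an [image_config()].
#' @return list with `image` (height x width x channel array, channel names in
#'   `dimnames[[3]]`) and `ground_truth` (list: `channel_masks` — logical
#'   masks of painted pixels per channel; `tumor_mask`, `caf1_mask`,
#'   `caf2_mask` — co-positive masks under the channel map; `abundance` —
#'   named vector of CAF1/CAF2 areas normalized to the tumor-mask area, NA if
#'   the tumor mask is empty).
#' @export
simulate_mxif_image <- function(config) {
  if (!inherits(config, "image_config")) config <- do.call(image_config, config)
  set.seed(config$seed)
  h <- config$height; w <- config$width
  img <- array(0, dim = c(h, w, length(config$channels)),
               dimnames = list(NULL, NULL, config$channels))
  painted <- lapply(config$channels, function(ch) matrix(FALSE, h, w))
  names(painted) <- config$channels
  for (r in config$regions) {
    m <- region_mask(r, h, w)
    for (ch in names(r$intensity)) {
      if (r$intensity[[ch]] > 0) {
        plane <- img[, , ch]
        plane[m] <- pmax(plane[m], r$intensity[[ch]])
        img[, , ch] <- plane
        painted[[ch]] <- painted[[ch]] | m
      }
    }
  }
  if (config$background_noise_sd > 0)
    img <- pmax(img + stats::rnorm(length(img), 0, config$background_noise_sd), 0)

  cm <- config$channel_map
  copos <- function(markers) Reduce(`&`, painted[markers])
  tumor <- painted[[cm$tumor]]
  caf1 <- copos(cm$caf1); caf2 <- copos(cm$caf2)
  ta <- sum(tumor)
  abundance <- c(CAF1 = if (ta > 0) sum(caf1 & tumor) / ta else NA_real_,
                 CAF2 = if (ta > 0) sum(caf2 & tumor) / ta else NA_real_)
  list(image = img,
       ground_truth = list(channel_masks = painted, tumor_mask = tumor,
                           caf1_mask = caf1, caf2_mask = caf2,
                           abundance = abundance))
}
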