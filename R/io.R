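#' Write a count matrix as MatrixMarket MTX plus gene/barcode TSVs
#'
#' @param m gene x cell matrix (dense or sparse).
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- Matrix::Matrix(as.matrix(m) * 1.0, sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return sparse dgCMatrix with gene rownames and cell colnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Write / read a cell annotation table (TSV)
#'
#' @param ann data.frame with columns cell_id, cell_type, sample_id, group_id.
#' @param path TSV path.
#' @return `read_cell_annotation` returns the data.frame.
#' @export
write_cell_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_annotation
#' @export
read_cell_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("cell_id", "cell_type", "sample_id", "group_id")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ann
}

#' Write an interaction prior as TSV
#'
#' Columns: ligand, receptor, directed (0/1), mode (blank when missing).
#'
#' @param prior data.frame of edges.
#' @param path TSV path.
#' @export
write_interaction_prior <- function(prior, path) {
  out <- prior
  out$mode[is.na(out$mode)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential-expression table as TSV
#'
#' @param de DE table from [de_by_celltype_sample()].
#' @param path TSV path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a multichannel image as TIFF plus a channel-map YAML
#'
#' Channels are stored as one 32-bit float TIFF directory each. Float TIFF
#' storage is defined on \[0, 1\], so intensities are divided by a global
#' `intensity_scale` (the image maximum, or 1 for an all-zero image) recorded
#' in the YAML together with the channel order and the marker roles.
#'
#' @param img height x width x channel array with named channels.
#' @param path TIFF path; the YAML is written next to it unless `yaml_path`
#'   is given.
#' @param channel_map list with marker roles (`tumor`, `caf1`, `caf2`);
#'   stored in the YAML.
#' @param yaml_path optional explicit YAML path.
#' @return list with `tiff` and `yaml` paths, invisibly.
#' @export
write_multichannel_tiff <- function(img, path, channel_map = NULL,
                                    yaml_path = NULL) {
  if (is.null(yaml_path)) yaml_path <- paste0(sub("\\.tiff?$", "", path), ".yaml")
  scale <- max(img, 1e-12)
  planes <- lapply(seq_len(dim(img)[3]), function(k) img[, , k] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = dimnames(img)[[3]], intensity_scale = scale)
  if (!is.null(channel_map)) meta$channel_map <- channel_map
  yaml::write_yaml(meta, yaml_path)
  invisible(list(tiff = path, yaml = yaml_path))
}

#' Read a multichannel image written by [write_multichannel_tiff()]
#'
#' @param path TIFF path.
#' @param yaml_path channel-map YAML path (default: next to the TIFF).
#' @return height x width x channel array, intensities rescaled; the parsed
#'   YAML is attached as attribute `channel_map_config`.
#' @export
read_multichannel_tiff <- function(path, yaml_path = NULL) {
  if (is.null(yaml_path)) yaml_path <- paste0(sub("\\.tiff?$", "", path), ".yaml")
  meta <- yaml::read_yaml(yaml_path)
  planes <- tiff::readTIFF(path, all = TRUE)
  img <- array(0, dim = c(dim(planes[[1]]), length(planes)),
               dimnames = list(NULL, NULL, meta$channels))
  for (k in seq_along(planes)) img[, , k] <- planes[[k]] * meta$intensity_scale
  attr(img, "channel_map_config") <- meta
  img
}

#' Write image ground truth as JSON
#'
#' Masks are stored as pixel index lists (1-based, column-major) so the file
#' stays plain text.
#'
#' @param gt ground-truth list from [simulate_mxif_image()].
#' @param path JSON path.
#' @export
write_image_ground_truth <- function(gt, path) {
  enc <- list(
    dim = dim(gt$tumor_mask),
    tumor_pixels = which(gt$tumor_mask),
    caf1_pixels = which(gt$caf1_mask),
    caf2_pixels = which(gt$caf2_mask),
    abundance = as.list(gt$abundance))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
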