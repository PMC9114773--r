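#' Threshold one channel of a multichannel image into a binary mask
#'
#' Marks pixels whose intensity strictly exceeds the threshold. The threshold
#' is either user-fixed or selected automatically with Otsu's bimodal
#' histogram method; either way it is recorded in the mask's `provenance`
#' attribute so the quantification is reproducible.
#'
#' @param img height x width x channel array with channel names in
#'   `dimnames[[3]]` (as produced by [simulate_mxif_image()] or
#'   [read_multichannel_tiff()]).
#' @param channel channel name or index.
#' @param threshold a numeric fixed threshold, or `"otsu"` for automatic
#'   selection (errors on a constant channel, suggesting a fixed threshold).
#' @return logical height x width matrix with attribute `provenance`
#'   (list: `channel`, `threshold`, `method`).
#' @export
threshold_channel <- function(img, channel, threshold = "otsu") {
  chans <- dimnames(img)[[3]]
  if (is.character(channel)) {
    if (!channel %in% chans) stop("unknown channel '", channel, "'", call. = FALSE)
    ch_name <- channel
  } else {
    if (channel < 1 || channel > dim(img)[3]) stop("channel index out of range",
                                                   call. = FALSE)
    ch_name <- if (!is.null(chans)) chans[channel] else as.character(channel)
  }
  plane <- img[, , channel]
  if (identical(threshold, "otsu")) {
    rng <- range(plane)
    if (diff(rng) == 0)
      stop("channel '", ch_name, "' has constant intensity; automatic ",
           "thresholding is undefined - supply a fixed threshold", call. = FALSE)
    thr <- EBImage::otsu(plane, range = rng, levels = 256L)
    method <- "otsu"
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold))
      stop("threshold must be a finite number or \"otsu\"", call. = FALSE)
    thr <- threshold
    method <- "fixed"
  }
  mask <- plane > thr
  attr(mask, "provenance") <- list(channel = ch_name, threshold = unname(thr),
                                   method = method)
  mask
}

#' Combine two binary masks pixelwise
#'
#' The default intersection encodes co-positivity: a pixel counts for a
#' fibroblast subtype only when positive for both of its markers. Union is
#' available for the looser overlay reading.
#'
#' @param a,b logical matrices of identical dimensions.
#' @param op `"intersection"` or `"union"`.
#' @return combined logical matrix; provenance of both inputs and the
#'   operation is attached.
#' @export
combine_masks <- function(a, b, op = c("intersection", "union")) {
  op <- match.arg(op)
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ", call. = FALSE)
  out <- if (op == "intersection") a & b else a | b
  attr(out, "provenance") <- list(op = op, a = attr(a, "provenance"),
                                  b = attr(b, "provenance"))
  out
}

#' Quantify fibroblast-subtype abundance within the tumor mask
#'
#' Restricts the subtype mask to the tumor region and normalizes its positive
#' area to the tumor-mask area, the mask-based abundance measure. Pixels
#' outside the tumor mask never affect the result, and the normalized
#' abundance always lies in \[0, 1\].
#'
#' @param caf_mask logical matrix for the fibroblast subtype.
#' @param tumor_mask logical matrix for the tumor region (nonempty).
#' @param image_id,caf_label identifiers carried into the record.
#' @return one-row data.frame: `image_id`, `caf_label`, `positive_area`,
#'   `tumor_area`, `normalized_abundance`.
#' @export
quantify_caf <- function(caf_mask, tumor_mask, image_id = NA_character_,
                         caf_label = NA_character_) {
  if (!all(dim(caf_mask) == dim(tumor_mask)))
    stop("mask dimensions differ", call. = FALSE)
  tumor_area <- sum(tumor_mask)
  if (tumor_area == 0)
    stop("empty tumor mask: normalized abundance is undefined", call. = FALSE)
  positive <- sum(caf_mask & tumor_mask)
  data.frame(image_id = image_id, caf_label = caf_label,
             positive_area = positive, tumor_area = tumor_area,
             normalized_abundance = positive / tumor_area,
             stringsAsFactors = FALSE)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Compares per-image abundance values between two groups with the classic
#' equal-variance Student's t: `df = n_x + n_y - 2`, two-sided p. Degenerate
#' zero-variance inputs return `p = 1` when the means are equal and `p = 0`
#' (with a warning) when they differ.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `df`, `p`.
#' @export
compare_groups <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values", call. = FALSE)
  df <- nx + ny - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t_stat = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means", call. = FALSE)
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_stat = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Mask-based CAF quantification of one multichannel image
#'
#' Thresholds the tumor marker and each fibroblast-subtype marker channel,
#' combines each subtype's marker masks (intersection by default), and
#' normalizes the subtype-positive area inside the tumor mask to the tumor
#' area.
#'
#' @param img height x width x channel array with named channels.
#' @param channel_map list with `tumor` (one marker), `caf1` and `caf2`
#'   (each a character vector of markers).
#' @param thresholds optional named numeric vector of fixed per-marker
#'   thresholds; markers not named use Otsu's method.
#' @param combine `"intersection"` (co-positivity, default) or `"union"`.
#' @param image_id identifier carried into the records.
#' @return data.frame with one row per subtype (CAF1, CAF2); attribute
#'   `provenance` records every threshold and the combination rule, and
#'   attribute `masks` holds the tumor and subtype masks.
#' @export
run_mxif_pipeline <- function(img, channel_map, thresholds = NULL,
                              combine = c("intersection", "union"),
                              image_id = NA_character_) {
  combine <- match.arg(combine)
  thr_for <- function(marker) {
    if (!is.null(thresholds) && marker %in% names(thresholds))
      thresholds[[marker]] else "otsu"
  }
  mask_for <- function(markers) {
    ms <- lapply(markers, function(mk) threshold_channel(img, mk, thr_for(mk)))
    Reduce(function(a, b) combine_masks(a, b, combine), ms)
  }
  tumor <- threshold_channel(img, channel_map$tumor, thr_for(channel_map$tumor))
  caf1 <- mask_for(channel_map$caf1)
  caf2 <- mask_for(channel_map$caf2)
  out <- rbind(quantify_caf(caf1, tumor, image_id, "CAF1"),
               quantify_caf(caf2, tumor, image_id, "CAF2"))
  attr(out, "provenance") <- list(
    combine = combine,
    tumor = attr(tumor, "provenance"),
    caf1 = attr(caf1, "provenance"),
    caf2 = attr(caf2, "provenance"))
  attr(out, "masks") <- list(tumor = tumor, CAF1 = caf1, CAF2 = caf2)
  out
}
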