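# Nuclear segmentation and per-cell intensity integration ("Target + Mask"):
# Hoechst channel -> label mask -> per-nucleus background-corrected
# integrated/mean intensity on every channel.

#' Segment nuclei from a Hoechst image
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' optional distance-transform watershed to split touching nuclei, area
#' filter, and relabeling to consecutive labels 1..K.
#'
#' A constant image yields an all-zero mask (no nuclei) rather than an
#' error; negative pixel values are an error. Thresholding operates on the
#' min-max normalised image, so segmentation is invariant to adding a
#' constant offset.
#'
#' @param hoechst_image 2D numeric matrix, non-negative.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value threshold in image units when
#'   `threshold_method = "fixed"`.
#' @param min_area minimum object area in px^2; smaller objects are dropped.
#' @param split_touching apply a distance-transform watershed to separate
#'   touching nuclei.
#' @param noise_floor_k for Otsu thresholding, the threshold is floored at
#'   `median + noise_floor_k * MAD` of the smoothed image, so a well with
#'   no cells (background and noise only) yields zero objects instead of
#'   noise speckle. Set 0 to disable.
#' @return integer label matrix (0 = background, k > 0 = nucleus k), labels
#'   consecutive 1..K.
#' @export
segment_nuclei <- function(hoechst_image,
                           smooth_sigma = 2,
                           threshold_method = c("otsu", "fixed"),
                           threshold_value = NULL,
                           min_area = 20,
                           split_touching = TRUE,
                           noise_floor_k = 6) {
  threshold_method <- match.arg(threshold_method)
  img <- as.matrix(hoechst_image)
  if (length(dim(img)) != 2L) stopf("expected a 2D image")
  if (any(img < 0)) stopf("image has negative pixel values")
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0L, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smooth_sigma)
  thr <- if (threshold_method == "otsu") {
    smv <- as.numeric(EBImage::imageData(sm))
    max(EBImage::otsu(sm, range = c(0, 1)),
        stats::median(smv) + noise_floor_k * stats::mad(smv))
  } else {
    if (is.null(threshold_value)) stopf("threshold_value required for fixed thresholding")
    (threshold_value - rng[1]) / diff(rng)
  }
  binary <- EBImage::fillHull(sm > thr)
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(binary))
  } else {
    EBImage::bwlabel(binary)
  }
  lab <- EBImage::imageData(labels)
  storage.mode(lab) <- "integer"
  # area filter + relabel to consecutive 1..K
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(areas >= min_area)
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  matrix(lab, nrow(img), ncol(img))
}

#' Count segmented cells
#'
#' Number of distinct non-zero labels; invariant to label permutation.
#'
#' @param mask integer label matrix.
#' @return integer cell count.
#' @export
count_cells <- function(mask) {
  length(setdiff(unique(as.integer(mask)), 0L))
}

#' Quantify every channel within each nucleus
#'
#' Applies a label mask to a well's channel images and returns one record
#' per nucleus: centroid, area, and per channel the mean and the
#' background-corrected integrated intensity (sum over mask pixels after
#' subtracting the per-channel background estimate from each pixel).
#' Integrated intensities may be negative after correction; they are kept,
#' not clipped.
#'
#' @param mask integer label matrix from [segment_nuclei()].
#' @param images named list of channel matrices (same shape as `mask`).
#' @param background background estimation: `"median_outside_mask"` (median
#'   of out-of-mask pixels, per channel), `"fixed"` (use
#'   `background_value`), or `"none"`.
#' @param background_value per-pixel background in a.u. when
#'   `background = "fixed"`.
#' @param expand_px expand each labelled nucleus by up to this many pixels
#'   (Voronoi-limited, so expanded cells never overlap) before integrating
#'   intensities. The default 12 px covers the dim outer skirt of a
#'   nucleus' fluorescent footprint that a global threshold cuts off;
#'   centroid and area are always reported from the unexpanded mask. Set 0
#'   to integrate strictly within the segmentation mask.
#' @param well_id well identifier stored in the table.
#' @return data.frame cell table: `well_id`, `cell_label`, `centroid_row`,
#'   `centroid_col`, `area`, then `<channel>_integrated` and
#'   `<channel>_mean` per channel.
#' @export
apply_mask <- function(mask, images,
                       background = c("median_outside_mask", "fixed", "none"),
                       background_value = 0,
                       expand_px = 12,
                       well_id = "well") {
  background <- match.arg(background)
  bad <- names(images)[vapply(images, function(im)
    !identical(dim(as.matrix(im)), dim(mask)), logical(1))]
  if (length(bad))
    stopf("channel image shape differs from mask for: %s", paste(bad, collapse = ", "))
  imask <- if (expand_px > 0) expand_labels(mask, expand_px) else mask
  labs <- as.integer(mask)
  inside <- labs > 0L
  K <- if (any(inside)) max(labs) else 0L
  idx <- labs[inside]
  area <- tabulate(idx, nbins = K)
  rows <- as.integer(row(mask))[inside] - 1L  # 0-based coordinates
  cols <- as.integer(col(mask))[inside] - 1L
  out <- data.frame(well_id = rep(well_id, K), cell_label = seq_len(K),
                    centroid_row = as.numeric(rowsum(rows, idx)) / area,
                    centroid_col = as.numeric(rowsum(cols, idx)) / area,
                    area = area)
  ilabs <- as.integer(imask)
  iin <- ilabs > 0L
  iidx <- ilabs[iin]
  iarea <- tabulate(iidx, nbins = K)
  for (ch in names(images)) {
    v <- as.numeric(images[[ch]])
    bg <- switch(background,
                 median_outside_mask = stats::median(v[!iin]),
                 fixed = background_value,
                 none = 0)
    sums <- if (K > 0) as.numeric(rowsum(v[iin], iidx)) else numeric(0)
    out[[int_col(ch)]] <- sums - iarea * bg
    out[[mean_col(ch)]] <- (sums - iarea * bg) / iarea
  }
  out
}

# Voronoi-limited label expansion: each background pixel within `px` of a
# labelled object joins its nearest object; expanded objects never merge.
expand_labels <- function(mask, px) {
  if (max(mask) == 0L) return(mask)
  binary <- EBImage::Image(mask > 0)
  dil <- EBImage::dilate(binary, EBImage::makeBrush(2L * as.integer(px) + 1L, "disc"))
  ex <- EBImage::propagate(EBImage::Image(matrix(0, nrow(mask), ncol(mask))),
                           EBImage::Image(mask), mask = dil, lambda = 1e8)
  out <- matrix(as.integer(EBImage::imageData(ex)), nrow(mask), ncol(mask))
  out
}

#' Segment a well and build its cell table in one step
#'
#' Convenience wrapper: [segment_nuclei()] on the Hoechst channel, then
#' [apply_mask()] over all channels.
#'
#' @param images named list of channel matrices including `"hoechst"`.
#' @param well_id well identifier.
#' @param seg_params list of arguments for [segment_nuclei()].
#' @param background,background_value passed to [apply_mask()].
#' @return data.frame cell table.
#' @export
quantify_well <- function(images, well_id = "well", seg_params = list(),
                          background = "median_outside_mask",
                          background_value = 0) {
  if (!"hoechst" %in% names(images)) stopf("no 'hoechst' channel in image set")
  mask <- do.call(segment_nuclei, c(list(images$hoechst), seg_params))
  apply_mask(mask, images, background = background,
             background_value = background_value, well_id = well_id)
}
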