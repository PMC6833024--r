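#' Threshold a probability map into a binary mask
#'
#' @param P probability matrix in `[0, 1]`.
#' @param threshold in `[0, 1]`; pixels with `P >= threshold` become 1.
#'   Default 0.5.
#' @return binary matrix.
#' @export
binarize <- function(P, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop("binarize: threshold must lie in [0, 1]")
  (P >= threshold) * 1L
}

#' Detect a square region of interest around a disc mask
#'
#' The tight bounding box of the mask is expanded by `margin` times its
#' larger dimension on each side and made square, then shifted/clipped to
#' stay inside the image.  An empty mask falls back to a centred box of half
#' the image side.  Boxes are 1-based and inclusive (`top:top+side-1`).
#'
#' @param od_mask binary matrix (stage-1 disc mask at source resolution).
#' @param margin expansion per side as a fraction of the bounding-box size.
#' @return list of class `roi_box`: `top`, `left`, `side`, `src_h`, `src_w`.
#' @export
detect_roi <- function(od_mask, margin = 0.5) {
  H <- nrow(od_mask); W <- ncol(od_mask)
  occ <- which(od_mask == 1, arr.ind = TRUE)
  if (nrow(occ) == 0) {
    side <- floor(min(H, W) / 2)
    top <- floor((H - side) / 2) + 1L
    left <- floor((W - side) / 2) + 1L
    return(new_roi(top, left, side, H, W))
  }
  r0 <- min(occ[, 1]); r1 <- max(occ[, 1])
  c0 <- min(occ[, 2]); c1 <- max(occ[, 2])
  ext <- max(r1 - r0 + 1, c1 - c0 + 1)
  side <- min(round(ext * (1 + 2 * margin)), H, W)
  ctr_r <- (r0 + r1) / 2
  ctr_c <- (c0 + c1) / 2
  top <- round(ctr_r - (side - 1) / 2)
  left <- round(ctr_c - (side - 1) / 2)
  top <- min(max(top, 1), H - side + 1)
  left <- min(max(left, 1), W - side + 1)
  new_roi(top, left, side, H, W)
}

new_roi <- function(top, left, side, src_h, src_w) {
  structure(list(top = as.integer(top), left = as.integer(left),
                 side = as.integer(side), src_h = as.integer(src_h),
                 src_w = as.integer(src_w)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI box: rows %d..%d, cols %d..%d (side %d in %d x %d)\n",
              x$top, x$top + x$side - 1, x$left, x$left + x$side - 1,
              x$side, x$src_h, x$src_w))
  invisible(x)
}

#' Crop a region of interest and resize it to the network side
#'
#' Images are resized bilinearly, masks by nearest neighbour.  When the ROI
#' side already equals `out_side` the crop is returned bit-identically.
#'
#' @param X image array or binary mask matrix.
#' @param roi an `roi_box` from [detect_roi()].
#' @param out_side output side, default 256 (cup-stage input).
#' @return cropped-and-resized array/matrix.
#' @export
crop_resize <- function(X, roi, out_side = 256L) {
  d <- dim(X)
  if (roi$top < 1 || roi$left < 1 ||
      roi$top + roi$side - 1 > d[1] || roi$left + roi$side - 1 > d[2])
    stop("crop_resize: ROI lies outside the image")
  rows <- roi$top:(roi$top + roi$side - 1)
  cols <- roi$left:(roi$left + roi$side - 1)
  cropped <- if (length(d) == 3L) X[rows, cols, , drop = FALSE]
             else X[rows, cols, drop = FALSE]
  if (roi$side == out_side) return(cropped)
  resize_grid(cropped, out_side, out_side)
}

#' Restore a cup mask predicted inside an ROI to source coordinates
#'
#' The ROI-sized mask is resized back to the ROI side (nearest neighbour) and
#' pasted at the recorded position into a zero mask of the source size.
#'
#' @param oc_roi_mask square binary matrix (stage-2 output).
#' @param roi the `roi_box` used for the crop.
#' @return binary matrix of size `src_h x src_w`.
#' @export
restore_mask <- function(oc_roi_mask, roi) {
  if (nrow(oc_roi_mask) != ncol(oc_roi_mask))
    stop("restore_mask: ROI mask must be square")
  m <- if (nrow(oc_roi_mask) == roi$side) oc_roi_mask
       else resize_grid(oc_roi_mask, roi$side, roi$side)
  out <- matrix(0L, roi$src_h, roi$src_w)
  out[roi$top:(roi$top + roi$side - 1),
      roi$left:(roi$left + roi$side - 1)] <- m
  out
}

#' Two-stage disc and cup segmentation of one fundus image
#'
#' Stage 1: resize the image to the disc network side, predict, binarize at
#' 0.5 and resize the disc mask back to source resolution.  Stage 2: detect
#' a square ROI around the disc, crop and resize to the cup network side,
#' predict, binarize, and restore the cup mask to source coordinates.
#'
#' @param X image array `H x W x 3` (any size; resized anisotropically).
#' @param od_net,oc_net `msmku` networks for disc and cup.
#' @param roi_margin ROI expansion per side, see [detect_roi()].
#' @param threshold binarization threshold.
#' @return `list(od_mask =, oc_mask =, roi =)`, masks at the input size.
#' @export
segment_fundus <- function(X, od_net, oc_net, roi_margin = 0.5,
                           threshold = 0.5) {
  d <- dim(X)
  od_side <- od_net$config$input_side
  oc_side <- oc_net$config$input_side
  x_od <- if (d[1] == od_side && d[2] == od_side) X
          else resize_grid(X, od_side, od_side)
  od_p <- predict(od_net, x_od, type = "prob")
  od_small <- binarize(od_p, threshold)
  od_mask <- if (all(d[1:2] == od_side)) od_small
             else resize_grid(od_small, d[1], d[2])
  roi <- detect_roi(od_mask, margin = roi_margin)
  x_oc <- crop_resize(X, roi, out_side = oc_side)
  oc_p <- predict(oc_net, x_oc, type = "prob")
  oc_roi <- binarize(oc_p, threshold)
  oc_mask <- restore_mask(oc_roi, roi)
  list(od_mask = od_mask, oc_mask = oc_mask, roi = roi)
}
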