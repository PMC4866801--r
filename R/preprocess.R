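# Mask construction. M1 delimits the seed for size/shape; M2 additionally
# drops pixels at or below the height threshold (default 20 units) whose
# colour readings are corrupted by boundary shadowing.

assert_stack <- function(stack) {
  if (!inherits(stack, "image_stack")) stop("not an image_stack")
  dims <- vapply(stack$intensity, function(m) base::dim(m), integer(2))
  if (any(dims[1, ] != nrow(stack$height)) ||
      any(dims[2, ] != ncol(stack$height))) {
    stop("channel and height images must share dimensions")
  }
  invisible(stack)
}

#' Segment a seed image into its binary mask M1
#'
#' Single seeds lie on an exactly-zero background, so segmentation thresholds
#' the height map at a small floor, applies a 3x3 morphological closing,
#' fills interior holes, and keeps the largest 4-connected component.
#'
#' @param stack An `image_stack`.
#' @param floor Height floor in height units (default 1).
#' @return Logical matrix M1: a single 4-connected, hole-free component.
#' @export
segment_seed <- function(stack, floor = 1) {
  assert_stack(stack)
  m0 <- stack$height > floor
  if (!any(m0)) stop("no seed found: height image has no pixel above floor")
  m <- .erode3(.dilate3(m0))
  m <- m | m0            # closing must not erase thin originals entirely
  m <- .fill_holes(m)
  lab <- .cc_label(m)
  tab <- tabulate(lab[lab > 0L])
  m1 <- lab == which.max(tab)
  storage.mode(m1) <- "logical"
  m1
}

#' Height-thresholded mask M2
#'
#' `M2 = M1 & (height > threshold)`; used for all colour and height
#' measurements so that shadowed low-height boundary pixels are excluded.
#'
#' @param stack An `image_stack`.
#' @param m1 Logical segmentation mask.
#' @param threshold Height threshold in height units (default 20).
#' @return Logical matrix M2 (subset of M1).
#' @export
height_mask <- function(stack, m1, threshold = 20) {
  assert_stack(stack)
  stopifnot(is.logical(m1), threshold >= 0)
  if (!any(m1)) stop("m1 is empty")
  m2 <- m1 & (stack$height > threshold)
  if (!any(m2)) {
    stop("seed below height threshold: no pixel of M1 exceeds ", threshold)
  }
  m2
}

#' Build both masks for a seed image
#'
#' @param stack An `image_stack`.
#' @param threshold Height threshold for M2 (default 20 height units).
#' @param floor Segmentation height floor for M1 (default 1).
#' @return A `mask_pair`: list with `m1`, `m2`, `height_threshold`.
#' @export
mask_pair <- function(stack, threshold = 20, floor = 1) {
  m1 <- segment_seed(stack, floor = floor)
  m2 <- height_mask(stack, m1, threshold = threshold)
  structure(list(m1 = m1, m2 = m2, height_threshold = threshold),
            class = "mask_pair")
}
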