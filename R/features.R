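# The thirteen per-seed features: six height-corrected colour factors,
# seed height, equivalent diameter, area, plumpness, perimeter, volume,
# circularity. Sample value = coordinate-wise median across seeds;
# standardisation is always against the calibration set.

#' Height-corrected colour factors of one seed
#'
#' Within M2, each pixel's colour value is divided by its surface height,
#' removing the (linear) height dependence of intensity; the channel factor
#' is the median of the corrected values. For noise-free imagery with
#' intensity proportional to height, the factor equals the proportionality
#' constant exactly.
#'
#' @param stack An `image_stack`.
#' @param m2 Logical height-thresholded mask (all in-mask heights > 0).
#' @return Named numeric length-6: `violet_factor` .. `nir_factor`.
#' @export
colour_factors <- function(stack, m2) {
  assert_stack(stack)
  if (!any(m2)) stop("m2 is empty")
  h <- stack$height[m2]
  if (any(h <= 0)) {
    stop("internal error: zero height inside M2 (threshold not applied?)")
  }
  out <- vapply(stack$intensity, function(im) median(im[m2] / h), 0)
  stats::setNames(out, paste0(CHANNELS, "_factor"))
}

#' Size, shape and height features of one seed
#'
#' * `area`: pixel count of M1.
#' * `perimeter`: length of the traced 8-connected boundary chain of M1
#'   (diagonal steps weighted sqrt(2)).
#' * `equivalent_diameter`: diameter of the circle of equal area,
#'   `2 * sqrt(area / pi)`.
#' * `volume`: sum of the height image over M1.
#' * `seed_height`: median height within M2.
#' * `circularity`: `(area * 4) / (equivalent_diameter * perimeter)`; ~1 for
#'   a disk, decreasing with elongation.
#' * `plumpness`: `seed_height / equivalent_diameter`, a dome-fullness ratio
#'   that drops when seeds shrivel.
#'
#' @param stack An `image_stack`.
#' @param masks A `mask_pair`.
#' @return Named numeric length-7.
#' @export
size_shape_features <- function(stack, masks) {
  assert_stack(stack)
  stopifnot(inherits(masks, "mask_pair"))
  m1 <- masks$m1; m2 <- masks$m2
  if (!any(m1) || !any(m2)) stop("empty mask")
  area <- sum(m1)
  perimeter <- .boundary_chain_length(m1)
  equivalent_diameter <- 2 * sqrt(area / pi)
  volume <- sum(stack$height[m1])
  seed_height <- median(stack$height[m2])
  circularity <- (area * 4) / (equivalent_diameter * perimeter)
  plumpness <- seed_height / equivalent_diameter
  c(seed_height = seed_height, equivalent_diameter = equivalent_diameter,
    area = area, plumpness = plumpness, perimeter = perimeter,
    volume = volume, circularity = circularity)
}

#' All thirteen features of one seed
#'
#' @param stack An `image_stack`.
#' @param masks Optional `mask_pair`; computed with defaults when omitted.
#' @param threshold Height threshold used when `masks` is omitted.
#' @return Named numeric length-13 in [feature_names()] order.
#' @export
seed_features <- function(stack, masks = NULL, threshold = 20) {
  if (is.null(masks)) masks <- mask_pair(stack, threshold = threshold)
  out <- c(colour_factors(stack, masks$m2),
           size_shape_features(stack, masks))
  out[FEATURE_NAMES]
}

#' Aggregate per-seed features to one sample feature vector
#'
#' The sample value of each feature is the median across the sample's seeds;
#' even counts use the midpoint of the two central order statistics.
#'
#' @param seed_feats List of named numeric vectors (one per seed) or a matrix
#'   with one row per seed.
#' @return Named numeric vector of coordinate-wise medians.
#' @export
sample_features <- function(seed_feats) {
  if (is.list(seed_feats)) {
    if (!length(seed_feats)) stop("no seed features supplied")
    seed_feats <- do.call(rbind, seed_feats)
  }
  if (!is.matrix(seed_feats) || nrow(seed_feats) == 0L) {
    stop("no seed features supplied")
  }
  apply(seed_feats, 2, median)
}

#' Extract the per-sample feature table of a dataset
#'
#' Renders each sample's seeds (from stored stacks or from the render plan),
#' builds masks, extracts the 13 features per seed and takes sample medians.
#' Stacks are discarded after use, so the full default design runs in
#' bounded memory.
#'
#' @param dataset A `pea_dataset`.
#' @param threshold Height threshold for M2 (default 20).
#' @return Data frame: `sample_id`, `grade`, `split`, `defective`, then the
#'   13 feature columns in [feature_names()] order.
#' @export
extract_features <- function(dataset, threshold = 20) {
  stopifnot(inherits(dataset, "pea_dataset"))
  rows <- vector("list", length(dataset$samples))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    stacks <- render_sample(dataset, i)
    feats <- lapply(stacks, function(st) {
      seed_features(st, threshold = threshold)
    })
    med <- sample_features(feats)
    rows[[i]] <- data.frame(sample_id = s$sample_id, grade = s$grade,
                            split = s$split, defective = s$defective,
                            t(med), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a feature standardiser on calibration samples
#'
#' Stores per-feature mean and standard deviation so that the calibration
#' matrix maps to zero mean and unit sd; validation samples are always scaled
#' with the calibration parameters, never their own.
#'
#' @param x Data frame or matrix of calibration feature values (feature
#'   columns only, or a feature table from [extract_features()], whose
#'   metadata columns are ignored).
#' @return A `standardiser` with `$mean` and `$sd` per feature.
#' @export
fit_standardiser <- function(x) {
  x <- feature_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 calibration records")
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  bad <- names(sdv)[sdv <= 0 | !is.finite(sdv)]
  if (length(bad)) {
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv), class = "standardiser")
}

#' Apply a fitted standardiser
#'
#' @param std A `standardiser`.
#' @param x Feature table (data frame with metadata columns preserved) or
#'   matrix.
#' @return Same shape as `x` with feature columns replaced by
#'   `(x - mean) / sd`.
#' @export
apply_standardiser <- function(std, x) {
  stopifnot(inherits(std, "standardiser"))
  feats <- names(std$mean)
  if (is.data.frame(x) && all(feats %in% names(x))) {
    for (f in feats) x[[f]] <- (x[[f]] - std$mean[[f]]) / std$sd[[f]]
    return(x)
  }
  x <- feature_matrix(x)
  x <- sweep(x[, feats, drop = FALSE], 2, std$mean, "-")
  sweep(x, 2, std$sd, "/")
}

# pull the numeric feature columns out of a table that may carry metadata
feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- intersect(FEATURE_NAMES, names(x))
    if (!length(keep)) keep <- names(x)[vapply(x, is.numeric, NA)]
    x <- as.matrix(x[, keep, drop = FALSE])
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
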