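# Plain-text serialisation: image stacks as per-channel TSV matrices plus a
# JSON header, dataset manifests and feature tables as TSV, the standardiser
# as a key-value file, LDA models as JSON.

#' Write an image stack to a directory of plain-text matrices
#'
#' Layout: `stack.json` (dimensions, channel order) plus one TSV matrix per
#' channel (`violet.tsv` .. `nir.tsv`) and `height.tsv`.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  assert_stack(stack)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dim = base::dim(stack$height), channels = CHANNELS),
    file.path(dir, "stack.json"), auto_unbox = FALSE
  )
  wm <- function(m, f) {
    write.table(format(m, digits = 9, trim = TRUE, scientific = TRUE),
                file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  for (ch in CHANNELS) wm(stack$intensity[[ch]], paste0(ch, ".tsv"))
  wm(stack$height, "height.tsv")
  invisible(dir)
}

#' Read an image stack written by [write_stack()]
#'
#' @param dir Directory containing `stack.json` and the channel TSVs.
#' @return An `image_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  rm_ <- function(f) {
    as.matrix(read.delim(file.path(dir, f), header = FALSE,
                         colClasses = "numeric"))
  }
  intensity <- lapply(stats::setNames(CHANNELS, CHANNELS), function(ch) {
    m <- rm_(paste0(ch, ".tsv")); dimnames(m) <- NULL; m
  })
  height <- rm_("height.tsv"); dimnames(height) <- NULL
  stopifnot(all(base::dim(height) == meta$dim))
  new_image_stack(intensity, height)
}

#' Write a dataset's imagery and manifest to disk
#'
#' One directory per seed (`<sample_id>/seed_<k>/`) and a `manifest.tsv`
#' with columns `sample_id`, `grade`, `split`, `defective`,
#' `seed_image_paths` (semicolon-separated, relative to `dir`).
#'
#' @param dataset A `pea_dataset`.
#' @param dir Output directory.
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pea_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    stacks <- render_sample(dataset, i)
    paths <- vapply(seq_along(stacks), function(k) {
      p <- file.path(s$sample_id, sprintf("seed_%02d", k))
      write_stack(stacks[[k]], file.path(dir, p))
      p
    }, "")
    data.frame(sample_id = s$sample_id, grade = s$grade, split = s$split,
               defective = s$defective,
               seed_image_paths = paste(paths, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the per-sample feature table from an on-disk manifest
#'
#' @param manifest_path Path to a `manifest.tsv` written by
#'   [write_dataset()].
#' @param threshold Height threshold for M2.
#' @return Feature data frame as from [extract_features()].
#' @export
extract_features_manifest <- function(manifest_path, threshold = 20) {
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  root <- dirname(manifest_path)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    paths <- strsplit(manifest$seed_image_paths[i], ";", fixed = TRUE)[[1]]
    feats <- lapply(paths, function(p) {
      seed_features(read_stack(file.path(root, p)), threshold = threshold)
    })
    data.frame(manifest[i, c("sample_id", "grade", "split", "defective")],
               t(sample_features(feats)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write/read a per-sample feature table as TSV
#'
#' @param features Feature data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write/read a fitted standardiser as a key-value text file
#'
#' @param std A `standardiser`.
#' @param path File path.
#' @return `path` (write) or the `standardiser` (read).
#' @export
write_standardiser <- function(std, path) {
  stopifnot(inherits(std, "standardiser"))
  df <- data.frame(feature = names(std$mean), mean = unname(std$mean),
                   sd = unname(std$sd))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_standardiser
#' @export
read_standardiser <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(mean = stats::setNames(df$mean, df$feature),
                 sd = stats::setNames(df$sd, df$feature)),
            class = "standardiser")
}

#' Write/read a fitted LDA model as JSON
#'
#' @param model An `lda_model`.
#' @param path File path.
#' @return `path` (write) or the `lda_model` (read).
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         class_labels = model$class_labels,
         class_means = model$class_means,
         pooled_cov = model$pooled_cov,
         priors = model$priors,
         prior_weights = model$prior_weights),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr, byrow = TRUE) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nr, byrow = byrow)
  }
  means <- as_mat(j$class_means, length(j$class_labels))
  dimnames(means) <- list(j$class_labels, j$feature_names)
  pc <- as_mat(j$pooled_cov, length(j$feature_names))
  dimnames(pc) <- list(j$feature_names, j$feature_names)
  ch <- chol(pc)
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(pc)
  structure(list(feature_names = j$feature_names,
                 class_labels = j$class_labels,
                 class_means = means, pooled_cov = pc, pooled_cov_inv = inv,
                 priors = j$priors, prior_weights = j$prior_weights),
            class = "lda_model")
}
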