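# Linear discriminant analysis with nearest-Mahalanobis classification,
# ANOVA-F/SVD feature screening, greedy forward feature selection and
# Mahalanobis diagnostics. Written from first principles: class means, pooled
# within-class covariance Sigma = sum_k (n_k - 1) S_k / (N - K), and
# d_k(x) = sqrt((x - mu_k)' Sigma^{-1} (x - mu_k)).

#' Screen features by one-way ANOVA F and matrix rank
#'
#' For every feature column, the one-way F statistic across groups
#' (`F = (SSB/df_b) / (SSW/df_w)`) with its p-value; additionally the
#' singular values of the feature matrix and a full-rank flag (smallest
#' singular value > `tol` x largest), plus Wilks' lambda of the one-way
#' multivariate analysis.
#'
#' @param x Feature table (data frame or matrix; metadata columns ignored).
#' @param groups Group label per row (>= 2 groups, each >= 2 records).
#' @param tol Relative singular-value tolerance for the rank decision.
#' @return A `screen_report`: `$table` (feature, F, df1, df2, p),
#'   `$singular_values`, `$full_rank`, `$wilks_lambda`.
#' @export
screen_features <- function(x, groups, tol = 1e-8) {
  xm <- feature_matrix(x)
  groups <- as.character(groups)
  stopifnot(nrow(xm) == length(groups))
  cnt <- table(groups)
  if (length(cnt) < 2L) stop("need at least 2 groups")
  if (any(cnt < 2L)) {
    stop("group(s) with fewer than 2 records: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  }
  n <- nrow(xm); k <- length(cnt)
  df1 <- k - 1L; df2 <- n - k
  grand <- colMeans(xm)
  ssb <- numeric(ncol(xm)); ssw <- numeric(ncol(xm))
  for (g in names(cnt)) {
    sub <- xm[groups == g, , drop = FALSE]
    mg <- colMeans(sub)
    ssb <- ssb + nrow(sub) * (mg - grand)^2
    ssw <- ssw + colSums(sweep(sub, 2, mg)^2)
  }
  fstat <- (ssb / df1) / (ssw / df2)
  pval <- pf(fstat, df1, df2, lower.tail = FALSE)
  sv <- svd(xm, nu = 0, nv = 0)$d
  # Wilks' lambda = det(W) / det(B + W)
  wmat <- matrix(0, ncol(xm), ncol(xm))
  for (g in names(cnt)) {
    sub <- sweep(xm[groups == g, , drop = FALSE], 2,
                 colMeans(xm[groups == g, , drop = FALSE]))
    wmat <- wmat + crossprod(sub)
  }
  tmat <- crossprod(sweep(xm, 2, grand))
  wilks <- tryCatch(det(wmat) / det(tmat), error = function(e) NA_real_)
  structure(
    list(table = data.frame(feature = colnames(xm), F = fstat,
                            df1 = df1, df2 = df2, p = pval,
                            row.names = NULL, stringsAsFactors = FALSE),
         singular_values = sv,
         full_rank = min(sv) > tol * max(sv),
         wilks_lambda = wilks),
    class = "screen_report"
  )
}

#' Fit a linear discriminant model
#'
#' Class means are per-class arithmetic means; the pooled within-class
#' covariance is the df-weighted average of per-class sample covariances.
#' Its inverse is computed once via a Cholesky factorisation and cached.
#'
#' @param x Feature table (data frame or matrix).
#' @param grouping Class label per row; every class needs >= 2 records and
#'   `N - K` must be at least the number of features.
#' @param features Feature columns to use (default: all feature columns).
#' @param priors `"equal"` (pure nearest-Mahalanobis, the default) or
#'   `"proportional"` (class frequencies enter the decision rule as
#'   `-2 log pi_k`).
#' @return An `lda_model`: `feature_names`, `class_labels` (declared order =
#'   order of first appearance unless `grouping` is a factor), `class_means`,
#'   `pooled_cov`, `pooled_cov_inv`, `priors`, `prior_weights`.
#' @export
fit_lda <- function(x, grouping, features = NULL,
                    priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  if (is.data.frame(x) && !is.null(features)) {
    x <- x[, features, drop = FALSE]
  }
  xm <- feature_matrix(x)
  if (!is.null(features)) {
    if (!all(features %in% colnames(xm))) {
      stop("missing feature(s): ",
           paste(setdiff(features, colnames(xm)), collapse = ", "))
    }
    xm <- xm[, features, drop = FALSE]
  }
  labels <- if (is.factor(grouping)) levels(droplevels(grouping)) else
    unique(as.character(grouping))
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(xm))
  cnt <- table(grouping)[labels]
  if (any(is.na(cnt)) || any(cnt < 2L)) {
    stop("every class needs at least 2 records")
  }
  n <- nrow(xm); k <- length(labels); p <- ncol(xm)
  if (n - k < p) {
    stop("pooled covariance is singular (N - K < p): reduce the feature set")
  }
  means <- matrix(NA_real_, k, p, dimnames = list(labels, colnames(xm)))
  pooled <- matrix(0, p, p, dimnames = list(colnames(xm), colnames(xm)))
  for (g in labels) {
    sub <- xm[grouping == g, , drop = FALSE]
    means[g, ] <- colMeans(sub)
    pooled <- pooled + crossprod(sweep(sub, 2, means[g, ]))
  }
  pooled <- pooled / (n - k)
  ch <- tryCatch(chol(pooled), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular: reduce or decorrelate the feature set")
  }
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(pooled)
  structure(
    list(feature_names = colnames(xm), class_labels = labels,
         class_means = means, pooled_cov = pooled, pooled_cov_inv = inv,
         priors = priors,
         prior_weights = as.numeric(cnt) / n),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: %d classes, %d features (%s priors)>\n",
              length(x$class_labels), length(x$feature_names), x$priors))
  cat(" classes: ", paste(x$class_labels, collapse = ", "), "\n")
  cat(" features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Classify records by nearest Mahalanobis distance to a class mean
#'
#' Distance to class k is `sqrt((x - mu_k)' Sigma^{-1} (x - mu_k))` with the
#' pooled within-class covariance. With equal priors the predicted label
#' minimises the distance (ties broken by declared class order); with
#' proportional priors the decision minimises `d^2 - 2 log pi_k` while
#' reported distances stay raw.
#'
#' @param model An `lda_model`.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns.
#' @return Data frame: `predicted`, `nearest_distance`, then one
#'   `dist_<class>` column per class.
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "lda_model"))
  xm <- feature_matrix(newdata)
  missing <- setdiff(model$feature_names, colnames(xm))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  xm <- xm[, model$feature_names, drop = FALSE]
  k <- length(model$class_labels)
  d2 <- matrix(NA_real_, nrow(xm), k)
  for (j in seq_len(k)) {
    cen <- sweep(xm, 2, model$class_means[j, ])
    d2[, j] <- rowSums((cen %*% model$pooled_cov_inv) * cen)
  }
  d2[d2 < 0] <- 0  # guard tiny negative rounding
  crit <- d2
  if (model$priors == "proportional") {
    crit <- sweep(d2, 2, 2 * log(model$prior_weights), "-")
  }
  pick <- apply(crit, 1, which.min)  # first minimum = declared-order tie-break
  dist <- sqrt(d2)
  out <- data.frame(predicted = model$class_labels[pick],
                    nearest_distance = dist[cbind(seq_len(nrow(dist)), pick)],
                    stringsAsFactors = FALSE)
  dcols <- as.data.frame(dist)
  names(dcols) <- paste0("dist_", gsub(" ", "_", model$class_labels))
  cbind(out, dcols)
}

#' Greedy forward feature selection for an LDA model
#'
#' Candidates are visited once, in the given preference order (colour, then
#' size, then shape). A candidate is kept if and only if refitting the model
#' with it strictly increases classification accuracy on the supplied
#' (calibration) records; candidates whose addition makes the fit singular
#' are treated as non-improving.
#'
#' @param x Feature table of calibration records.
#' @param grouping True class label per row.
#' @param candidates Character vector of feature names in preference order.
#' @param priors Passed to [fit_lda()].
#' @return Character vector of kept features (a subsequence of `candidates`).
#' @export
forward_select <- function(x, grouping, candidates,
                           priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  stopifnot(length(candidates) >= 1L)
  grouping <- as.character(grouping)
  kept <- character(0)
  best <- 0
  for (cand in candidates) {
    acc <- tryCatch({
      m <- fit_lda(x, grouping, features = c(kept, cand), priors = priors)
      mean(classify(m, x)$predicted == grouping)
    }, error = function(e) NA_real_)
    if (!is.na(acc) && acc > best) {
      kept <- c(kept, cand)
      best <- acc
    }
  }
  if (!length(kept)) stop("no candidate feature yields a fittable model")
  kept
}

#' Mean nearest-class-mean Mahalanobis distance by defect status
#'
#' Diagnostic behind the observation that defective samples sit further from
#' their nearest market-grade mean than non-defective ones.
#'
#' @param model An `lda_model`.
#' @param x Feature table of the records to classify.
#' @param defective Logical flag per record.
#' @return Data frame with one row per group (`defective`, `n`,
#'   `mean_distance`, `se`); `se = sd/sqrt(n)`, `NA` when `n < 2`.
#' @export
mahalanobis_summary <- function(model, x, defective) {
  xm <- feature_matrix(x)
  stopifnot(length(defective) == nrow(xm))
  nd <- classify(model, xm)$nearest_distance
  out <- lapply(c(FALSE, TRUE), function(flag) {
    v <- nd[defective == flag]
    if (!length(v)) return(NULL)
    data.frame(defective = flag, n = length(v), mean_distance = mean(v),
               se = if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_)
  })
  do.call(rbind, out)
}
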