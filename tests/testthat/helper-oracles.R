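# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately naive (per-pixel scans, textbook formulas) and never call the
# package's own fast paths.

channels <- c("violet", "blue", "green", "orange", "red", "nir")

# -- synthetic shapes ---------------------------------------------------------

ellipse_mask <- function(a, b, pad = 4L) {
  n <- 2L * as.integer(ceiling(max(a, b))) + 2L * pad
  cx <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  ((xs - cx) / a)^2 + ((ys - cx) / b)^2 <= 1
}

disk_mask <- function(r, pad = 4L) ellipse_mask(r, r, pad)

square_mask <- function(s, pad = 4L) {
  n <- s + 2L * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(s), pad + seq_len(s)] <- TRUE
  m
}

# a stack whose mask is given and whose height/intensity are prescribed
make_stack <- function(height, intensity = NULL) {
  if (is.null(intensity)) {
    intensity <- lapply(seq_len(6), function(i) height)
  }
  names(intensity) <- channels
  peagrade:::new_image_stack(intensity, height)
}

# paraboloid dome stack: peak H over an axis-aligned ellipse (a, b),
# intensity per channel = refl * height (noise free)
dome_stack <- function(a, b, peak, refl = rep(1, 6), n = 96L) {
  cx <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  h <- peak * pmax(1 - ((xs - cx) / a)^2 - ((ys - cx) / b)^2, 0)
  make_stack(h, lapply(refl, function(r) r * h))
}

# -- brute-force oracles ------------------------------------------------------

# per-pixel scan: count of mask pixels with >=1 background neighbour
border_count_oracle <- function(m, conn = 8) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- if (conn == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    for (d in offs) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc || !m[ni, nj]) {
        cnt <- cnt + 1L
        break
      }
    }
  }
  cnt
}

# textbook one-way ANOVA F for one feature
anova_f_oracle <- function(values, groups) {
  summary(stats::aov(values ~ factor(groups)))[[1]][["F value"]][1]
}

# Mahalanobis distance via stats::mahalanobis (never the package's matrix path)
mahal_oracle <- function(x, center, cov) {
  sqrt(stats::mahalanobis(x, center, cov))
}

# -- small fixture datasets ---------------------------------------------------

tiny_counts <- function(cal_n = 3L, cal_d = 1L, val_n = 2L, val_d = 1L,
                        grades = peagrade::grade_names()) {
  rbind(
    data.frame(grade = grades, split = "calibration",
               n_samples = cal_n, n_defective = cal_d),
    data.frame(grade = grades, split = "validation",
               n_samples = val_n, n_defective = val_d)
  )
}

tiny_design <- function(rng_seed = 42L, seeds = 3L, ...) {
  peagrade::dataset_design(counts = tiny_counts(...), seeds_per_sample = seeds,
                           image_dim = c(80L, 80L), rng_seed = rng_seed)
}

# Gaussian class data for discriminant tests
gauss_classes <- function(n, means, sd = 1, seed = 1) {
  set.seed(seed)
  p <- length(means[[1]])
  x <- do.call(rbind, lapply(seq_along(means), function(k) {
    matrix(rnorm(n * p, rep(means[[k]], each = n), sd), n, p)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = as.data.frame(x),
       g = rep(paste0("class", seq_along(means)), each = n))
}
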