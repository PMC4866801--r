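# Synthetic seed-image generator. Stands in for instrument imagery: one seed
# per stack, six colour channels proportional to reflectance x surface height
# (so the height-corrected colour factors recover reflectance), plus the
# height map itself.

#' Construct a market-grade specification for the synthetic generator
#'
#' A grade spec states the per-channel reflectance of the seed coat and the
#' size/shape/height distribution of seeds of that grade. Channel order is
#' violet, blue, green, orange, red, NIR.
#'
#' @param grade_name Grade label (any string; the eight standard grades are in
#'   [grade_names()]).
#' @param reflectance Numeric length-6, strictly positive; dimensionless
#'   per-channel reflectance coefficients. The colour factor of a rendered
#'   seed converges to this vector as noise goes to 0.
#' @param semi_axes Numeric length-2 `(a, b)`: mean footprint semi-axes in
#'   pixels.
#' @param axis_sd Standard deviation of each semi-axis (pixels); must be
#'   non-negative and smaller than both axis means.
#' @param height_mean,height_sd Mean and sd of the dome peak height (height
#'   units; the segmentation threshold scale is 20 units).
#' @param shape_noise Boundary irregularity amplitude (pixels).
#' @param speckle_density Expected fraction of the coat covered by natural
#'   dark speckles (0 disables speckling).
#' @param speckle_darkness Fractional intensity reduction inside speckles.
#' @return A `grade_spec` object.
#' @export
grade_spec <- function(grade_name, reflectance, semi_axes, axis_sd,
                       height_mean, height_sd, shape_noise = 0.5,
                       speckle_density = 0, speckle_darkness = 0) {
  stopifnot(is.character(grade_name), length(grade_name) == 1L)
  reflectance <- as.numeric(reflectance)
  if (length(reflectance) != 6L || any(!is.finite(reflectance)) ||
      any(reflectance <= 0)) {
    stop("reflectance must be 6 strictly positive finite values")
  }
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 2L, all(semi_axes > 0))
  if (axis_sd < 0 || axis_sd >= min(semi_axes)) {
    stop("axis_sd must be non-negative and smaller than the axis means")
  }
  if (height_sd < 0 || height_sd >= height_mean) {
    stop("height_sd must be non-negative and smaller than height_mean")
  }
  stopifnot(shape_noise >= 0, speckle_density >= 0, speckle_density < 1,
            speckle_darkness >= 0, speckle_darkness < 1)
  structure(
    list(grade_name = grade_name,
         reflectance = stats::setNames(reflectance, CHANNELS),
         semi_axes = semi_axes, axis_sd = axis_sd,
         height_mean = height_mean, height_sd = height_sd,
         shape_noise = shape_noise,
         speckle_density = speckle_density,
         speckle_darkness = speckle_darkness),
    class = "grade_spec"
  )
}

#' Default specifications for the eight field-pea market grades
#'
#' Reflectance vectors are chosen so that every pair of grades is separated,
#' on at least one of the blue/green/orange/red channels, by much more than
#' the within-grade spread the generator induces at its default noise levels;
#' NIR varies little between grades. Marrowfat is distinctly larger than the
#' other grades and Yellow Forage smaller; Mottled Dun and Kaspa type coats
#' carry natural dark speckling.
#'
#' @return Named list of 8 [grade_spec()] objects, one per grade in
#'   [grade_names()] order.
#' @export
default_grade_specs <- function() {
  s <- list(
    grade_spec("White",         c(0.55, 0.80, 0.85, 0.88, 0.90, 0.95),
               c(22, 20.0), 1.2, 180, 12, 0.5),
    grade_spec("Blue",          c(0.50, 0.75, 0.70, 0.55, 0.50, 0.90),
               c(21, 19.0), 1.2, 175, 12, 0.5),
    grade_spec("Mottled Dun",   c(0.30, 0.45, 0.55, 0.60, 0.62, 0.85),
               c(20, 18.0), 1.2, 170, 12, 0.5, 0.12, 0.55),
    grade_spec("Kaspa Dun",     c(0.32, 0.48, 0.58, 0.66, 0.70, 0.88),
               c(19, 17.5), 1.1, 165, 11, 0.5),
    grade_spec("Green Dun",     c(0.35, 0.55, 0.70, 0.60, 0.55, 0.86),
               c(20, 18.5), 1.2, 170, 12, 0.5),
    grade_spec("Yellow Forage", c(0.28, 0.42, 0.68, 0.80, 0.82, 0.92),
               c(16, 14.0), 1.0, 140, 10, 1.0),
    grade_spec("Marrowfat",     c(0.40, 0.60, 0.78, 0.62, 0.52, 0.88),
               c(28, 25.0), 1.4, 220, 14, 1.5),
    grade_spec("Kaspa type",    c(0.33, 0.50, 0.62, 0.72, 0.66, 0.87),
               c(19, 17.0), 1.1, 165, 11, 0.5, 0.05, 0.45)
  )
  stats::setNames(s, vapply(s, `[[`, "", "grade_name"))
}

DEFECT_KINDS <- c("none", "disease_stain", "exposed_cotyledon",
                  "shrivel", "insect")

# spectral signatures of the defect overlays (violet..NIR)
STAIN_TRANSMIT <- c(0.40, 0.45, 0.50, 0.55, 0.60, 0.85)
COTYLEDON_REFL <- c(0.20, 0.35, 0.62, 0.78, 0.80, 0.90)
SHRIVEL_DULL   <- c(0.35, 0.30, 0.22, 0.18, 0.15, 0.05)
INSECT_DULL    <- c(0.30, 0.25, 0.18, 0.14, 0.12, 0.04)

#' Construct a defect profile for a rendered seed
#'
#' @param kind One of `"none"`, `"disease_stain"`, `"exposed_cotyledon"`,
#'   `"shrivel"`, `"insect"`.
#' @param severity Fraction in `[0, 1]`; `kind = "none"` forces 0. Severity
#'   scales patch coverage (stain/cotyledon), height loss (shrivel) and pit
#'   count (insect).
#' @return A `defect_profile` object.
#' @export
defect_profile <- function(kind = "none", severity = 0) {
  kind <- match.arg(kind, DEFECT_KINDS)
  stopifnot(is.numeric(severity), length(severity) == 1L,
            severity >= 0, severity <= 1)
  if (kind == "none") severity <- 0
  structure(list(kind = kind, severity = severity), class = "defect_profile")
}

#' Calibration/validation dataset design
#'
#' The default `counts` table reproduces the standard design: 175 calibration
#' samples (39 defective) and 142 validation samples (39 defective) across
#' the eight market grades.
#'
#' @param counts Data frame with columns `grade`, `split`
#'   (`"calibration"`/`"validation"`), `n_samples`, `n_defective`.
#' @param seeds_per_sample Seeds imaged per sample (>= 1).
#' @param image_dim Integer length-2 `(rows, cols)` of every image.
#' @param rng_seed Integer master seed; all randomness derives from it.
#' @param noise_sd Log-sd of the multiplicative intensity noise.
#' @param severity_range Length-2 range from which the severity of each
#'   defective seed's defect is drawn.
#' @return A `dataset_design` object.
#' @export
dataset_design <- function(counts = default_design_counts(),
                           seeds_per_sample = 30L,
                           image_dim = c(96L, 96L),
                           rng_seed = 1L,
                           noise_sd = 0.05,
                           severity_range = c(0.3, 0.8)) {
  counts <- as.data.frame(counts)
  need <- c("grade", "split", "n_samples", "n_defective")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns: ", paste(need, collapse = ", "))
  }
  if (any(counts$n_defective > counts$n_samples)) {
    stop("n_defective exceeds n_samples in at least one design cell")
  }
  if (any(counts$n_samples < 0) || any(counts$n_defective < 0)) {
    stop("design counts must be non-negative")
  }
  stopifnot(seeds_per_sample >= 1, length(image_dim) == 2L,
            all(image_dim >= 8), noise_sd >= 0,
            length(severity_range) == 2L, severity_range[1] <= severity_range[2],
            severity_range[1] >= 0, severity_range[2] <= 1)
  structure(
    list(counts = counts,
         seeds_per_sample = as.integer(seeds_per_sample),
         image_dim = as.integer(image_dim),
         rng_seed = as.integer(rng_seed),
         noise_sd = noise_sd,
         severity_range = severity_range),
    class = "dataset_design"
  )
}

#' Default per-grade sample counts (calibration and validation)
#'
#' @return Data frame with one row per (grade, split) cell; totals are 175
#'   calibration samples (39 defective) and 142 validation samples (39
#'   defective).
#' @export
default_design_counts <- function() {
  cal_n <- c(50, 31, 7, 13, 16, 5, 6, 47)
  cal_d <- c(4, 0, 4, 7, 0, 5, 0, 19)
  val_n <- c(45, 44, 5, 8, 5, 6, 2, 27)
  val_d <- c(4, 0, 4, 6, 1, 6, 0, 18)
  rbind(
    data.frame(grade = GRADE_NAMES, split = "calibration",
               n_samples = cal_n, n_defective = cal_d,
               stringsAsFactors = FALSE),
    data.frame(grade = GRADE_NAMES, split = "validation",
               n_samples = val_n, n_defective = val_d,
               stringsAsFactors = FALSE)
  )
}

# deterministic 31-bit sub-seed from (master seed, sample idx, seed idx)
derive_seed <- function(base, i, j = 0L) {
  b <- as.double(base %% 100000L)
  as.integer((b * 20011 + i * 1009 + j + 11) %% 2147483629)
}

new_image_stack <- function(intensity, height) {
  structure(list(intensity = intensity, height = height),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack %dx%d px, 6 colour channels + height; peak %.1f>\n",
              nrow(x$height), ncol(x$height), max(x$height)))
  invisible(x)
}

# circular patches over the footprint until target coverage is reached;
# returns a logical matrix
sample_patches <- function(footprint, coverage, r_range, max_patches = 80L) {
  idx <- which(footprint)
  n_fp <- length(idx)
  patch <- matrix(FALSE, nrow(footprint), ncol(footprint))
  if (coverage <= 0 || n_fp == 0L) return(patch)
  nr <- nrow(footprint)
  rows <- matrix(seq_len(nr), nr, ncol(footprint))
  cols <- matrix(seq_len(ncol(footprint)), nr, ncol(footprint), byrow = TRUE)
  for (k in seq_len(max_patches)) {
    ctr <- idx[ceiling(runif(1) * n_fp)]
    ci <- ((ctr - 1L) %% nr) + 1L
    cj <- ((ctr - 1L) %/% nr) + 1L
    r <- runif(1, r_range[1], r_range[2])
    patch <- patch | ((rows - ci)^2 + (cols - cj)^2 <= r^2)
    if (sum(patch & footprint) >= coverage * n_fp) break
  }
  patch & footprint
}

#' Render one seed as a synthetic image stack
#'
#' The seed is an elliptical paraboloid height dome with a low-frequency
#' irregular boundary; each colour channel is
#' `reflectance * height * exp(noise)`, so the height-corrected colour factor
#' of the downstream feature pipeline recovers the spec's reflectance vector.
#' Defects overlay the stack: disease stains darken intensity patches
#' (strongest at short wavelengths), exposed cotyledon replaces patch
#' reflectance with a yellow-shifted coat-free value, shrivelling scales the
#' height field by `1 - severity` (dimples are carved only below the median
#' height, so the median height scales exactly) and dulls the coat slightly,
#' and insect damage adds dark pits. All randomness is a pure function of
#' `rng_seed`.
#'
#' @param spec A [grade_spec()].
#' @param defect A [defect_profile()].
#' @param rng_seed Integer seed.
#' @param dim Image dimensions `(rows, cols)`, both positive.
#' @param noise_sd Log-sd of multiplicative lognormal intensity noise.
#' @return An `image_stack`: `$intensity` (named list of 6 matrices, channel
#'   order violet..NIR) and `$height` (matrix, 0 on background).
#' @export
render_seed <- function(spec, defect = defect_profile("none"), rng_seed = 1L,
                        dim = c(96L, 96L), noise_sd = 0.05) {
  stopifnot(inherits(spec, "grade_spec"), inherits(defect, "defect_profile"))
  if (length(dim) != 2L || any(dim <= 0)) {
    stop("image dimensions must be positive")
  }
  nr <- as.integer(dim[1]); nc <- as.integer(dim[2])
  set.seed(as.integer(rng_seed))

  # geometry draws (fixed order so geometry is identical across defect kinds)
  a <- max(4, rnorm(1, spec$semi_axes[1], spec$axis_sd))
  b <- max(4, rnorm(1, spec$semi_axes[2], spec$axis_sd))
  theta <- runif(1, 0, pi)
  peak <- max(30, rnorm(1, spec$height_mean, spec$height_sd))
  ck <- rnorm(3, 0, spec$shape_noise / (2:4))
  psi <- runif(3, 0, 2 * pi)

  x <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  y <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  u <- sqrt((xr / a)^2 + (yr / b)^2)
  phi <- atan2(yr / b, xr / a)
  g <- 1 + (ck[1] * cos(2 * phi + psi[1]) + ck[2] * cos(3 * phi + psi[2]) +
              ck[3] * cos(4 * phi + psi[3])) / mean(c(a, b))
  g <- pmax(g, 0.5)
  height <- peak * pmax(1 - (u / g)^2, 0)
  footprint <- height > 0

  # per-seed coat reflectance jitter (scales with the noise knob, so factors
  # converge to the spec reflectance exactly as noise_sd -> 0)
  refl <- spec$reflectance * exp(rnorm(6, 0, 0.6 * noise_sd))

  # per-channel multiplicative coat map (speckle, defect colour effects)
  coat <- rep(list(matrix(1, nr, nc)), 6)
  if (spec$speckle_density > 0) {
    spots <- sample_patches(footprint, spec$speckle_density, c(1.2, 2.5),
                            max_patches = 200L)
    for (c in 1:6) coat[[c]][spots] <- 1 - spec$speckle_darkness
  }

  sev <- defect$severity
  if (defect$kind == "disease_stain" && sev > 0) {
    stain <- sample_patches(footprint, 0.25 + 0.55 * sev, c(3, 7))
    for (c in 1:6) coat[[c]][stain] <- coat[[c]][stain] * STAIN_TRANSMIT[c]
  } else if (defect$kind == "exposed_cotyledon" && sev > 0) {
    patch <- sample_patches(footprint, 0.15 + 0.45 * sev, c(2, 5))
    for (c in 1:6) coat[[c]][patch] <- COTYLEDON_REFL[c] / refl[c]
  } else if (defect$kind == "shrivel" && sev > 0) {
    height <- height * (1 - sev)
    # dimples only strictly below the median footprint height: the global
    # scaling is then the only effect the median height sees
    med <- median(height[footprint])
    dimple <- sample_patches(footprint, 0.25, c(2, 4)) & (height < med)
    height[dimple] <- height[dimple] * 0.5
    for (c in 1:6) coat[[c]] <- coat[[c]] * (1 - SHRIVEL_DULL[c] * sev)
  } else if (defect$kind == "insect" && sev > 0) {
    pits <- sample_patches(footprint, 0.03 + 0.07 * sev, c(1, 2.5))
    height[pits] <- height[pits] * 0.4
    for (c in 1:6) {
      coat[[c]][pits] <- coat[[c]][pits] * 0.3
      coat[[c]] <- coat[[c]] * (1 - INSECT_DULL[c] * sev)
    }
  }

  intensity <- vector("list", 6)
  for (c in 1:6) {
    noise <- matrix(exp(rnorm(nr * nc, 0, noise_sd)), nr, nc)
    intensity[[c]] <- refl[c] * height * coat[[c]] * noise
  }
  names(intensity) <- CHANNELS
  new_image_stack(intensity, height)
}

# draw defect kinds/severities for the seeds of one sample; returns a list of
# defect_profile, length n_seeds (RNG state of the caller is used)
draw_sample_defects <- function(n_seeds, defective,
                                severity_range = c(0.3, 0.8)) {
  kinds <- DEFECT_KINDS[-1]
  weights <- c(0.5, 0.15, 0.2, 0.15)  # disease staining most prevalent
  profiles <- rep(list(defect_profile("none")), n_seeds)
  if (defective) {
    frac <- runif(1, 0.75, 1.0)
    n_def <- min(n_seeds, ceiling(frac * n_seeds))
  } else {
    cap <- ceiling(0.05 * n_seeds) - 1L  # strictly below 5% of seeds
    n_def <- min(rbinom(1, n_seeds, 0.01), max(cap, 0L))
  }
  if (n_def > 0) {
    pos <- sample.int(n_seeds, n_def)
    for (p in pos) {
      k <- sample(kinds, 1, prob = weights)
      s <- if (defective) runif(1, severity_range[1], severity_range[2]) else
        runif(1, 0.05, 0.2)
      profiles[[p]] <- defect_profile(k, s)
    }
  }
  profiles
}

#' Generate a labelled seed-image dataset from a design
#'
#' Each sample carries a grade, a split tag, a defective flag and
#' `seeds_per_sample` rendered seeds. Defective samples have at least 75% of
#' their seeds rendered with a defect; non-defective samples fewer than 5%.
#' The whole dataset is a pure function of `design$rng_seed`: per-seed render
#' seeds are derived deterministically, so two calls with the same design are
#' bit-for-bit identical.
#'
#' @param design A [dataset_design()].
#' @param specs Named list of [grade_spec()] covering every grade in the
#'   design.
#' @param keep_stacks Keep rendered pixel arrays in the returned object?
#'   With the full default design this needs several GB; use `FALSE` (the
#'   default of [run_experiment()]) to keep only the per-seed render plan,
#'   from which [render_sample()] reproduces any sample's stacks on demand.
#' @return A `pea_dataset`: list with `$samples` (each sample a list with
#'   `sample_id`, `grade`, `split`, `defective`, `plan`, and `stacks` if
#'   kept), `$design`, `$specs`.
#' @export
generate_dataset <- function(design, specs = default_grade_specs(),
                             keep_stacks = TRUE) {
  stopifnot(inherits(design, "dataset_design"))
  missing_g <- setdiff(design$counts$grade, names(specs))
  if (length(missing_g)) {
    stop("no grade_spec for: ", paste(missing_g, collapse = ", "))
  }
  samples <- list()
  s_idx <- 0L
  for (r in seq_len(nrow(design$counts))) {
    row <- design$counts[r, ]
    if (row$n_samples == 0L) next
    for (k in seq_len(row$n_samples)) {
      s_idx <- s_idx + 1L
      defective <- k <= row$n_defective
      set.seed(derive_seed(design$rng_seed, s_idx, 0L))
      profiles <- draw_sample_defects(design$seeds_per_sample, defective,
                                      design$severity_range)
      plan <- lapply(seq_len(design$seeds_per_sample), function(j) {
        list(grade = row$grade, defect = profiles[[j]],
             rng_seed = derive_seed(design$rng_seed, s_idx, j))
      })
      sample_id <- sprintf("%s_%s_%03d",
                           substr(row$split, 1, 3),
                           gsub(" ", "", row$grade), k)
      samples[[s_idx]] <- list(sample_id = sample_id, grade = row$grade,
                               split = row$split, defective = defective,
                               plan = plan, stacks = NULL)
    }
  }
  ds <- structure(list(samples = samples, design = design, specs = specs),
                  class = "pea_dataset")
  if (keep_stacks) {
    for (i in seq_along(ds$samples)) {
      ds$samples[[i]]$stacks <- render_sample(ds, i)
    }
  }
  ds
}

#' Render (or re-render) the image stacks of one dataset sample
#'
#' @param dataset A `pea_dataset`.
#' @param i Sample index.
#' @return List of `image_stack`, one per seed.
#' @export
render_sample <- function(dataset, i) {
  s <- dataset$samples[[i]]
  if (!is.null(s$stacks)) return(s$stacks)
  d <- dataset$design
  lapply(s$plan, function(p) {
    render_seed(dataset$specs[[p$grade]], p$defect, p$rng_seed,
                dim = d$image_dim, noise_sd = d$noise_sd)
  })
}

#' @export
print.pea_dataset <- function(x, ...) {
  n <- length(x$samples)
  spl <- vapply(x$samples, `[[`, "", "split")
  def <- vapply(x$samples, `[[`, NA, "defective")
  cat(sprintf(paste0("<pea_dataset: %d samples (%d calibration, %d ",
                     "validation; %d defective), %d seeds/sample>\n"),
              n, sum(spl == "calibration"), sum(spl == "validation"),
              sum(def), x$design$seeds_per_sample))
  invisible(x)
}
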