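# Synthetic seed-image generator.

test_that("default grade specs cover the eight market grades distinctly", {
  specs <- default_grade_specs()
  expect_length(specs, 8L)
  expect_setequal(names(specs), grade_names())
  expect_identical(vapply(specs, `[[`, "", "grade_name"), setNames(nm = names(specs)))

  refl <- t(vapply(specs, `[[`, numeric(6), "reflectance"))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_false(isTRUE(all.equal(refl[i, ], refl[j, ])),
                 info = paste(rownames(refl)[i], "vs", rownames(refl)[j]))
  }

  # White and Marrowfat sizes differ by more than 2 pooled sds
  w <- specs$White; m <- specs$Marrowfat
  pooled_sd <- sqrt((w$axis_sd^2 + m$axis_sd^2) / 2)
  expect_gt(abs(mean(w$semi_axes) - mean(m$semi_axes)), 2 * pooled_sd)
})

test_that("grade-spec and defect-profile validation rejects bad inputs", {
  expect_error(grade_spec("x", c(1, 1, 1, 1, 1), c(10, 9), 1, 100, 5),
               "reflectance")
  expect_error(grade_spec("x", rep(-1, 6), c(10, 9), 1, 100, 5),
               "reflectance")
  expect_error(grade_spec("x", rep(0.5, 6), c(10, 9), 20, 100, 5), "axis_sd")
  expect_error(grade_spec("x", rep(0.5, 6), c(10, 9), 1, 100, 200),
               "height_sd")
  expect_error(defect_profile("disease_stain", 1.5), "severity")
  expect_identical(defect_profile("none", 1)$severity, 0)
})

test_that("induced colour factors separate every pair of grades on a mid channel", {
  specs <- default_grade_specs()
  mid <- paste0(c("blue", "green", "orange", "red"), "_factor")
  per_grade <- lapply(specs, function(sp) {
    f <- vapply(1:6, function(i) {
      seed_features(render_seed(sp, rng_seed = 1000L + i))[mid]
    }, numeric(4))
    list(mean = rowMeans(f), sd = apply(f, 1, sd))
  })
  for (i in 1:7) for (j in (i + 1):8) {
    a <- per_grade[[i]]; b <- per_grade[[j]]
    sep <- abs(a$mean - b$mean) > pmax(a$sd, b$sd)
    expect_true(any(sep),
                info = paste(names(specs)[i], "vs", names(specs)[j]))
  }
})

test_that("render_seed is deterministic in rng_seed and validates dimensions", {
  spec <- default_grade_specs()$Blue
  s1 <- render_seed(spec, rng_seed = 5L)
  s2 <- render_seed(spec, rng_seed = 5L)
  expect_identical(s1, s2)
  s3 <- render_seed(spec, rng_seed = 6L)
  expect_false(identical(s1$height, s3$height))
  expect_error(render_seed(spec, dim = c(0, 96)), "positive")

  # stack invariants: shapes equal, background 0, finite non-negative
  expect_true(all(vapply(s1$intensity, function(m) all(dim(m) == dim(s1$height)), NA)))
  expect_true(all(s1$height >= 0), all(is.finite(s1$height)))
  expect_true(all(vapply(s1$intensity, function(m) all(is.finite(m)) && all(m >= 0), NA)))
  expect_identical(s1$intensity$violet[s1$height == 0],
                   rep(0, sum(s1$height == 0)))
})

test_that("shrivel scales the median height exactly by 1 - severity", {
  spec <- default_grade_specs()$White
  for (seed in c(3L, 11L, 27L)) {
    clean <- render_seed(spec, rng_seed = seed)
    shriv <- render_seed(spec, defect_profile("shrivel", 0.5), rng_seed = seed)
    expect_identical(median(shriv$height[shriv$height > 0]),
                     0.5 * median(clean$height[clean$height > 0]))
  }
})

test_that("disease staining strictly lowers the green colour factor", {
  spec <- default_grade_specs()$`Kaspa Dun`
  for (seed in c(2L, 9L)) {
    clean <- seed_features(render_seed(spec, rng_seed = seed))
    stained <- seed_features(render_seed(
      spec, defect_profile("disease_stain", 0.6), rng_seed = seed))
    expect_lt(stained[["green_factor"]], clean[["green_factor"]])
    # stains absorb short wavelengths hardest
    expect_lt(stained[["violet_factor"]] / clean[["violet_factor"]],
              stained[["nir_factor"]] / clean[["nir_factor"]])
  }
})

test_that("colour factors converge to the spec reflectance as noise -> 0", {
  specs <- default_grade_specs()
  for (g in c("White", "Green Dun", "Marrowfat")) {
    sp <- specs[[g]]
    f <- seed_features(render_seed(sp, rng_seed = 4L, noise_sd = 1e-4))
    got <- f[paste0(channels, "_factor")]
    expect_equal(unname(got), unname(sp$reflectance), tolerance = 2e-3)
  }
  # moderate noise still recovers reflectance within a few percent
  sp <- specs$Blue
  f <- seed_features(render_seed(sp, rng_seed = 8L, noise_sd = 0.05))
  expect_equal(unname(f[paste0(channels, "_factor")]),
               unname(sp$reflectance), tolerance = 0.08)
})

test_that("generate_dataset honours the design cells and defect rules", {
  design <- tiny_design(rng_seed = 7L, seeds = 4L)
  ds <- generate_dataset(design, keep_stacks = FALSE)
  expect_s3_class(ds, "pea_dataset")
  expect_length(ds$samples, sum(design$counts$n_samples))

  meta <- data.frame(
    grade = vapply(ds$samples, `[[`, "", "grade"),
    split = vapply(ds$samples, `[[`, "", "split"),
    defective = vapply(ds$samples, `[[`, NA, "defective")
  )
  for (r in seq_len(nrow(design$counts))) {
    row <- design$counts[r, ]
    sel <- meta$grade == row$grade & meta$split == row$split
    expect_identical(sum(sel), as.integer(row$n_samples))
    expect_identical(sum(meta$defective[sel]), as.integer(row$n_defective))
  }

  # defective samples: >= 75% of seeds defective; non-defective: < 5%
  for (s in ds$samples) {
    n_def <- sum(vapply(s$plan, function(p) p$defect$kind != "none", NA))
    frac <- n_def / length(s$plan)
    if (s$defective) expect_gte(frac, 0.75) else expect_lt(frac, 0.05)
  }
})

test_that("generate_dataset is bit-for-bit deterministic", {
  counts <- tiny_counts(cal_n = 1L, cal_d = 1L, val_n = 1L, val_d = 0L,
                        grades = c("White", "Kaspa type"))
  design <- dataset_design(counts, seeds_per_sample = 2L,
                           image_dim = c(64L, 64L), rng_seed = 99L)
  d1 <- generate_dataset(design)
  d2 <- generate_dataset(design)
  expect_identical(d1, d2)
  # and materialised stacks match the on-demand render path
  d3 <- generate_dataset(design, keep_stacks = FALSE)
  expect_identical(d1$samples[[1]]$stacks, render_sample(d3, 1))
})

test_that("all-zero defect designs render every seed clean", {
  counts <- tiny_counts(cal_n = 2L, cal_d = 0L, val_n = 1L, val_d = 0L,
                        grades = c("Blue", "Marrowfat"))
  design <- dataset_design(counts, seeds_per_sample = 20L,
                           image_dim = c(64L, 64L), rng_seed = 3L)
  ds <- generate_dataset(design, keep_stacks = FALSE)
  kinds <- unlist(lapply(ds$samples, function(s) {
    vapply(s$plan, function(p) p$defect$kind, "")
  }))
  expect_true(all(kinds == "none"))
})

test_that("designs with defective > total are rejected", {
  counts <- tiny_counts(cal_n = 2L, cal_d = 3L, grades = "White")
  expect_error(dataset_design(counts), "n_defective")
})
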