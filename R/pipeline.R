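# Orchestration of the three standard models:
#   model1 - market grade from the four mid-wavelength colour factors,
#            trained on non-defective calibration samples (7 grades; Yellow
#            Forage omitted because all its samples are defective);
#   model2 - market grade from eight colour/size/shape features, trained on
#            the full calibration set (8 grades);
#   defect - defective vs non-defective from the model-2 features, trained on
#            the full calibration set.

MODEL1_FEATURES <- c("blue_factor", "green_factor", "orange_factor",
                     "red_factor")
MODEL2_FEATURES <- c(MODEL1_FEATURES, "violet_factor", "equivalent_diameter",
                     "circularity", "plumpness")

#' Configuration of one of the three standard models
#'
#' @param model_id `"model1"`, `"model2"` or `"defect"`.
#' @return A `model_config`: `model_id`, `features`, `classes`, `target`
#'   (`"grade"` or `"defective"`), `train` rule (`"nondefective_calibration"`
#'   or `"full_calibration"`).
#' @export
model_config <- function(model_id = c("model1", "model2", "defect")) {
  model_id <- match.arg(model_id)
  cfg <- switch(model_id,
    model1 = list(features = MODEL1_FEATURES,
                  classes = setdiff(GRADE_NAMES, "Yellow Forage"),
                  target = "grade", train = "nondefective_calibration"),
    model2 = list(features = MODEL2_FEATURES, classes = GRADE_NAMES,
                  target = "grade", train = "full_calibration"),
    defect = list(features = MODEL2_FEATURES,
                  classes = c("defective", "non-defective"),
                  target = "defective", train = "full_calibration")
  )
  structure(c(list(model_id = model_id), cfg), class = "model_config")
}

target_labels <- function(config, records) {
  if (config$target == "grade") as.character(records$grade)
  else ifelse(records$defective, "defective", "non-defective")
}

#' Fit and evaluate one standard model on a standardised feature table
#'
#' Fits the configured LDA on its training subset and scores the four
#' evaluation cells: non-defective/defective x calibration/validation.
#' Model 1 is never assessed on defective calibration samples (reported
#' `NA`), and its defective-validation accuracy excludes Yellow Forage
#' samples, which have no class in that model.
#'
#' @param config A [model_config()] (or a model id string).
#' @param records Standardised feature table with `sample_id`, `grade`,
#'   `split`, `defective` and the feature columns.
#' @param priors Passed to [fit_lda()].
#' @return A `model_report`: `config`, fitted `model`, `predictions` (with
#'   truth, predicted label, per-class distance and evaluation cell),
#'   `accuracy` (4-vector of percentages, NA where unassessed), `confusion`
#'   (per-split tables).
#' @export
run_model <- function(config, records, priors = "equal") {
  if (is.character(config)) config <- model_config(config)
  stopifnot(inherits(config, "model_config"))
  need <- c("sample_id", "grade", "split", "defective", config$features)
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  }
  truth <- target_labels(config, records)
  train_idx <- records$split == "calibration"
  if (config$train == "nondefective_calibration") {
    train_idx <- train_idx & !records$defective
  }
  # records whose label has no class in this model (e.g. Yellow Forage under
  # model 1) cannot be used for training
  train_idx <- train_idx & truth %in% config$classes
  absent <- setdiff(config$classes, truth[train_idx])
  if (length(absent)) {
    stop("training subset lacks class(es): ", paste(absent, collapse = ", "))
  }
  model <- fit_lda(records[train_idx, , drop = FALSE],
                   factor(truth[train_idx], levels = config$classes),
                   features = config$features, priors = priors)
  pred <- classify(model, records)
  pred <- cbind(records[, c("sample_id", "grade", "split", "defective")],
                truth = truth, pred)

  scored <- rep(TRUE, nrow(records))
  if (config$model_id == "model1") {
    scored <- records$grade != "Yellow Forage"  # grade absent from the model
  }
  cell <- function(split, defective) {
    sel <- records$split == split & records$defective == defective & scored
    if (config$model_id == "model1" && split == "calibration" && defective) {
      return(NA_real_)  # model 1 is not assessed on defective calibration
    }
    if (!any(sel)) return(NA_real_)
    100 * mean(pred$predicted[sel] == truth[sel])
  }
  accuracy <- c(nondefective_calibration = cell("calibration", FALSE),
                defective_calibration = cell("calibration", TRUE),
                nondefective_validation = cell("validation", FALSE),
                defective_validation = cell("validation", TRUE))
  confusion <- lapply(c(calibration = "calibration",
                        validation = "validation"), function(sp) {
    sel <- records$split == sp & scored
    table(truth = factor(truth[sel], levels = config$classes),
          predicted = factor(pred$predicted[sel], levels = config$classes))
  })
  structure(list(config = config, model = model, predictions = pred,
                 accuracy = accuracy, confusion = confusion),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report %s: %s>\n", x$config$model_id,
              paste(sprintf("%s=%s", names(x$accuracy),
                            ifelse(is.na(x$accuracy), "NA",
                                   sprintf("%.0f%%", x$accuracy))),
                    collapse = " ")))
  invisible(x)
}

#' Tabulate model accuracies in the standard four-column layout
#'
#' One row per model; columns are percent accuracy on non-defective
#' calibration, defective calibration, non-defective validation and
#' defective validation samples, rounded to the nearest integer percent,
#' `NA` where a cell is not assessed.
#'
#' @param reports List of `model_report` objects (or a single one).
#' @return Data frame with a `model` column and the four accuracy columns.
#' @export
accuracy_table <- function(reports) {
  if (inherits(reports, "model_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  rows <- lapply(reports, function(r) {
    data.frame(model = r$config$model_id, t(round(r$accuracy)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-imagery experiment
#'
#' Generates the dataset from the design (streaming: per-sample pixel data is
#' discarded after feature extraction), extracts the 13-feature table,
#' standardises against the full calibration split, and fits/evaluates the
#' requested models.
#'
#' @param design A [dataset_design()].
#' @param specs Grade specs (default [default_grade_specs()]).
#' @param models Character subset of `c("model1", "model2", "defect")`.
#' @param threshold Height threshold for M2.
#' @param verbose Print per-stage progress?
#' @return A `pea_experiment`: `features` (raw), `records` (standardised),
#'   `standardiser`, `reports` (named list of `model_report`), `table`
#'   (accuracy table).
#' @export
run_experiment <- function(design = dataset_design(),
                           specs = default_grade_specs(),
                           models = c("model1", "model2", "defect"),
                           threshold = 20, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating dataset plan (%d samples)", sum(design$counts$n_samples))
  ds <- generate_dataset(design, specs, keep_stacks = FALSE)
  say("rendering seeds and extracting features")
  features <- extract_features(ds, threshold = threshold)
  std <- fit_standardiser(features[features$split == "calibration", ])
  records <- apply_standardiser(std, features)
  reports <- lapply(stats::setNames(models, models), function(m) {
    say("fitting %s", m)
    run_model(model_config(m), records)
  })
  structure(list(features = features, records = records, standardiser = std,
                 reports = reports, table = accuracy_table(reports)),
            class = "pea_experiment")
}

#' @export
print.pea_experiment <- function(x, ...) {
  cat("Classification rates (% correct):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
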