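#' Match a candidate against truth masks
#'
#' A candidate inherits the label of the truth object it overlaps most,
#' provided the overlap covers at least `min_frac` of the union of the two
#' masks (a Jaccard criterion); otherwise it is a "non-nodule" detection
#' artifact.
#'
#' @param cand a `nodule_candidate`.
#' @param truth_masks list of logical matrices.
#' @param truth_labels labels parallel to the masks.
#' @param min_frac minimum Jaccard overlap to accept a match.
#' @return a label string.
#' @export
candidate_truth_label <- function(cand, truth_masks, truth_labels, min_frac = 0.3) {
  if (!length(truth_masks)) return("non-nodule")
  j <- vapply(truth_masks, function(m) {
    inter <- sum(m & cand$region_mask)
    if (inter == 0) return(0)
    inter / sum(m | cand$region_mask)
  }, numeric(1))
  if (max(j) >= min_frac) truth_labels[which.max(j)] else "non-nodule"
}

#' Build a labelled candidate-level dataset from phantom slices
#'
#' Runs the front half of the pipeline (phantom, denoise, segment, candidate
#' extraction, featurization) over `n_slices` phantoms and labels every
#' candidate against the truth masks. Nodule-matching candidates keep their
#' benign/malignant label; everything else is non-nodule.
#'
#' @param n_slices number of slices to generate.
#' @param seed base seed; slice i uses seed + i - 1.
#' @param spec_args arguments forwarded to [phantom_spec()] (seed is managed
#'   here).
#' @param denoise_cfg [denoise_config()] or NULL to skip denoising.
#' @param seg_cfg a [segment_config()].
#' @param feat_cfg a [feature_config()].
#' @param min_area candidate minimum area.
#' @return list: `X` feature matrix, `y3` three-class factor
#'   (benign/malignant/non-nodule), `y` binary factor (nodule/non-nodule),
#'   `descriptors` data frame, `slice` integer slice index per candidate.
#' @export
phantom_candidate_dataset <- function(n_slices = 6, seed = 1, spec_args = list(),
                                      denoise_cfg = denoise_config("catte", iterations = 5),
                                      seg_cfg = segment_config(),
                                      feat_cfg = feature_config(),
                                      min_area = 10) {
  X <- NULL; y3 <- character(0); desc <- NULL; slice <- integer(0)
  for (i in seq_len(n_slices)) {
    sp <- do.call(phantom_spec, c(spec_args, list(seed = seed + i - 1L)))
    ls <- generate_phantom(sp)
    img <- if (is.null(denoise_cfg)) ls$image else denoise(ls$image, denoise_cfg)
    mask <- segment_foreground(img, seg_cfg)
    cands <- label_candidates(mask, img, min_area = min_area)
    if (!length(cands)) next
    Xi <- extract_feature_matrix(cands, img, feat_cfg)
    di <- do.call(rbind, lapply(cands, function(cc) as.data.frame(as.list(cc$descriptors))))
    li <- vapply(cands, candidate_truth_label, character(1),
                 truth_masks = ls$truth_masks, truth_labels = ls$truth_labels)
    X <- rbind(X, Xi); desc <- rbind(desc, di)
    y3 <- c(y3, li); slice <- c(slice, rep(i, length(cands)))
  }
  check_that(!is.null(X) && nrow(X) > 0, "no candidates produced; check the config")
  y3 <- factor(y3, levels = c("benign", "malignant", "non-nodule"))
  y <- factor(ifelse(y3 == "non-nodule", "non-nodule", "nodule"),
              levels = c("non-nodule", "nodule"))
  list(X = X, y3 = droplevels(y3), y = y, descriptors = desc, slice = slice)
}

#' Pipeline configuration
#'
#' Reads a YAML (or JSON) file, or accepts an equivalent named list, and
#' validates the presence and basic sanity of every stage block before any
#' stage runs (fail-fast). Required blocks: `phantom` (or `input`),
#' `denoise`, `segment`, `rules`, `features`, `model`, `eval`; `lda` is
#' optional. A global `seed` and `out_dir` are required.
#'
#' @param x path to a YAML/JSON file, or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else x
  required <- c("phantom", "denoise", "segment", "rules", "features", "model", "eval")
  for (blk in required) {
    check_that(!is.null(cfg[[blk]]) || (blk == "phantom" && !is.null(cfg$input)),
               "pipeline config missing the '%s' block", blk)
  }
  check_that(!is.null(cfg$seed), "pipeline config missing 'seed'")
  check_that(!is.null(cfg$out_dir), "pipeline config missing 'out_dir'")
  check_that(!is.null(cfg$model$kind), "model block must name a 'kind'")
  # validate stage blocks against their module constructors now, not mid-run
  do.call(denoise_config, cfg$denoise)
  do.call(segment_config, cfg$segment)
  do.call(feature_config, cfg$features %||% list())
  if (length(cfg$rules)) do.call(rule_thresholds, lapply(cfg$rules, unlist))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Default pipeline configuration for the phantom benchmark
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @export
default_pipeline_config <- function(out_dir = tempfile("ncrun"), seed = 1) {
  pipeline_config(list(
    seed = seed, out_dir = out_dir, log_level = "info",
    phantom = list(n_train_slices = 6, n_test_slices = 3,
                   width = 128, height = 128, n_nodules = 3, n_vessels = 5,
                   noise_sigma = 0.05),
    denoise = list(method = "catte", iterations = 5, kappa = 0.1, dt = 0.2),
    segment = list(closing_radius = 2),
    rules = list(mean_intensity = c(0.3, NA), circularity = c(0.4, NA),
                 elongation = c(NA, 3.0), rectangularity = c(0.3, NA)),
    features = list(L = 16),
    lda = list(use = FALSE),
    model = list(kind = "hybrid"),
    eval = list(positive = "nodule")))
}

#' Run the end-to-end phantom pipeline
#'
#' Stages: phantom generation (train and test slice sets), denoising,
#' segmentation, candidate extraction, featurization, optional LDA, model
#' fitting, evaluation on the held-out slices. All artifacts are written
#' under `cfg$out_dir` with stable names, and the returned manifest records
#' the config hash, per-stage seeds and artifact paths. Stage seeds are
#' derived as `seed + stage index`, so a rerun with the same config is
#' bit-identical.
#'
#' @param cfg a [pipeline_config()] (or list/path accepted by it).
#' @return the manifest (invisibly written to manifest.json as well).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  seed <- as.integer(cfg$seed)

  ph <- cfg$phantom
  n_tr <- ph$n_train_slices %||% 6
  n_te <- ph$n_test_slices %||% 3
  spec_args <- ph[setdiff(names(ph), c("n_train_slices", "n_test_slices"))]
  dn <- do.call(denoise_config, cfg$denoise)
  sg <- do.call(segment_config, cfg$segment)
  ft <- do.call(feature_config, cfg$features %||% list())
  th <- if (length(cfg$rules)) do.call(rule_thresholds, lapply(cfg$rules, unlist))
        else default_rule_thresholds()

  train <- phantom_candidate_dataset(n_tr, seed + 1L, spec_args, dn, sg, ft)
  test <- phantom_candidate_dataset(n_te, seed + 1L + n_tr, spec_args, dn, sg, ft)

  utils::write.csv(data.frame(train$X, label = train$y3, check.names = FALSE),
                   file.path(out, "features_train.csv"), row.names = FALSE)
  utils::write.csv(data.frame(test$X, label = test$y3, check.names = FALSE),
                   file.path(out, "features_test.csv"), row.names = FALSE)

  spec <- model_spec(cfg$model$kind,
                     use_lda = isTRUE(cfg$lda$use),
                     thresholds = if (cfg$model$kind == "hybrid") th else NULL)
  fitted <- fit_model(spec, train$X, train$y, descriptors = train$descriptors,
                      seed = seed + 10L)
  pred <- predict(fitted, test$X, descriptors = test$descriptors)
  score <- predict(fitted, test$X, type = "score", descriptors = test$descriptors)
  positive <- cfg$eval$positive %||% "nodule"
  metrics <- confusion_metrics(test$y, pred, positive)
  roc <- tryCatch(roc_auc(test$y, score, positive), error = function(e) NULL)
  report <- c(metrics, list(auc = if (is.null(roc)) NA else roc$auc,
                            split = sprintf("%d/%d slices", n_tr, n_te),
                            seed = seed))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) {
    utils::write.csv(roc$roc, file.path(out, "roc.csv"), row.names = FALSE)
  }
  if (fitted$model$kind %in% c("svm", "lr", "hybrid")) {
    model_to_json(fitted, file.path(out, "model.json"))
  }
  preds <- data.frame(slice = test$slice, truth = test$y, pred = pred, score = score)
  utils::write.csv(preds, file.path(out, "predictions.csv"), row.names = FALSE)

  manifest <- list(config_hash = cfg_hash, seed = seed,
                   package_version = as.character(utils::packageVersion("nodulecad")),
                   stage_seeds = list(phantom_train = seed + 1L,
                                      phantom_test = seed + 1L + n_tr,
                                      model = seed + 10L),
                   n_train_candidates = nrow(train$X),
                   n_test_candidates = nrow(test$X),
                   artifacts = list(config = "config.json",
                                    features_train = "features_train.csv",
                                    features_test = "features_test.csv",
                                    predictions = "predictions.csv",
                                    report = "report.json"),
                   report = report)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Build a three-class (benign / malignant / non-nodule) candidate dataset
#'
#' Generates paired slice sets: benign-nodule slices (smooth margins, smaller
#' radii) and malignant-nodule slices (spiculated margins, larger radii),
#' both carrying elongated vessels and compact vessel cross-sections as
#' non-nodule distractors. Mirrors the separability structure of real
#' nodule data: malignant candidates stand apart in shape, while compact
#' non-nodules blend into the benign population.
#'
#' @param seed base seed.
#' @param n_per_kind slices per nodule kind.
#' @return as [phantom_candidate_dataset()], with all three classes present.
#' @export
three_class_dataset <- function(seed = 1, n_per_kind = 2) {
  common <- list(width = 128, height = 128, n_vessels = 2,
                 n_vessel_xsections = 3, noise_sigma = 0.05)
  ben <- phantom_candidate_dataset(n_per_kind, seed,
           spec_args = c(common, list(n_nodules = 3, spiculation = FALSE,
                                      nodule_radius_range = c(4, 8))))
  mal <- phantom_candidate_dataset(n_per_kind, seed + 500L,
           spec_args = c(common, list(n_nodules = 3, spiculation = TRUE,
                                      nodule_radius_range = c(7, 11))))
  list(X = rbind(ben$X, mal$X),
       y3 = factor(c(as.character(ben$y3), as.character(mal$y3)),
                   levels = c("benign", "malignant", "non-nodule")),
       descriptors = rbind(ben$descriptors, mal$descriptors))
}

#' Detection sensitivity/specificity of the full default pipeline
#'
#' The package's headline benchmark: for each seed, run the whole flow
#' (phantom, denoise, segment, crop, features, LDA, hybrid rule+SVM) with
#' default settings, train on `n_train` slices and report candidate-level
#' sensitivity and specificity on `n_test` held-out slices.
#'
#' @param seeds benchmark seeds.
#' @param n_train,n_test slice counts.
#' @return data frame with one row per seed: sensitivity, specificity.
#' @export
detection_benchmark <- function(seeds, n_train = 6, n_test = 3) {
  spec_args <- list(width = 128, height = 128, n_nodules = 3, n_vessels = 5,
                    noise_sigma = 0.05)
  rows <- lapply(seeds, function(s) {
    tr <- phantom_candidate_dataset(n_train, seed = s * 1000L, spec_args = spec_args)
    te <- phantom_candidate_dataset(n_test, seed = s * 1000L + n_train,
                                    spec_args = spec_args)
    fitted <- fit_model(model_spec("hybrid", use_lda = TRUE), tr$X, tr$y,
                        descriptors = tr$descriptors, seed = s)
    pred <- predict(fitted, te$X, descriptors = te$descriptors)
    m <- confusion_metrics(te$y, pred, "nodule")
    data.frame(seed = s, sensitivity = m$sensitivity, specificity = m$specificity)
  })
  do.call(rbind, rows)
}

#' Compare the classifier bank on repeated phantom benchmarks
#'
#' For each seed, builds a fresh candidate dataset, splits it by slice into
#' train/test, fits every declared model on identical data and records
#' held-out accuracy. This is the harness behind the qualitative ordering
#' checks (LDA+rule+SVM vs rule+SVM vs plain SVM vs baselines).
#'
#' @param seeds integer vector of benchmark seeds.
#' @param models named list of [model_spec()]s.
#' @param n_slices slices per seed.
#' @param spec_args phantom parameters.
#' @param train_frac fraction of slices used for training.
#' @return matrix of accuracies, seeds x models.
#' @export
benchmark_models <- function(seeds, models,
                             n_slices = 8,
                             spec_args = list(width = 128, height = 128,
                                              n_nodules = 3, n_vessels = 5,
                                              noise_sigma = 0.05),
                             train_frac = 0.75) {
  acc <- matrix(NA_real_, length(seeds), length(models),
                dimnames = list(NULL, names(models)))
  for (si in seq_along(seeds)) {
    ds <- phantom_candidate_dataset(n_slices, seed = seeds[si] * 1000L,
                                    spec_args = spec_args)
    tr_slices <- seq_len(ceiling(train_frac * n_slices))
    tr <- ds$slice %in% tr_slices
    if (length(unique(ds$y[tr])) < 2 || length(unique(ds$y[!tr])) < 2) next
    for (mi in seq_along(models)) {
      fitted <- fit_model(models[[mi]], ds$X[tr, , drop = FALSE], ds$y[tr],
                          descriptors = ds$descriptors[tr, , drop = FALSE],
                          seed = seeds[si])
      pred <- predict(fitted, ds$X[!tr, , drop = FALSE],
                      descriptors = ds$descriptors[!tr, , drop = FALSE])
      acc[si, mi] <- mean(pred == ds$y[!tr])
    }
  }
  acc[stats::complete.cases(acc), , drop = FALSE]
}
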