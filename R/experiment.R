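# Experiment orchestration: the four tasks, the fixed 80/20 stratified
# split, repeated stratified 10-fold cross-validation over candidate
# (feature x model) configurations, cascaded inference, and ablations.
# All feature fitting happens inside the training data (or training fold)
# only; the test set is touched exactly once, by the selected model.

#' Model configuration
#'
#' @param family One of `"majority"`, `"nb"`, `"logistic"`, `"svm"`.
#' @param lambda L2 strength for logistic regression (default 1).
#' @param C Hinge trade-off for the linear SVM (default 1).
#' @param max_epochs,batch_size,learning_rate,tol,seed Optimizer settings
#'   passed to the corresponding fit function.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("svm", "logistic", "nb", "majority"),
                         lambda = 1, C = 1, max_epochs = 100,
                         batch_size = 32, learning_rate = 0.1,
                         tol = 1e-4, seed = 42) {
  family <- match.arg(family)
  structure(list(family = family, lambda = lambda, C = C,
                 max_epochs = max_epochs, batch_size = batch_size,
                 learning_rate = learning_rate, tol = tol, seed = seed),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model config: %s\n", x$family))
  invisible(x)
}

# fit the configured classifier; naive Bayes and the majority baseline
# consume token sequences, the linear models the feature matrix
fit_classifier <- function(mconfig, features, token_seqs, labels) {
  switch(mconfig$family,
    majority = fit_majority(labels),
    nb = fit_naive_bayes(token_seqs, labels),
    logistic = fit_logistic(features, labels, lambda = mconfig$lambda,
                            max_epochs = mconfig$max_epochs,
                            batch_size = mconfig$batch_size,
                            learning_rate = mconfig$learning_rate,
                            tol = mconfig$tol, seed = mconfig$seed),
    svm = fit_linear_svm(features, labels, C = mconfig$C,
                         max_epochs = mconfig$max_epochs,
                         tol = mconfig$tol))
}

predict_classifier <- function(model, features, token_seqs) {
  if (inherits(model, "naive_bayes_model")) {
    predict(model, token_seqs)
  } else if (inherits(model, "majority_model")) {
    predict(model, length(token_seqs))
  } else {
    predict(model, features)
  }
}

# does this model family need the feature matrix at all?
needs_features <- function(mconfig) {
  mconfig$family %in% c("logistic", "svm")
}

#' Repeated stratified cross-validation over candidate configurations
#'
#' Scores every candidate — a list with elements `features` (a
#' [feature_config()]) and `model` (a [model_config()]) — by mean
#' validation accuracy over `folds` x `repeats` stratified partitions,
#' fitting all feature models inside each training fold only. The winner
#' is the candidate with the highest mean accuracy; ties break by mean
#' macro-F1, then by candidate order. A single candidate is returned
#' unconditionally without fold evaluation.
#'
#' @param token_seqs List of training token vectors.
#' @param labels Training labels.
#' @param candidates List of candidate configurations.
#' @param folds Folds per repeat (default 10; reduced with a warning when
#'   the smallest stratum is smaller).
#' @param repeats Distinct fold partitions (default 3).
#' @param seed Base RNG seed; repeat r uses `seed + r`.
#' @param lexicon Concept lexicon for concept-block candidates.
#' @return A list: `best` (the winning candidate), `best_index`, and
#'   `scores` (data.frame of mean accuracy and macro-F1 per candidate;
#'   `NULL` when only one candidate was supplied).
#' @export
cross_validate <- function(token_seqs, labels, candidates, folds = 10,
                           repeats = 3, seed = 42,
                           lexicon = default_concept_lexicon()) {
  if (length(candidates) == 0L) stop("no candidate configurations")
  if (length(candidates) == 1L) {
    return(list(best = candidates[[1L]], best_index = 1L, scores = NULL))
  }
  labels <- as.character(labels)
  acc <- matrix(0, nrow = length(candidates), ncol = 0L)
  f1 <- matrix(0, nrow = length(candidates), ncol = 0L)
  for (r in seq_len(repeats)) {
    assign <- stratified_folds(labels, folds = folds, seed = seed + r)
    kf <- attr(assign, "folds")
    for (fold in seq_len(kf)) {
      val <- which(assign == fold)
      trn <- which(assign != fold)
      col_acc <- numeric(length(candidates))
      col_f1 <- numeric(length(candidates))
      for (ci in seq_along(candidates)) {
        cand <- candidates[[ci]]
        fm <- NULL
        feats_trn <- NULL
        feats_val <- NULL
        if (needs_features(cand$model)) {
          fm <- fit_feature_models(token_seqs[trn], labels[trn],
                                   cand$features, lexicon = lexicon,
                                   seed = seed + r)
          feats_trn <- build_feature_matrix(token_seqs[trn], fm)
          feats_val <- build_feature_matrix(token_seqs[val], fm)
        }
        model <- fit_classifier(cand$model, feats_trn, token_seqs[trn],
                                labels[trn])
        pred <- predict_classifier(model, feats_val, token_seqs[val])
        rep_ <- evaluate_predictions(pred, labels[val],
                                     classes = sort(unique(labels)))
        col_acc[ci] <- rep_$accuracy
        col_f1[ci] <- rep_$macro_f1
      }
      acc <- cbind(acc, col_acc)
      f1 <- cbind(f1, col_f1)
    }
  }
  mean_acc <- rowMeans(acc)
  mean_f1 <- rowMeans(f1)
  best <- order(-mean_acc, -mean_f1, seq_along(candidates))[1L]
  list(best = candidates[[best]], best_index = best,
       scores = data.frame(candidate = seq_along(candidates),
                           mean_accuracy = mean_acc,
                           mean_macro_f1 = mean_f1))
}

#' Run one classification experiment end to end
#'
#' Maps the corpus onto the task's label scheme (dropping excluded
#' records), preprocesses, splits once under the fixed stratified 80/20
#' scheme, selects a candidate by repeated stratified cross-validation on
#' the training set, refits the winner on the full training set and
#' evaluates it exactly once on the test set.
#'
#' @param corpus A `strategy_corpus`.
#' @param task Task id in 1:4.
#' @param candidates A list of candidate configurations (each a list with
#'   `features` and `model`), or a single such configuration.
#' @param split_seed,cv_seed RNG seeds for the split and the fold
#'   partitions.
#' @param folds,repeats Cross-validation shape (defaults 10 x 3).
#' @param lexicon Concept lexicon for concept-block candidates.
#' @param preprocess_cfg A [preprocess_config()].
#' @param token_seqs Optional precomputed result of
#'   [preprocess_corpus()] for `corpus` (skips preprocessing).
#' @return An object of class `strategy_experiment`: the test-set
#'   `report`, the selected configuration, the fitted model and a
#'   provenance record (seeds, counts, fold scores).
#' @export
run_experiment <- function(corpus, task, candidates,
                           split_seed = 42, cv_seed = 42, folds = 10,
                           repeats = 3,
                           lexicon = default_concept_lexicon(),
                           preprocess_cfg = preprocess_config(),
                           token_seqs = NULL) {
  if (!is.null(candidates$model) &&
      inherits(candidates$model, "model_config")) {
    candidates <- list(candidates)
  }
  if (is.null(token_seqs)) {
    token_seqs <- preprocess_corpus(corpus, preprocess_cfg)
  }
  tlab <- task_labels(corpus$label, task)
  keep <- which(tlab != "EXCLUDED")
  if (length(keep) == 0L) stop("no records in the task domain")
  toks <- token_seqs[keep]
  labs <- tlab[keep]
  sp <- stratified_split(labs, seed = split_seed)
  sel <- cross_validate(toks[sp$train], labs[sp$train], candidates,
                        folds = folds, repeats = repeats, seed = cv_seed,
                        lexicon = lexicon)
  cand <- sel$best
  fm <- NULL
  feats_trn <- NULL
  feats_tst <- NULL
  if (needs_features(cand$model)) {
    fm <- fit_feature_models(toks[sp$train], labs[sp$train],
                             cand$features, lexicon = lexicon,
                             seed = cv_seed)
    feats_trn <- build_feature_matrix(toks[sp$train], fm)
    feats_tst <- build_feature_matrix(toks[sp$test], fm)
  }
  model <- fit_classifier(cand$model, feats_trn, toks[sp$train],
                          labs[sp$train])
  pred <- predict_classifier(model, feats_tst, toks[sp$test])
  report <- evaluate_predictions(pred, labs[sp$test],
                                 classes = task_classes(task))
  structure(list(report = report, task = task, selected = cand,
                 selection = sel, model = model, feature_models = fm,
                 provenance = list(split_seed = split_seed,
                                   cv_seed = cv_seed, folds = folds,
                                   repeats = repeats,
                                   n_train = length(sp$train),
                                   n_test = length(sp$test),
                                   test_counts = sp$test_counts)),
            class = "strategy_experiment")
}

#' @export
print.strategy_experiment <- function(x, ...) {
  cat(sprintf("Task %d experiment (%s + %s): ", x$task,
              x$selected$model$family,
              if (is.null(x$selected$features)) "tokens"
              else x$selected$features$base))
  cat(sprintf("accuracy %.2f%%, macro-F1 %.2f (test n = %d)\n",
              100 * x$report$accuracy, x$report$macro_f1, x$report$n))
  invisible(x)
}

#' Build a stage predictor for the cascade
#'
#' Fits one task's feature models and classifier on the given training
#' records and wraps them as a function from a token sequence to a label.
#'
#' @param token_seqs Training token sequences.
#' @param labels Training labels in the stage's scheme.
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param lexicon Concept lexicon.
#' @param seed RNG seed for feature fitting.
#' @return A function: `function(tokens) -> label`.
#' @export
stage_predictor <- function(token_seqs, labels, features, model,
                            lexicon = default_concept_lexicon(),
                            seed = 42) {
  mconfig <- model
  fm <- NULL
  feats <- NULL
  if (needs_features(mconfig)) {
    fm <- fit_feature_models(token_seqs, labels, features,
                             lexicon = lexicon, seed = seed)
    feats <- build_feature_matrix(token_seqs, fm)
  }
  fitted <- fit_classifier(mconfig, feats, token_seqs, labels)
  function(tokens) {
    fv <- if (!is.null(fm)) {
      matrix(build_feature_vector(tokens, fm), nrow = 1L)
    } else NULL
    predict_classifier(fitted, fv, list(tokens))[[1L]]
  }
}

#' Cascaded (pipelined) five-class prediction
#'
#' Runs tasks 1-3 in sequence: a record predicted non-strategy stops at
#' stage 1; a strategy predicted extrinsic stops at stage 2 as ENV;
#' otherwise stage 3 assigns one of the intrinsic classes. Later stages
#' are never invoked after a stop.
#'
#' @param tokens Character vector of preprocessed tokens (one record).
#' @param stages List of three stage functions (see [stage_predictor()]):
#'   stage 1 returns STRATEGY/NONSTRAT, stage 2 EXTRINSIC/INTRINSIC,
#'   stage 3 SELF/PREF/COMP.
#' @return One of the five class labels.
#' @export
cascade_predict <- function(tokens, stages) {
  if (length(stages) < 3L || any(vapply(stages, is.null, logical(1L)))) {
    stop("cascade needs all three stage models")
  }
  s1 <- stages[[1L]](tokens)
  if (s1 == "NONSTRAT") return("NONSTRAT")
  s2 <- stages[[2L]](tokens)
  if (s2 == "EXTRINSIC") return("ENV")
  s3 <- stages[[3L]](tokens)
  if (!s3 %in% intrinsic_classes()) {
    stop("stage 3 returned a non-intrinsic label: ", s3)
  }
  s3
}

#' @rdname cascade_predict
#' @param token_seqs List of token vectors.
#' @return `cascade_predict_corpus()`: character vector of five-class
#'   labels, one per record.
#' @export
cascade_predict_corpus <- function(token_seqs, stages) {
  vapply(token_seqs, cascade_predict, character(1L), stages = stages)
}

#' Feature-block ablation
#'
#' Evaluates the full configuration, then each variant with exactly one
#' hand-crafted block (concepts, pos, dep, pmi) toggled off. Blocks not
#' enabled in the base configuration yield a not-applicable row.
#'
#' @param corpus A `strategy_corpus`.
#' @param task Task id in 1:4.
#' @param features The full [feature_config()].
#' @param model A [model_config()].
#' @param ... Passed to [run_experiment()].
#' @return An object of class `ablation_report`: a data.frame with one
#'   row for the full configuration and one per toggle.
#' @export
run_ablation <- function(corpus, task, features, model, ...) {
  toggles <- c(concepts = "concepts", pos = "pos", dep = "dep",
               pmi = "pmi")
  full <- run_experiment(corpus, task,
                         list(features = features, model = model), ...)
  rows <- data.frame(configuration = "full",
                     accuracy = 100 * full$report$accuracy,
                     macro_f1 = full$report$macro_f1,
                     applicable = TRUE, stringsAsFactors = FALSE)
  for (tg in names(toggles)) {
    if (!isTRUE(features[[tg]])) {
      rows <- rbind(rows, data.frame(configuration = paste0("-", tg),
                                     accuracy = NA_real_,
                                     macro_f1 = NA_real_,
                                     applicable = FALSE))
      next
    }
    fc <- features
    fc[[tg]] <- FALSE
    ex <- run_experiment(corpus, task,
                         list(features = fc, model = model), ...)
    rows <- rbind(rows, data.frame(configuration = paste0("-", tg),
                                   accuracy = 100 * ex$report$accuracy,
                                   macro_f1 = ex$report$macro_f1,
                                   applicable = TRUE))
  }
  class(rows) <- c("ablation_report", "data.frame")
  rows
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Feature ablation (accuracy %, macro-F1):\n")
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `features` and `model` are passed as arguments to
#' [feature_config()] and [model_config()]; any other keys are returned
#' untouched.
#'
#' @param path Path to a YAML file.
#' @return List with elements `features`, `model` and the remaining keys.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  out$features <- do.call(feature_config, as.list(raw$features))
  out$model <- do.call(model_config, as.list(raw$model))
  out
}
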