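#' Pipeline configuration
#'
#' One canonical record of everything a training run depends on, so that
#' identical configurations reproduce identical artifacts. Either a
#' pre-computed labeled feature-matrix TSV, or positive/negative FASTA
#' files plus an AAindex1 file, may serve as input.
#'
#' @param fasta_pos,fasta_neg Paths to FASTA files of the two classes.
#' @param aaindex Path to an AAindex1 flat file.
#' @param matrix_tsv Path to a labeled feature-matrix TSV (alternative to
#'   the FASTA + AAindex route).
#' @param method Selector: `"relieff"`, `"infogain"` or `"mrmr"`.
#' @param n_features Size of the frozen feature subset (`NULL` = all).
#' @param C_grid,gamma_grid Grid-search lattices.
#' @param k_folds Cross-validation folds.
#' @param seed Seed for fold assignment (and any other randomness).
#' @param standardize Apply z-score standardization fitted on training
#'   data before selection and classification.
#' @param nested Recompute the feature ranking inside each fold when
#'   estimating cross-validated performance (honest estimate); the
#'   deployed model still uses the frozen subset.
#' @param relieff_k ReliefF neighbor count.
#' @param out_dir If non-`NULL`, artifacts (model JSON, ranking TSV, grid
#'   TSV, report JSON) are written here.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta_pos = NULL, fasta_neg = NULL,
                            aaindex = NULL, matrix_tsv = NULL,
                            method = "relieff", n_features = NULL,
                            C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            k_folds = 5L, seed = 1L, standardize = TRUE,
                            nested = FALSE, relieff_k = 10L,
                            out_dir = NULL) {
  method <- match.arg(method, c("relieff", "infogain", "mrmr"))
  have_fasta <- !is.null(fasta_pos) && !is.null(fasta_neg) && !is.null(aaindex)
  if (!have_fasta && is.null(matrix_tsv))
    stop_config("provide either fasta_pos+fasta_neg+aaindex or matrix_tsv")
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Load the labeled training matrix a configuration points at
#'
#' @param config A [pipeline_config()].
#' @return A labeled [feature_matrix()].
#' @export
load_training_data <- function(config) {
  if (!is.null(config$matrix_tsv)) {
    m <- read_feature_matrix(config$matrix_tsv)
    if (is.null(m$y)) stop_format("training matrix must be labeled")
    return(m)
  }
  pos <- read_fasta(config$fasta_pos)
  neg <- read_fasta(config$fasta_neg)
  tables <- read_aaindex1(config$aaindex)
  encode_dataset(rbind(pos, neg), tables,
                 y = rep(c(1L, -1L), c(nrow(pos), nrow(neg))))
}

# Dispatch a selector on a labeled matrix.
rank_features <- function(m, method, relieff_k = 10L, n_features = NULL) {
  switch(method,
         relieff = relieff_weights(m, k_neighbors = relieff_k),
         infogain = infogain_scores(m),
         mrmr = mrmr_order(m, n_select = n_features %||% ncol(m$X)),
         stop_config("unknown selector: ", method))
}

#' Run the training workflow
#'
#' Executes the full training pipeline: encode (if starting from FASTA),
#' standardize (statistics fitted on the training data only), rank
#' features with the configured filter method and freeze the top subset,
#' tune `(C, gamma)` by stratified cross-validated grid search on that
#' subset, refit on all training data at the best pair, and report
#' cross-validated performance from the out-of-fold predictions at the
#' best pair.
#'
#' @param config A [pipeline_config()].
#' @param train Optional labeled [feature_matrix()]; when supplied, the
#'   configuration's input paths are ignored.
#' @return A list with `model` (`lux_svm`), `grid` (`lux_grid_search`),
#'   `ranking` (`feature_ranking` or `NULL`), `cv_report`
#'   (`evaluation_report` from out-of-fold predictions), `selected`
#'   (feature ids used) and `config`.
#' @export
run_train <- function(config, train = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(train)) train <- load_training_data(config)
  y <- assert_labels(train$y)

  scaling <- NULL
  work <- train
  if (isTRUE(config$standardize)) {
    scaling <- fit_standardizer(train)
    work <- apply_standardizer(train, scaling)
  }

  d <- ncol(work$X)
  k_sel <- config$n_features %||% d
  if (k_sel > d) stop_config("n_features (", k_sel, ") exceeds d = ", d)
  ranking <- rank_features(work, config$method, config$relieff_k, k_sel)
  selected <- top_k(ranking, k_sel)
  sub <- subset_features(work, selected)

  grid <- grid_search_cv(sub, C_grid = config$C_grid,
                         gamma_grid = config$gamma_grid,
                         k = config$k_folds, seed = config$seed)

  sub_scaling <- if (!is.null(scaling))
    list(center = scaling$center[selected], scale = scaling$scale[selected])
  model <- train_svm(sub, C = grid$best_C, gamma = grid$best_gamma,
                     scaling = sub_scaling)

  cv_report <- cv_out_of_fold_report(train, config, grid, selected)

  result <- list(model = model, grid = grid, ranking = ranking,
                 cv_report = cv_report, selected = selected, config = config)
  if (!is.null(config$out_dir)) write_train_artifacts(result, config$out_dir)
  result
}

# Out-of-fold evaluation at the tuned (C, gamma). Under `nested`, the
# standardizer and the feature ranking are refitted inside each fold.
cv_out_of_fold_report <- function(train, config, grid, selected) {
  y <- train$y
  folds <- stratified_kfold(y, k = config$k_folds, seed = config$seed)
  pred <- integer(length(y)); dec <- numeric(length(y))
  for (fold in seq_len(config$k_folds)) {
    tr <- folds != fold
    tr_m <- feature_matrix(train$X[tr, , drop = FALSE], train$sample_ids[tr],
                           train$feature_ids, y[tr])
    te_m <- feature_matrix(train$X[!tr, , drop = FALSE],
                           train$sample_ids[!tr], train$feature_ids, y[!tr])
    if (isTRUE(config$standardize)) {
      sc <- fit_standardizer(tr_m)
      tr_m <- apply_standardizer(tr_m, sc)
      te_m <- apply_standardizer(te_m, sc)
    }
    ids <- if (isTRUE(config$nested)) {
      k_sel <- length(selected)
      top_k(rank_features(tr_m, config$method, config$relieff_k, k_sel), k_sel)
    } else selected
    fit <- train_svm(subset_features(tr_m, ids),
                     C = grid$best_C, gamma = grid$best_gamma)
    f <- decision_value(fit, subset_features(te_m, ids)$X)
    dec[!tr] <- f
    pred[!tr] <- ifelse(f > 0, 1L, -1L)
  }
  evaluation_report(y, pred, decision_values = dec)
}

write_train_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  provenance <- list(seed = cfg$seed, method = cfg$method,
                     n_features = length(result$selected),
                     standardize = isTRUE(cfg$standardize),
                     nested = isTRUE(cfg$nested),
                     package_version = as.character(utils::packageVersion("luxpred")))
  save_model(result$model, file.path(out_dir, "model.json"),
             extra = list(provenance = provenance))
  rk <- result$ranking
  utils::write.table(
    data.frame(rank = seq_along(rk$feature_ids), feature_id = rk$feature_ids,
               score = formatC(rk$scores, format = "g", digits = 17)),
    file.path(out_dir, "ranking.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  g <- result$grid
  utils::write.table(
    within(g$grid, cv_accuracy <- formatC(cv_accuracy, format = "g", digits = 17)),
    file.path(out_dir, "grid.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  rep <- result$cv_report
  writeLines(jsonlite::toJSON(list(
    provenance = provenance,
    counts = unclass(rep$counts),
    accuracy = rep$accuracy, sensitivity = rep$sensitivity,
    specificity = rep$specificity, mcc = rep$mcc,
    auc = rep$auc,
    best_C = g$best_C, best_gamma = g$best_gamma,
    best_cv_accuracy = g$best_accuracy), auto_unbox = TRUE, digits = NA),
    file.path(out_dir, "cv_report.json"))
  invisible(out_dir)
}

#' Predict classes for new sequences with a trained model
#'
#' Encodes the sequences for exactly the features the model expects,
#' applies the stored scaling, and reports decision values and predicted
#' labels (`+1` = positive class, e.g. bioluminescent). If true labels
#' are supplied, a full [evaluation_report()] is attached.
#'
#' @param model A `lux_svm` (or a path to a model JSON).
#' @param records Sequence records from [read_fasta()] (or a FASTA path).
#' @param tables Property tables from [read_aaindex1()] (or an AAindex1
#'   path); must contain every accession the model expects.
#' @param y Optional true labels in `{+1, -1}`.
#' @return A list with `predictions` (data frame: `id`, `decision_value`,
#'   `label`) and, when `y` is given, `report`.
#' @export
run_predict <- function(model, records, tables, y = NULL) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "lux_svm"))
  if (is.character(records)) records <- read_fasta(records)
  if (is.character(tables)) tables <- read_aaindex1(tables)
  accs <- vapply(tables, function(t) t$accession, "")
  missing <- setdiff(model$feature_ids, accs)
  if (length(missing))
    stop_format("AAindex input lacks accession(s) the model needs: ",
                paste(missing, collapse = ", "))
  m <- encode_dataset(records, tables[match(model$feature_ids, accs)], y = y)
  if (!is.null(model$scaling)) m <- apply_standardizer(m, model$scaling)
  f <- decision_value(model, m$X)
  out <- list(predictions = data.frame(
    id = records$id, decision_value = f,
    label = ifelse(f > 0, 1L, -1L), stringsAsFactors = FALSE))
  if (!is.null(y)) out$report <- evaluation_report(y, out$predictions$label, f)
  out
}

#' Run the selector-by-subset-size experiment table
#'
#' For every selector method and every subset size, trains with
#' cross-validated grid search on the training matrix and evaluates on
#' the held-out test matrix, mirroring the benchmark-table design
#' (sensitivity, specificity, MCC, test accuracy, CV accuracy per row).
#' A size equal to the full dimension is reported as `"all"`.
#'
#' @param train,test Labeled [feature_matrix()] objects over the same
#'   features.
#' @param methods Selector methods to run.
#' @param subset_sizes Integer vector of subset sizes.
#' @param config A [pipeline_config()] supplying grids, folds, seed and
#'   flags (its `method`/`n_features` are overridden per row).
#' @return A data frame with columns `method`, `n_features`,
#'   `sensitivity`, `specificity`, `mcc`, `test_accuracy`, `cv_accuracy`.
#' @export
run_experiment_table <- function(train, test,
                                 methods = c("relieff", "infogain", "mrmr"),
                                 subset_sizes = c(100L, 200L, 300L, 400L, 500L),
                                 config = pipeline_config(matrix_tsv = "unused")) {
  stopifnot(inherits(train, "feature_matrix"), inherits(test, "feature_matrix"))
  if (!identical(train$feature_ids, test$feature_ids))
    stop_format("train and test matrices must share features")
  d <- ncol(train$X)
  if (any(subset_sizes > d))
    stop_config("subset sizes exceed feature count d = ", d)
  rows <- list()
  for (method in methods) {
    for (k_sel in subset_sizes) {
      cfg <- config
      cfg$method <- method
      cfg$n_features <- as.integer(k_sel)
      cfg$out_dir <- NULL
      fit <- run_train(cfg, train = train)
      scaled_test <- if (isTRUE(cfg$standardize))
        apply_standardizer(test, fit_standardizer(train)) else test
      f <- decision_value(fit$model, subset_features(scaled_test, fit$selected)$X)
      rep <- evaluation_report(test$y, ifelse(f > 0, 1L, -1L), f)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method,
        n_features = if (k_sel == d) "all" else as.character(k_sel),
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        mcc = rep$mcc, test_accuracy = rep$accuracy,
        cv_accuracy = fit$grid$best_accuracy, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
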