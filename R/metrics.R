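#' Confusion counts for binary interaction predictions
#'
#' Class 1 (interaction) is the positive class.
#'
#' @param y_true,y_pred Integer vectors of labels in {0, 1}.
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion(c(1, 0, 1, 0), c(1, 0, 0, 1))
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ")
  }
  if (any(!y_true %in% c(0L, 1L)) || any(!y_pred %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

#' Accuracy, specificity, sensitivity and precision from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), specificity = TN/(TN+FP),
#' sensitivity = TP/(TP+FN), precision = TP/(TP+FP). A metric whose
#' denominator is zero is returned as `NA` (explicitly undefined), never as
#' a silent zero.
#'
#' @param counts Named vector from [confusion()] (`TP`, `TN`, `FP`, `FN`).
#' @return Named numeric vector `accuracy`, `specificity`, `sensitivity`,
#'   `precision`.
#' @export
classification_metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("invalid confusion counts")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = ratio(tp + tn, tp + tn + fp + fn),
    specificity = ratio(tn, tn + fp),
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp))
}

#' Cross-validated evaluation of the encode-train-predict pipeline
#'
#' For each of `k` stratified folds: fit the per-feature scaler on the
#' training folds' proteins only, encode training and test pairs with it,
#' train a fresh stacked autoencoder on the training folds, and evaluate on
#' the held-out fold. No information from a test fold — scaler included —
#' enters training.
#'
#' @param pairs Data frame `idA`, `idB`, `label`.
#' @param features Per-protein feature matrix from [encode_proteins()].
#' @param hidden Hidden layer sizes for [sae()].
#' @param control [sae_control()] hyperparameters.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving folds, initialization and batch order.
#' @param pretrain Run layer-wise pretraining (default TRUE).
#' @return Object of class `ppi_cv`: list with `folds` (per-fold metric data
#'   frame), `mean`, `sd`, `counts` (summed confusion counts), `k`, `hidden`.
#' @export
cross_validate <- function(pairs, features, hidden = 400L,
                           control = sae_control(), k = 10L, seed = 1L,
                           pretrain = TRUE) {
  if (length(unique(pairs$label)) < 2L) {
    stop("dataset must contain both classes")
  }
  fold <- make_folds(pairs$label, k = k, seed = seed)
  per_fold <- vector("list", k)
  total_counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    tr <- pairs[fold != f, , drop = FALSE]
    te <- pairs[fold == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2L) {
      stop("training folds for fold ", f, " contain a single class")
    }
    enc_tr <- encode_pair_matrix(tr, features)          # fits scaler on train
    enc_te <- encode_pair_matrix(te, features, enc_tr$scaler)
    fit <- sae(enc_tr$x, tr$label, hidden = hidden, control = control,
               pretrain = pretrain, seed = derive_seed(seed, 10L + f))
    pred <- predict(fit, enc_te$x)
    cts <- confusion(te$label, pred)
    total_counts <- total_counts + cts
    per_fold[[f]] <- c(fold = f, cts, classification_metrics(cts))
  }
  folds <- as.data.frame(do.call(rbind, per_fold))
  metric_cols <- c("accuracy", "specificity", "sensitivity", "precision")
  out <- list(
    folds = folds,
    assignment = fold,
    mean = colMeans(folds[metric_cols], na.rm = TRUE),
    sd = apply(folds[metric_cols], 2, stats::sd, na.rm = TRUE),
    counts = total_counts,
    k = k, hidden = hidden, seed = seed
  )
  class(out) <- "ppi_cv"
  out
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation, hidden layer(s) [",
      paste(x$hidden, collapse = ", "), "]\n", sep = "")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Compare candidate network architectures by cross-validation
#'
#' Runs [cross_validate()] for each candidate hidden-layer configuration and
#' selects the one with the highest mean accuracy; ties are broken toward
#' the architecture with fewer trainable parameters.
#'
#' @param pairs,features,control,k,seed,pretrain As in [cross_validate()].
#' @param candidates List of hidden-size vectors, e.g.
#'   `list(100, 400, c(400, 100))`.
#' @return List with `table` (one row per candidate: architecture, mean and
#'   sd accuracy, parameter count), `best` (the winning hidden sizes) and
#'   `results` (the full `ppi_cv` objects).
#' @export
architecture_sweep <- function(pairs, features, candidates,
                               control = sae_control(), k = 10L, seed = 1L,
                               pretrain = TRUE) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  n_in <- 2L * ncol(features)
  n_params <- vapply(candidates, function(h) {
    dims <- c(n_in, h, 2L)
    sum(dims[-1] * (dims[-length(dims)] + 1L))
  }, numeric(1))
  results <- lapply(candidates, function(h) {
    cross_validate(pairs, features, hidden = h, control = control,
                   k = k, seed = seed, pretrain = pretrain)
  })
  acc <- vapply(results, function(r) r$mean[["accuracy"]], numeric(1))
  tbl <- data.frame(
    architecture = vapply(candidates, function(h)
      paste0("[", paste(c(n_in, h, 2L), collapse = ","), "]"), character(1)),
    mean_accuracy = acc,
    sd_accuracy = vapply(results, function(r) r$sd[["accuracy"]], numeric(1)),
    n_parameters = n_params,
    stringsAsFactors = FALSE
  )
  best <- order(-acc, n_params)[1L]
  list(table = tbl, best = candidates[[best]], results = results)
}

#' Write per-fold metrics as CSV
#'
#' Columns: fold, TP, TN, FP, FN, accuracy, specificity, sensitivity,
#' precision, plus `mean` and `sd` summary rows.
#'
#' @param cv A `ppi_cv` object.
#' @param path Output path.
#' @export
write_cv_metrics <- function(cv, path) {
  df <- cv$folds
  metric_cols <- c("accuracy", "specificity", "sensitivity", "precision")
  summary_rows <- df[seq_len(2), , drop = FALSE]
  summary_rows[] <- NA
  summary_rows$fold <- c("mean", "sd")
  summary_rows[1, metric_cols] <- cv$mean
  summary_rows[2, metric_cols] <- cv$sd
  df$fold <- as.character(df$fold)
  utils::write.csv(rbind(df, summary_rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
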