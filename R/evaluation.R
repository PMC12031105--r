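#' Classification metrics: accuracy, macro precision, macro F1
#'
#' Precision and F1 are macro-averaged over classes; a class absent
#' from the predictions contributes 0 precision (with a warning).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_levels Class set; defaults to the union of observed
#'   labels.
#' @return List with `accuracy`, `precision`, `f1` in \[0, 1\].
#' @export
classification_metrics <- function(y_true, y_pred,
                                   class_levels = NULL) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  if (is.null(class_levels)) {
    class_levels <- sort(unique(c(y_true, y_pred)))
  }
  yt <- factor(y_true, levels = class_levels)
  yp <- factor(y_pred, levels = class_levels)
  cm <- table(yt, yp)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- rec <- f1 <- numeric(length(class_levels))
  for (k in seq_along(class_levels)) {
    tp <- cm[k, k]
    pred_k <- sum(cm[, k])
    true_k <- sum(cm[k, ])
    if (pred_k == 0) {
      if (true_k > 0) {
        warning("class never predicted: ", class_levels[k],
          " (0 precision)")
      }
      prec[k] <- 0
    } else {
      prec[k] <- tp / pred_k
    }
    rec[k] <- if (true_k == 0) 0 else tp / true_k
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else {
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    }
  }
  present <- vapply(seq_along(class_levels),
    function(k) sum(cm[k, ]) > 0, logical(1))
  list(
    accuracy = acc,
    precision = mean(prec[present]),
    f1 = mean(f1[present]),
    confusion = cm
  )
}

#' Leave-one-task-out cross-validation
#'
#' One fold per task: the held-out task is the test set, the
#' remaining tasks form the training set. Feature scaling is fitted
#' on each training fold only; per-fold seeds are derived from the
#' base config seed plus the fold index.
#'
#' @param dataset List of `discrete_graph`s with task tags and all
#'   levels present in every task.
#' @param config A [sgatcn_config()].
#' @param class_levels Workload level order.
#' @param verbose Print per-fold results.
#' @return An `eval_report`: per-fold metrics, mean metrics, config
#'   provenance.
#' @export
cross_task_cv <- function(dataset, config = sgatcn_config(),
                          class_levels = c("low", "medium", "high"),
                          verbose = FALSE) {
  tasks <- vapply(dataset, `[[`, character(1), "task")
  labels <- vapply(dataset, `[[`, character(1), "label")
  fold_tasks <- unique(tasks)
  if (length(fold_tasks) < 2L) stop("need >= 2 distinct tasks")
  for (task in fold_tasks) {
    lv <- unique(labels[tasks == task])
    if (!all(class_levels %in% lv)) {
      stop("task ", task, " is missing workload level(s): ",
        paste(setdiff(class_levels, lv), collapse = ", "))
    }
  }
  folds <- list()
  for (f in seq_along(fold_tasks)) {
    held <- fold_tasks[f]
    train_idx <- which(tasks != held)
    test_idx <- which(tasks == held)
    fold_config <- config
    fold_config$seed <- config$seed + f
    model <- sgatcn_train(dataset[train_idx], fold_config,
      class_levels = class_levels)
    pred <- sgatcn_classify(model, dataset[test_idx])
    metrics <- classification_metrics(labels[test_idx], pred,
      class_levels = class_levels)
    folds[[f]] <- list(task = held, metrics = metrics,
      n_test = length(test_idx))
    if (verbose) {
      message(sprintf("fold %s: acc %.3f", held, metrics$accuracy))
    }
  }
  mean_of <- function(field) {
    mean(vapply(folds, function(f) f$metrics[[field]], numeric(1)))
  }
  structure(
    list(
      folds = folds,
      accuracy = mean_of("accuracy"),
      precision = mean_of("precision"),
      f1 = mean_of("f1"),
      config = config
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> leave-one-task-out cross-validation\n")
  for (f in x$folds) {
    cat(sprintf("  test=%-10s acc %.3f prec %.3f f1 %.3f (n=%d)\n",
      f$task, f$metrics$accuracy, f$metrics$precision, f$metrics$f1,
      f$n_test))
  }
  cat(sprintf("  mean: acc %.3f prec %.3f f1 %.3f\n", x$accuracy,
    x$precision, x$f1))
  invisible(x)
}

#' Sparsity sweep of cross-task accuracy
#'
#' Re-runs the full leave-one-task-out cross-validation at each
#' sparsity. Because sparsification is part of graph construction,
#' the caller supplies a builder that maps a sparsity value to the
#' dataset (e.g. a closure over [build_discrete_graphs()]).
#'
#' @param dataset_builder Function `(sparsity) -> list of
#'   discrete_graph`.
#' @param sparsities Numeric vector in (0, 1).
#' @param config A [sgatcn_config()].
#' @param class_levels Workload level order.
#' @return Data frame: sparsity, held-out task, accuracy, plus the
#'   per-sparsity mean rows (`task == "mean"`).
#' @export
sparsity_sweep <- function(dataset_builder, sparsities,
                           config = sgatcn_config(),
                           class_levels = c("low", "medium", "high")) {
  stopifnot(all(sparsities > 0 & sparsities < 1))
  out <- list()
  for (sp in sparsities) {
    dataset <- dataset_builder(sp)
    rep <- cross_task_cv(dataset, config, class_levels)
    for (f in rep$folds) {
      out[[length(out) + 1L]] <- data.frame(
        sparsity = sp, task = f$task, accuracy = f$metrics$accuracy
      )
    }
    out[[length(out) + 1L]] <- data.frame(
      sparsity = sp, task = "mean", accuracy = rep$accuracy
    )
  }
  do.call(rbind, out)
}

#' Band-masking ablation
#'
#' Zeroes the named band's snapshot (adjacency and features) in
#' every graph — train and test alike — and reruns the leave-one-
#' task-out cross-validation.
#'
#' @param dataset List of `discrete_graph`s.
#' @param band Band to mask, or a vector of bands.
#' @param config A [sgatcn_config()].
#' @param class_levels Workload level order.
#' @return An `eval_report` with the masked band recorded.
#' @export
band_masking <- function(dataset, band, config = sgatcn_config(),
                         class_levels = c("low", "medium", "high")) {
  known <- unique(unlist(lapply(dataset[[1]]$snapshots, `[[`, "band")))
  bad <- setdiff(band, known)
  if (length(bad)) stop("unknown band: ", paste(bad, collapse = ", "))
  masked <- lapply(dataset, function(dg) {
    for (b in band) dg <- mask_band(dg, b)
    dg
  })
  rep <- cross_task_cv(masked, config, class_levels)
  rep$masked_band <- band
  rep
}

#' Label-permutation null accuracy
#'
#' Shuffles training labels before fitting and reports cross-task
#' accuracy, which should sit at chance for balanced classes.
#'
#' @param dataset List of `discrete_graph`s.
#' @param config A [sgatcn_config()].
#' @param seed Permutation seed.
#' @param class_levels Workload level order.
#' @export
permutation_null_cv <- function(dataset, config = sgatcn_config(),
                                seed = 1L,
                                class_levels = c("low", "medium", "high")) {
  set.seed(seed)
  labels <- vapply(dataset, `[[`, character(1), "label")
  shuffled <- sample(labels)
  permuted <- Map(function(dg, lab) {
    dg$label <- lab
    dg
  }, dataset, shuffled)
  cross_task_cv(permuted, config, class_levels)
}
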