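#' Stratified nested cross-validation splits
#'
#' Outer k-fold (default 10) test sets partition all subjects,
#' stratified by diagnosis so per-fold class counts deviate from perfect
#' proportionality by at most one subject per class. Within each outer
#' fold the remaining ~90% is partitioned into `n_inner` (default 9)
#' stratified parts; inner split j uses part j as validation (~10% of the
#' total) and the rest as training (~80%), yielding the 80/10/10 layout
#' and exactly `n_inner` models per outer fold.
#'
#' @param labels Diagnosis vector (factor or character) for all subjects.
#' @param k Number of outer folds.
#' @param seed Integer seed; splits are deterministic given it.
#' @param n_inner Number of inner splits (rotations of an inner
#'   `n_inner`-fold partition).
#' @return A `nested_splits` object: list with `k`, `n_inner`, `seed` and
#'   `outer`, where `outer[[i]]` has `test` (indices) and `inner`
#'   (list of `list(train, val)` index pairs).
#' @export
make_nested_splits <- function(labels, k = 10, seed = 1L, n_inner = k - 1) {
  labels <- as.character(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs >= k subjects for stratified ", k,
         "-fold splits; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  # stratified assignment with balanced totals: every class spreads over
  # the folds with per-class deviation <= 1, and each class's remainder
  # subjects go to the currently least-loaded folds so overall fold sizes
  # also deviate by at most 1 where arithmetic allows
  stratified_assign <- function(lab, k) {
    fold_of <- integer(length(lab))
    load <- integer(k)
    for (cl in names(sort(table(lab), decreasing = TRUE))) {
      idx <- sample(which(lab == cl))
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      per_fold <- rep(base, k)
      if (rem > 0) {
        extra <- order(load + stats::runif(k))[seq_len(rem)]
        per_fold[extra] <- per_fold[extra] + 1L
      }
      fold_of[idx] <- rep(seq_len(k), times = per_fold)
      load <- load + per_fold
    }
    fold_of
  }
  with_seed(seed, {
    fold_of <- stratified_assign(labels, k)
    outer <- purrr::map(seq_len(k), function(i) {
      test <- which(fold_of == i)
      rest <- which(fold_of != i)
      inner_of <- stratified_assign(labels[rest], n_inner)
      inner <- purrr::map(seq_len(n_inner), function(j) {
        list(train = rest[inner_of != j], val = rest[inner_of == j])
      })
      list(test = test, inner = inner)
    })
    structure(list(k = as.integer(k), n_inner = as.integer(n_inner),
                   seed = as.integer(seed), outer = outer),
              class = "nested_splits")
  })
}

#' Probabilistic ensemble prediction
#'
#' Final fold predictions are the arithmetic mean of the inner-fold
#' members' softmax outputs; the label is the argmax with ties broken
#' toward the lower class index.
#'
#' @param ensemble A `trained_ensemble` (one outer fold's members plus
#'   their harmonization model) as produced by [run_nested_cv()].
#' @param data Feature table; transformed with the ensemble's own
#'   harmonization model unless already harmonized. A pre-extracted
#'   w-score matrix is also accepted.
#' @return Tibble with `subject_id`, per-class probability columns and
#'   `prediction`.
#' @export
ensemble_predict <- function(ensemble, data) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (length(ensemble$members) != ensemble$n_inner) {
    stop("ensemble must contain exactly ", ensemble$n_inner,
         " members, got ", length(ensemble$members), call. = FALSE)
  }
  if (is.matrix(data)) {
    X <- data
    ids <- rownames(data)
  } else {
    if (!is_harmonized(data)) {
      data <- transform_to_wscores(ensemble$harmonization, data)
    }
    X <- feature_matrix(data, ensemble$harmonization$schema)
    ids <- data$subject_id
  }
  probs <- Reduce(`+`, purrr::map(ensemble$members, function(m) {
    softmax_rows(net_forward(m, X)$logits)
  })) / length(ensemble$members)
  colnames(probs) <- DIAGNOSES
  pred <- factor(DIAGNOSES[max.col(probs, ties.method = "first")],
                 levels = DIAGNOSES)
  dplyr::bind_cols(tibble::tibble(subject_id = ids),
                   tibble::as_tibble(probs),
                   tibble::tibble(prediction = pred))
}

# train harmonization + the n_inner ensemble members of one outer fold;
# only non-test rows are ever touched (scope = "all" deliberately breaks
# this for the leakage audit's negative control)
train_outer_fold <- function(data, schema, config, opt, splits, fold_index,
                             seed = 1L, reference_group = "bvFTD",
                             covariates = c("age", "sex", "tiv",
                                            "cohort", "scanner_id"),
                             scope = c("train_only", "all")) {
  scope <- match.arg(scope)
  fold <- splits$outer[[fold_index]]
  non_test <- sort(unlist(purrr::map(fold$inner, "val")))
  harm_rows <- if (scope == "all") seq_len(nrow(data)) else non_test
  harm <- fit_harmonization(data[harm_rows, ], schema,
                            reference_group = reference_group,
                            covariates = covariates,
                            fold_id = paste0("outer_", fold_index))
  w_train <- transform_to_wscores(harm, data[non_test, ])
  Xw <- matrix(NA_real_, nrow(data), 735)
  Xw[non_test, ] <- feature_matrix(w_train, schema)
  y_all <- as.integer(data$diagnosis)
  members <- vector("list", splits$n_inner)
  for (j in seq_len(splits$n_inner)) {
    sp <- fold$inner[[j]]
    fit <- train_net(Xw[sp$train, , drop = FALSE], y_all[sp$train],
                     Xw[sp$val, , drop = FALSE], y_all[sp$val],
                     config, opt,
                     seed = child_seed(seed, fold_index, j))
    members[[j]] <- fit$model
    attr(members[[j]], "history") <- fit$history
    attr(members[[j]], "best_epoch") <- fit$best_epoch
  }
  structure(list(members = members, harmonization = harm,
                 config = config, n_inner = splits$n_inner,
                 fold = fold_index),
            class = "trained_ensemble")
}

#' Run the full nested cross-validation pipeline
#'
#' For each outer fold: fit the w-score harmonization on the fold's
#' non-test subjects only, transform everyone with it, train one network
#' per inner split (class-weighted loss, validation-checkpointed SGD), and
#' predict the held-out test subjects with the probabilistic ensemble of
#' the inner members. Test subjects never influence harmonization or
#' training (see [audit_leakage()]).
#'
#' @param data Raw feature table.
#' @param schema An [atlas_schema()].
#' @param config A [parallel_net_config()].
#' @param opt An [sgd_spec()].
#' @param splits Optional pre-built [make_nested_splits()]; built from
#'   `seed` otherwise.
#' @param seed Integer master seed (splits, initializations, batch order).
#' @param reference_group,covariates Passed to [fit_harmonization()].
#' @param keep_models Keep trained members (needed for attribution maps).
#' @return An `ftd_cv_result`: pooled confusion matrix, tidy `metrics`,
#'   per-fold metrics, per-subject `predictions`, and (optionally) the
#'   per-fold `trained_ensemble` objects.
#' @export
run_nested_cv <- function(data, schema = default_atlas_schema(),
                          config = parallel_net_config(),
                          opt = sgd_spec(), splits = NULL, seed = 1L,
                          reference_group = "bvFTD",
                          covariates = c("age", "sex", "tiv",
                                         "cohort", "scanner_id"),
                          keep_models = TRUE) {
  if (is.null(splits)) {
    splits <- make_nested_splits(data$diagnosis, k = 10,
                                 seed = child_seed(seed, 1L))
  }
  preds <- vector("list", splits$k)
  ensembles <- vector("list", splits$k)
  fold_metrics <- vector("list", splits$k)
  for (i in seq_len(splits$k)) {
    fold <- splits$outer[[i]]
    ensemble <- train_outer_fold(data, schema, config, opt, splits, i,
                                 seed = seed,
                                 reference_group = reference_group,
                                 covariates = covariates)
    w_test <- transform_to_wscores(ensemble$harmonization,
                                   data[fold$test, ])
    pr <- ensemble_predict(ensemble, w_test)
    pr$truth <- data$diagnosis[fold$test]
    pr$fold <- i
    preds[[i]] <- pr
    cm_fold <- confusion_matrix(pr$truth, pr$prediction)
    fold_metrics[[i]] <- dplyr::mutate(metrics_report(cm_fold), fold = i)
    ensembles[[i]] <- if (keep_models) ensemble else NULL
  }
  predictions <- dplyr::bind_rows(preds)
  confusion <- confusion_matrix(predictions$truth, predictions$prediction)
  structure(
    list(confusion = confusion,
         metrics = metrics_report(confusion),
         fold_metrics = dplyr::bind_rows(fold_metrics),
         predictions = predictions,
         ensembles = ensembles,
         splits = splits, config = config, opt = opt, seed = seed),
    class = "ftd_cv_result"
  )
}

#' @export
print.ftd_cv_result <- function(x, ...) {
  cat("<ftd_cv_result>", sum(x$confusion), "subjects,",
      x$splits$k, "outer folds\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.ftd_cv_result <- function(x, ...) x$metrics

#' @export
glance.ftd_cv_result <- function(x, ...) {
  tibble::tibble(
    n = sum(x$confusion),
    k_outer = x$splits$k,
    n_inner = x$splits$n_inner,
    overall_balanced_accuracy =
      x$metrics$balanced_accuracy[x$metrics$class == "overall"]
  )
}

#' Four-way architecture/feature ablation
#'
#' Runs, on identical outer splits, the four experiments of the model
#' comparison: volume-only input, thickness-only input, naive
#' concatenation of both types into a single MLP, and the two-level
#' parallel embedding model. Reports per-class and overall balanced
#' accuracy per experiment (pooled over outer folds) plus per-fold values
#' for dispersion plots.
#'
#' @param data Raw feature table.
#' @param schema An [atlas_schema()].
#' @param opt An [sgd_spec()] shared by all experiments.
#' @param seed Master seed; splits are shared across experiments.
#' @param k,n_inner Fold structure.
#' @param dropout Dropout rate for all configurations.
#' @return An `ftd_ablation`: list with `summary` (experiment x class BA
#'   tibble), `fold_values`, and the four `ftd_cv_result`s.
#' @export
run_ablation <- function(data, schema = default_atlas_schema(),
                         opt = sgd_spec(), seed = 1L, k = 10,
                         n_inner = k - 1, dropout = 0.2) {
  splits <- make_nested_splits(data$diagnosis, k = k,
                               seed = child_seed(seed, 1L),
                               n_inner = n_inner)
  experiments <- list(
    "volume" = volume_only_config(dropout = dropout),
    "thickness" = thickness_only_config(dropout = dropout),
    "thickness+volume (naive)" = naive_concat_config(dropout = dropout),
    "thickness+volume (multi-level)" = parallel_net_config(dropout = dropout)
  )
  results <- purrr::imap(experiments, function(cfg, nm) {
    run_nested_cv(data, schema, cfg, opt, splits = splits, seed = seed,
                  keep_models = FALSE)
  })
  summary <- purrr::imap_dfr(results, function(res, nm) {
    m <- res$metrics
    tibble::tibble(experiment = nm,
                   class = m$class,
                   balanced_accuracy = m$balanced_accuracy)
  })
  fold_values <- purrr::imap_dfr(results, function(res, nm) {
    dplyr::mutate(res$fold_metrics, experiment = nm)
  })
  structure(list(summary = summary, fold_values = fold_values,
                 results = results, seed = seed),
            class = "ftd_ablation")
}

#' @export
print.ftd_ablation <- function(x, ...) {
  cat("<ftd_ablation>\n")
  print(tidyr::pivot_wider(x$summary, names_from = "class",
                           values_from = "balanced_accuracy"))
  invisible(x)
}
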