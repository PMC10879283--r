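#' Multiclass confusion matrix
#'
#' @param truth,prediction Factors (or characters) over the diagnosis
#'   levels; rows of the result are truth, columns prediction.
#' @param levels Class levels; defaults to the three FTD subtypes.
#' @return Integer matrix, truth x prediction.
#' @export
confusion_matrix <- function(truth, prediction, levels = DIAGNOSES) {
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(prediction), levels = levels)
  unclass(table(truth = t_f, prediction = p_f))
}

#' Balanced accuracy from a confusion matrix
#'
#' One-vs-rest: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), and
#' balanced accuracy their mean. `overall_balanced_accuracy()` averages the
#' per-class balanced accuracies over all classes.
#'
#' @param confusion Square confusion matrix, truth x prediction.
#' @param class Class name or index to evaluate one-vs-rest.
#' @return A value in \[0, 1\].
#' @examples
#' cm <- matrix(c(2, 1, 0, 0, 1, 0, 0, 0, 1), 3,
#'              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' balanced_accuracy(cm, "b")          # 5/6
#' overall_balanced_accuracy(diag(3))  # 1
#' @export
balanced_accuracy <- function(confusion, class) {
  k <- if (is.character(class)) match(class, rownames(confusion)) else class
  tp <- confusion[k, k]
  fn <- sum(confusion[k, ]) - tp
  fp <- sum(confusion[, k]) - tp
  tn <- sum(confusion) - tp - fn - fp
  if (tp + fn == 0) stop("no subjects of the evaluated class", call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  (sens + spec) / 2
}

#' @rdname balanced_accuracy
#' @export
overall_balanced_accuracy <- function(confusion) {
  mean(vapply(seq_len(nrow(confusion)),
              function(k) balanced_accuracy(confusion, k), numeric(1)))
}

#' Tidy per-class metrics report
#'
#' @param confusion Square confusion matrix, truth x prediction.
#' @return Tibble with one row per class (`sensitivity`, `specificity`,
#'   `balanced_accuracy`) plus an `overall` row.
#' @export
metrics_report <- function(confusion) {
  classes <- rownames(confusion)
  per <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- sum(confusion) - tp - fn - fp
    tibble::tibble(class = classes[k],
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2)
  })
  dplyr::bind_rows(per,
                   tibble::tibble(class = "overall",
                                  sensitivity = NA_real_,
                                  specificity = NA_real_,
                                  balanced_accuracy =
                                    mean(per$balanced_accuracy)))
}
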