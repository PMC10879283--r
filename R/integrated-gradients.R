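#' Integrated Gradients along a straight-line path
#'
#' Path-integral attribution: for a scalar score \eqn{F} and baseline
#' \eqn{x'},
#' \deqn{IG_i(x) = (x_i - x'_i)\int_0^1
#'   \partial F\big(x' + \alpha (x - x')\big)/\partial x_i \, d\alpha,}
#' approximated with a midpoint Riemann sum over `steps` points. The
#' attributions satisfy the completeness axiom: their sum converges to
#' \eqn{F(x) - F(x')} as `steps` grows, and is exact for linear \eqn{F} at
#' any step count.
#'
#' @param grad_fn Function mapping a matrix of input rows to the matrix of
#'   gradients of the scalar score at those rows (same shape).
#' @param x Numeric input vector.
#' @param baseline Numeric baseline vector (default all-zero).
#' @param steps Number of midpoint quadrature steps (>= 1).
#' @return Signed attribution vector, same length as `x`.
#' @examples
#' # linear score F(x) = w.x : attribution is exactly w * x
#' w <- c(1, -2, 3)
#' ig <- integrated_gradients(function(X) matrix(w, nrow(X), 3, byrow = TRUE),
#'                            x = c(4, 5, 6), steps = 8)
#' all.equal(ig, w * c(4, 5, 6))
#' @export
integrated_gradients <- function(grad_fn, x, baseline = rep(0, length(x)),
                                 steps = 128L) {
  stopifnot(length(x) == length(baseline), steps >= 1)
  alphas <- (seq_len(steps) - 0.5) / steps
  diff <- x - baseline
  path <- outer(alphas, diff) +
    matrix(baseline, steps, length(x), byrow = TRUE)
  G <- grad_fn(path)
  if (any(!is.finite(G))) stop("non-finite gradient on path", call. = FALSE)
  diff * colMeans(G)
}

# gradient of the target-class pre-softmax logit wrt inputs, batched
logit_input_gradient <- function(model, X, class_index) {
  fwd <- net_forward(model, X)
  d_logits <- matrix(0, nrow(X), ncol(fwd$logits))
  d_logits[, class_index] <- 1
  net_backward(model, fwd, d_logits)$d_input
}

#' Integrated-Gradient attributions for subjects under one network
#'
#' Attributes the pre-softmax logit of `target_class` relative to an
#' all-zero w-score baseline (the covariate-adjusted reference-group mean,
#' i.e. "no deviation from the bvFTD-referenced norm").
#'
#' @param model An `ftdnet_model`.
#' @param X W-score matrix (subjects x 735) or harmonized feature table.
#' @param target_class Diagnosis name or class index to attribute.
#' @param baseline Baseline vector; all-zero by default.
#' @param steps Quadrature steps (default 128).
#' @param schema Schema for column extraction when `X` is a tibble.
#' @return Matrix of signed attributions, subjects x 735.
#' @export
ig_attribute <- function(model, X, target_class, baseline = NULL,
                         steps = 128L, schema = default_atlas_schema()) {
  if (!is.matrix(X)) X <- feature_matrix(X, schema)
  k <- if (is.character(target_class)) match(target_class, DIAGNOSES) else
    as.integer(target_class)
  if (is.null(baseline)) baseline <- rep(0, ncol(X))
  n <- nrow(X)
  p <- ncol(X)
  out <- matrix(0, n, p, dimnames = dimnames(X))
  alphas <- (seq_len(steps) - 0.5) / steps
  # batch the n x steps path points through the network in chunks
  chunk <- max(1L, 16384L %/% steps)
  for (s in seq(1, n, by = chunk)) {
    rows <- s:min(s + chunk - 1, n)
    idx <- rep(rows, each = steps)
    D <- X[idx, , drop = FALSE] -
      matrix(baseline, length(idx), p, byrow = TRUE)
    P <- D * rep(alphas, length(rows)) +
      matrix(baseline, length(idx), p, byrow = TRUE)
    G <- logit_input_gradient(model, P, k)
    if (any(!is.finite(G))) stop("non-finite gradient on path",
                                 call. = FALSE)
    mean_g <- rowsum(G, group = idx, reorder = TRUE) / steps
    out[rows, ] <- (X[rows, , drop = FALSE] -
                      matrix(baseline, length(rows), p, byrow = TRUE)) *
      mean_g
  }
  out
}

#' Population-mean feature-importance map for one subtype
#'
#' Mean Integrated-Gradient attribution, toward the subtype's own logit,
#' over all subjects of that subtype, averaged over the ensemble members;
#' positive values mark features whose increase pushes the model toward
#' the subtype, negative values the reverse.
#'
#' @param ensemble A `trained_ensemble` from [run_nested_cv()].
#' @param data Feature table (transformed with the ensemble's
#'   harmonization model if not already harmonized).
#' @param subtype Diagnosis whose map to compute.
#' @param steps IG quadrature steps.
#' @param schema An [atlas_schema()].
#' @return Tibble with one row per feature: `feature`, `label`, `block`
#'   (`thickness`/`cortical_volume`/`subcortical_volume`), `index`,
#'   `subtype`, `importance` (signed mean attribution).
#' @export
population_importance_map <- function(ensemble, data, subtype,
                                      steps = 128L,
                                      schema = default_atlas_schema()) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (!is.matrix(data) && !is_harmonized(data)) {
    data <- transform_to_wscores(ensemble$harmonization, data)
  }
  rows <- which(as.character(data$diagnosis) == subtype)
  if (!length(rows)) stop("no subjects with diagnosis ", subtype,
                          call. = FALSE)
  X <- feature_matrix(data[rows, ], schema)
  acc <- matrix(0, length(rows), ncol(X))
  for (m in ensemble$members) {
    acc <- acc + ig_attribute(m, X, subtype, steps = steps, schema = schema)
  }
  mean_attr <- colMeans(acc / length(ensemble$members))
  fn <- feature_names(schema)
  blocks <- feature_blocks(schema)
  block_of <- character(735)
  block_of[blocks$thickness] <- "thickness"
  block_of[blocks$cortical_volume] <- "cortical_volume"
  block_of[blocks$subcortical_volume] <- "subcortical_volume"
  tibble::tibble(
    feature = fn,
    label = sub("^(thk|cvol|svol)_", "", fn),
    block = block_of,
    index = seq_along(fn),
    subtype = subtype,
    importance = unname(mean_attr)
  )
}

#' Export per-patch importance tables to CSV
#'
#' One row per atlas label per feature type with the signed mean
#' attribution, suitable for external cortical-surface rendering. The
#' conventional symmetric display range for such maps is +/- max
#' absolute importance (typical published maps use about +/- 0.06).
#'
#' @param maps Tibble(s) from [population_importance_map()] (rows may
#'   cover several subtypes).
#' @param path Output CSV path.
#' @return The combined tibble, invisibly.
#' @export
export_importance_tables <- function(maps, path) {
  maps <- dplyr::bind_rows(maps)
  readr::write_csv(maps, path)
  invisible(maps)
}
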