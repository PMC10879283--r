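#' GLM-based w-score harmonization
#'
#' Multi-cohort morphometry carries confounds (cohort, scanner, sex, TIV)
#' that bias downstream modeling. The w-score harmonization fits, per
#' feature, an ordinary-least-squares model of the feature on the
#' confounds using only subjects of a designated reference diagnostic group
#' (bvFTD by default), then expresses every subject's value as a
#' standardized residual from that normative fit:
#' \deqn{w_{if} = (x_{if} - d_i^\top \beta_f) / \sigma_f}
#' where \eqn{d_i} is the subject's design row and \eqn{\sigma_f} the
#' reference-group residual SD with an \eqn{n_{ref} - p} denominator.
#' Fitting and transforming are strictly separated so that
#' cross-validation folds never leak: [transform_to_wscores()] re-estimates
#' nothing.
#'
#' Categorical covariates are dummy-encoded against a fixed reference
#' level. Scanner is treated as a combined cohort-by-scanner factor; when
#' both `cohort` and `scanner_id` are requested the nested scanner factor
#' subsumes the cohort term (keeping both would make the design exactly
#' collinear), so cohort effects are still removed.
#'
#' @param data Raw feature table (tibble) containing the training fold.
#' @param schema An [atlas_schema()].
#' @param reference_group Diagnosis used as normative reference.
#' @param covariates Metadata columns to regress out. Numeric columns enter
#'   linearly; character/factor columns are dummy-encoded.
#' @param fold_id Optional label recorded on the model (bookkeeping for
#'   cross-validation).
#' @return A `wscore_model` with per-feature coefficients `beta`
#'   (terms x 735), residual SDs `sigma`, the covariate spec with stored
#'   factor levels, and the reference group.
#' @export
fit_harmonization <- function(data, schema = default_atlas_schema(),
                              reference_group = "bvFTD",
                              covariates = c("age", "sex", "tiv",
                                             "cohort", "scanner_id"),
                              fold_id = NA_character_) {
  stopifnot(reference_group %in% DIAGNOSES)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariates absent from table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if ("scanner_id" %in% covariates && "cohort" %in% covariates) {
    covariates <- setdiff(covariates, "cohort")
  }
  ref_rows <- which(as.character(data$diagnosis) == reference_group)
  # categorical levels come from the reference rows the GLM is fit on; a
  # level with no reference subjects would yield an all-zero dummy (rank
  # deficiency), so such levels fall under the unseen-level rule instead
  spec <- make_covariate_spec(data[ref_rows, ], covariates)
  X <- build_design(data[ref_rows, ], spec, warn_unseen = FALSE)
  p <- ncol(X)
  if (length(ref_rows) < p + 2) {
    stop("need at least ", p + 2, " reference-group (", reference_group,
         ") subjects for a ", p, "-column design; got ", length(ref_rows),
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient harmonization design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- feature_matrix(data[ref_rows, ], schema)
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  sigma <- sqrt(colSums(res^2) / (length(ref_rows) - p))
  degen <- which(sigma <= .Machine$double.eps^0.5)
  if (length(degen)) {
    stop("degenerate features with zero reference residual variance: ",
         paste(utils::head(names(degen), 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(spec = spec, beta = beta, sigma = sigma,
         reference_group = reference_group,
         n_reference = length(ref_rows),
         feature_names = feature_names(schema),
         schema = schema, fold_id = fold_id),
    class = "wscore_model"
  )
}

make_covariate_spec <- function(data, covariates) {
  levels_map <- list()
  for (cv in covariates) {
    col <- data[[cv]]
    if (is.character(col) || is.factor(col)) {
      lv <- if (is.factor(col)) levels(droplevels(col)) else sort(unique(col))
      levels_map[[cv]] <- lv
    }
  }
  list(covariates = covariates, levels = levels_map)
}

build_design <- function(data, spec, warn_unseen = TRUE) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (cv in spec$covariates) {
    col <- data[[cv]]
    if (is.null(col)) stop("missing covariate: ", cv, call. = FALSE)
    if (cv %in% names(spec$levels)) {
      lv <- spec$levels[[cv]]
      val <- as.character(col)
      unseen <- setdiff(unique(val), lv)
      if (length(unseen)) {
        if (warn_unseen) {
          warning("unseen ", cv, " level(s) mapped to reference '",
                  lv[1], "': ", paste(unseen, collapse = ", "),
                  call. = FALSE)
        }
        val[val %in% unseen] <- lv[1]
      }
      for (l in lv[-1]) cols[[paste0(cv, l)]] <- as.numeric(val == l)
    } else {
      if (!is.numeric(col)) stop("covariate ", cv, " must be numeric",
                                 call. = FALSE)
      if (anyNA(col)) stop("missing values in covariate ", cv, call. = FALSE)
      cols[[cv]] <- as.numeric(col)
    }
  }
  do.call(cbind, cols)
}

#' Transform a feature table to w-scores with a fitted harmonization model
#'
#' Applies a [fit_harmonization()] model to any table (all diagnoses,
#' including held-out folds): no parameter is re-estimated here. Unseen
#' categorical levels (e.g. a scanner absent from the training fold) are
#' mapped to the reference level with a warning.
#'
#' @param model A `wscore_model`.
#' @param data Feature table providing all covariates in the model spec.
#' @return A tibble with identical metadata and the 735 feature columns
#'   replaced by w-scores; flagged harmonized (see [is_harmonized()]).
#' @export
transform_to_wscores <- function(model, data) {
  stopifnot(inherits(model, "wscore_model"))
  X <- build_design(data, model$spec)
  Y <- feature_matrix(data, model$schema)
  W <- (Y - X %*% model$beta) / matrix(rep(model$sigma, each = nrow(Y)),
                                       nrow(Y))
  out <- data
  out[, model$feature_names] <- tibble::as_tibble(W)
  as_feature_tibble(out, harmonized = TRUE)
}

#' @export
print.wscore_model <- function(x, ...) {
  cat("<wscore_model> reference:", x$reference_group,
      "| n_ref:", x$n_reference,
      "| design columns:", nrow(x$beta),
      "| features:", length(x$sigma), "\n")
  invisible(x)
}

#' Tidy a w-score harmonization model
#'
#' @param x A `wscore_model`.
#' @param ... Unused.
#' @return Long tibble: `feature`, `term`, `estimate`, plus per-feature
#'   `sigma` on intercept rows omitted — sigma is reported by `glance()`.
#' @export
tidy.wscore_model <- function(x, ...) {
  beta <- x$beta
  tibble::tibble(
    feature = rep(colnames(beta), each = nrow(beta)),
    term = rep(rownames(beta), times = ncol(beta)),
    estimate = as.vector(beta)
  )
}

#' @rdname tidy.wscore_model
#' @export
glance.wscore_model <- function(x, ...) {
  tibble::tibble(
    reference_group = x$reference_group,
    n_reference = x$n_reference,
    n_terms = nrow(x$beta),
    n_features = length(x$sigma),
    sigma_median = stats::median(x$sigma)
  )
}

#' Serialize / restore a harmonization model as JSON
#'
#' @param model A `wscore_model`.
#' @param path JSON file path.
#' @return `write_wscore_model()` returns `path` invisibly;
#'   `read_wscore_model()` the restored model.
#' @export
write_wscore_model <- function(model, path) {
  stopifnot(inherits(model, "wscore_model"))
  payload <- list(
    spec = model$spec,
    beta = list(terms = rownames(model$beta),
                features = colnames(model$beta),
                values = as.vector(model$beta)),
    sigma = unname(model$sigma),
    reference_group = model$reference_group,
    n_reference = model$n_reference,
    fold_id = model$fold_id,
    schema = unclass(model$schema)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wscore_model
#' @export
read_wscore_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- matrix(x$beta$values, nrow = length(x$beta$terms),
                 dimnames = list(x$beta$terms, x$beta$features))
  schema <- atlas_schema(x$schema$cortical_labels, x$schema$subcortical_labels)
  sigma <- stats::setNames(x$sigma, x$beta$features)
  structure(
    list(spec = list(covariates = x$spec$covariates,
                     levels = as.list(x$spec$levels)),
         beta = beta, sigma = sigma,
         reference_group = x$reference_group,
         n_reference = x$n_reference,
         feature_names = feature_names(schema),
         schema = schema, fold_id = x$fold_id),
    class = "wscore_model"
  )
}
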