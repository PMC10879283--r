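#' Patch-wise group-contrast linear models
#'
#' Classical mass-univariate counterpart of the attribution maps: per
#' feature, OLS of the feature on an indicator of the contrasted subtype
#' (vs. all other groups) plus covariates (age, sex, education by
#' default), with a two-sided t test on the indicator coefficient and
#' Benjamini-Hochberg FDR control at `q` over each feature-type family
#' (the 15 subcortical tests share the volume family with the 360
#' cortical-volume tests).
#'
#' Contrasts run on whatever the supplied table holds; pass harmonized
#' w-scores to match what the classifier sees, or a raw table for
#' unadjusted effects.
#'
#' @param data Feature table.
#' @param schema An [atlas_schema()].
#' @param subtype Diagnosis contrasted against the rest.
#' @param covariates Metadata columns adjusted for.
#' @param q FDR level.
#' @return A `stat_map` tibble: per feature `estimate` (subtype-vs-rest
#'   coefficient), `statistic`, `p.value`, `q.value`, `significant`, plus
#'   `label`, `block`, `family`.
#' @export
patchwise_group_contrast <- function(data, schema = default_atlas_schema(),
                                     subtype = "bvFTD",
                                     covariates = c("age", "sex",
                                                    "education"),
                                     q = 0.05) {
  stopifnot(subtype %in% DIAGNOSES)
  grp <- as.numeric(as.character(data$diagnosis) == subtype)
  if (sum(grp) < 2 || sum(1 - grp) < 2) {
    stop("need >= 2 subjects inside and outside ", subtype, call. = FALSE)
  }
  spec <- make_covariate_spec(data, covariates)
  X <- cbind(build_design(data, spec, warn_unseen = FALSE),
             group = grp)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("collinear contrast design; columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  }
  Y <- feature_matrix(data, schema)
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
  tstat <- beta["group", ] / se
  pval <- 2 * stats::pt(-abs(tstat), df)

  fn <- feature_names(schema)
  blocks <- feature_blocks(schema)
  block_of <- character(735)
  block_of[blocks$thickness] <- "thickness"
  block_of[blocks$cortical_volume] <- "cortical_volume"
  block_of[blocks$subcortical_volume] <- "subcortical_volume"
  family <- ifelse(block_of == "thickness", "thickness", "volume")
  out <- tibble::tibble(
    feature = fn,
    label = sub("^(thk|cvol|svol)_", "", fn),
    block = block_of,
    family = family,
    index = seq_along(fn),
    subtype = subtype,
    estimate = unname(beta["group", ]),
    statistic = unname(tstat),
    p.value = unname(pval)
  )
  out <- dplyr::group_by(out, .data$family)
  out <- dplyr::mutate(out,
                       q.value = bh_fdr(.data$p.value, q = q)$q.value,
                       significant = bh_fdr(.data$p.value, q = q)$significant)
  out <- dplyr::ungroup(out)
  class(out) <- c("stat_map", class(out))
  out
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Adjusted q-values via the standard step-up procedure; rejection iff the
#' sorted \eqn{p_{(i)} \le (i/m)\,q} for the largest such i (equivalently,
#' q-value <= q).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return Tibble with `p.value`, `q.value`, `significant` in input order.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.03, 0.5))  # 4 rejections at q = 0.05
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p.value = p_values, q.value = qv, significant = qv <= q)
}
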