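#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

DIAGNOSES <- c("bvFTD", "nfvPPA", "svPPA")
METADATA_COLS <- c("subject_id", "diagnosis", "age", "sex", "education",
                   "tiv", "cohort", "scanner_id")

#' @export
generics::tidy

#' @export
generics::glance

as_feature_tibble <- function(data, harmonized = FALSE) {
  data <- tibble::as_tibble(data)
  data$diagnosis <- factor(as.character(data$diagnosis), levels = DIAGNOSES)
  data$sex <- factor(as.character(data$sex), levels = c("M", "F"))
  attr(data, "harmonized") <- harmonized
  data
}

#' Is a feature table harmonized (w-score valued)?
#'
#' @param data A feature table tibble.
#' @return `TRUE` if the table carries the harmonized flag set by
#'   [transform_to_wscores()].
#' @export
is_harmonized <- function(data) {
  isTRUE(attr(data, "harmonized"))
}

feature_matrix <- function(data, schema, block = NULL) {
  cols <- feature_names(schema)
  if (!is.null(block)) cols <- cols[feature_blocks(schema)[[block]]]
  m <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- data$subject_id
  m
}

#' Load a feature table from feature + metadata CSV files
#'
#' The on-disk dialect is UTF-8 CSV with header. The features file has a
#' `subject_id` column plus the 735 feature columns named
#' `thk_<label>` / `cvol_<label>` / `svol_<label>` against the schema's
#' label registry; the metadata file is keyed by `subject_id` and supplies
#' diagnosis, age, sex, education, TIV, cohort and scanner.
#'
#' @param features_path,metadata_path CSV file paths.
#' @param schema An [atlas_schema()]; defaults to [default_atlas_schema()].
#' @return A tibble with metadata columns followed by the 735 feature
#'   columns in schema order, one row per subject, joined by `subject_id`.
#' @export
load_feature_table <- function(features_path, metadata_path,
                               schema = default_atlas_schema()) {
  feats <- readr::read_csv(features_path, show_col_types = FALSE,
                           progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  expected <- feature_names(schema)
  have <- setdiff(names(feats), "subject_id")
  missing <- setdiff(expected, have)
  extra <- setdiff(have, expected)
  if (length(missing) || length(extra)) {
    stop("feature columns do not match the 735-feature schema; missing: [",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "",
         "] (", length(missing), "), unexpected: [",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ..." else "",
         "] (", length(extra), ")", call. = FALSE)
  }
  missing_meta <- setdiff(METADATA_COLS, names(meta))
  if (length(missing_meta)) {
    stop("metadata file lacks required columns: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  bad <- expected[!vapply(feats[expected], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature columns: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(meta$subject_id, feats$subject_id)
  unmatched2 <- setdiff(feats$subject_id, meta$subject_id)
  if (length(unmatched) || length(unmatched2)) {
    stop("subject_id mismatch between metadata and features; ",
         "in metadata only: [", paste(unmatched, collapse = ", "),
         "], in features only: [", paste(unmatched2, collapse = ", "), "]",
         call. = FALSE)
  }
  out <- dplyr::inner_join(meta[, METADATA_COLS],
                           feats[, c("subject_id", expected)],
                           by = "subject_id")
  as_feature_tibble(out)
}

#' Write a feature table to feature + metadata CSV files
#'
#' Inverse of [load_feature_table()]; round-trips losslessly at full
#' double precision.
#'
#' @param data Feature table tibble.
#' @param features_path,metadata_path Output CSV paths.
#' @param schema The `atlas_schema` the table is bound to.
#' @return `data`, invisibly.
#' @export
write_feature_table <- function(data, features_path, metadata_path,
                                schema = default_atlas_schema()) {
  cols <- feature_names(schema)
  readr::write_csv(data[, c("subject_id", cols)], features_path)
  readr::write_csv(data[, METADATA_COLS], metadata_path)
  invisible(data)
}

#' Validate a feature table against its invariants
#'
#' Checks the table-level contract: all 735 feature columns present and
#' finite, unique subject ids, positive age and TIV, diagnosis within the
#' three-class set, and (for raw, pre-harmonization tables) strictly
#' positive thickness. Violations are reported, not repaired; missing
#' values are rejected rather than imputed.
#'
#' @param data Feature table tibble.
#' @param schema An `atlas_schema`.
#' @return A tibble of violations with columns `rule`, `subject_id`,
#'   `detail`; zero rows iff the table passes.
#' @export
validate_table <- function(data, schema = default_atlas_schema()) {
  cols <- feature_names(schema)
  v <- list()
  add <- function(rule, subject_id, detail) {
    tibble::tibble(rule = rule, subject_id = as.character(subject_id),
                   detail = detail)
  }
  missing_cols <- setdiff(c(METADATA_COLS, cols), names(data))
  if (length(missing_cols)) {
    return(add("missing_column", NA_character_,
               paste(utils::head(missing_cols, 10), collapse = ", ")))
  }
  dup <- unique(data$subject_id[duplicated(data$subject_id)])
  for (id in dup) v[[length(v) + 1L]] <- add("duplicate_subject_id", id, "")
  bad_dx <- is.na(data$diagnosis)
  if (any(bad_dx)) {
    v[[length(v) + 1L]] <- add("invalid_diagnosis",
                               data$subject_id[bad_dx],
                               "diagnosis not in {bvFTD, nfvPPA, svPPA}")
  }
  for (col in c("age", "tiv")) {
    bad <- !is.finite(data[[col]]) | data[[col]] <= 0
    if (any(bad)) {
      v[[length(v) + 1L]] <- add(paste0("nonpositive_", col),
                                 data$subject_id[bad], col)
    }
  }
  fm <- feature_matrix(data, schema)
  nf <- which(!is.finite(fm), arr.ind = TRUE)
  if (nrow(nf)) {
    v[[length(v) + 1L]] <- add("missing_value",
                               data$subject_id[nf[, 1]],
                               cols[nf[, 2]])
  }
  if (!is_harmonized(data)) {
    thk <- fm[, feature_blocks(schema)$thickness, drop = FALSE]
    np <- which(is.finite(thk) & thk <= 0, arr.ind = TRUE)
    if (nrow(np)) {
      v[[length(v) + 1L]] <- add("nonpositive_thickness",
                                 data$subject_id[np[, 1]],
                                 cols[np[, 2]])
    }
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), subject_id = character(),
                   detail = character())
}
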