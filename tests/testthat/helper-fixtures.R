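# small synthetic cohort shared across test files (computed once per run)
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(simulation_config(
        n_per_class = c(bvFTD = 30, nfvPPA = 18, svPPA = 15),
        n_scanners_per_cohort = 2, seed = 11))
    }
    cache
  }
})

# hand-built feature table with fully controlled feature values; metadata
# filled with innocuous defaults
manual_table <- function(X, diagnosis,
                         schema = default_atlas_schema(),
                         cohort = NULL, scanner = NULL) {
  n <- nrow(X)
  colnames(X) <- feature_names(schema)
  meta <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    diagnosis = diagnosis,
    age = seq(55, 75, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    education = rep(16, n),
    tiv = seq(1.3e6, 1.6e6, length.out = n),
    cohort = cohort %||% rep("cohort1", n),
    scanner_id = scanner %||% rep("cohort1_scn1", n)
  )
  out <- dplyr::bind_cols(meta, tibble::as_tibble(X))
  ftdnet:::as_feature_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_features <- function(n, seed = 1, sd = 1, mean = 0) {
  set.seed(seed)
  matrix(rnorm(n * 735, mean, sd), n, 735)
}

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)
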