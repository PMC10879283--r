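#' Run configuration for the end-to-end pipeline
#'
#' Bundles all stage parameters with their defaults (SGD with learning
#' rate 1e-3 and L2 weight decay 1e-5; 10-fold nested CV; 128-step
#' Integrated Gradients; FDR 0.05) into one serializable object whose
#' hash is recorded in every output.
#'
#' @param sim A [simulation_config()] (or `NULL` to load data instead).
#' @param net A [parallel_net_config()].
#' @param opt An [sgd_spec()].
#' @param k_outer,n_inner Nested-CV fold structure.
#' @param ig_steps Integrated-Gradient quadrature steps.
#' @param fdr FDR level for the statistical maps.
#' @param ablation Run the four-way ablation too?
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = simulation_config(),
                       net = parallel_net_config(),
                       opt = sgd_spec(),
                       k_outer = 10, n_inner = k_outer - 1,
                       ig_steps = 128L, fdr = 0.05,
                       ablation = FALSE, seed = 1L) {
  structure(list(sim = sim, net = net, opt = opt,
                 k_outer = as.integer(k_outer),
                 n_inner = as.integer(n_inner),
                 ig_steps = as.integer(ig_steps), fdr = fdr,
                 ablation = ablation, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Execute the full pipeline into a run directory
#'
#' simulate -> per-fold harmonize -> nested-CV train -> evaluate ->
#' (optional) ablation -> Integrated-Gradient maps -> statistical maps.
#' All stages derive their seeds from `config$seed`; a manifest with the
#' seeds and the config hash is written alongside the outputs, and two
#' runs with identical configs produce identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param data Optional pre-loaded feature table; simulated from
#'   `config$sim` when `NULL`.
#' @param schema An [atlas_schema()].
#' @return Invisibly, a list with the main results (`cv`, `importance`,
#'   `statmaps`, optionally `ablation`) and `out_dir`.
#' @export
run_full_pipeline <- function(config, out_dir, data = NULL,
                              schema = default_atlas_schema()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(data)) {
    sim <- generate_cohort(config$sim, schema)
    data <- sim$data
    truth <- sim$truth
    write_feature_table(data, file.path(out_dir, "features.csv"),
                        file.path(out_dir, "metadata.csv"), schema)
    jsonlite::write_json(
      list(planted = truth$planted,
           config = unclass(config$sim)),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  splits <- make_nested_splits(data$diagnosis, k = config$k_outer,
                               seed = child_seed(config$seed, 1L),
                               n_inner = config$n_inner)
  cv <- run_nested_cv(data, schema, config$net, config$opt,
                      splits = splits, seed = config$seed)
  readr::write_csv(cv$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(cv$fold_metrics, file.path(out_dir, "fold_metrics.csv"))
  readr::write_csv(tibble::as_tibble(cv$confusion, rownames = "truth"),
                   file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(
    list(metrics = cv$metrics,
         overall_balanced_accuracy =
           cv$metrics$balanced_accuracy[cv$metrics$class == "overall"]),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  ablation <- NULL
  if (isTRUE(config$ablation)) {
    ablation <- run_ablation(data, schema, config$opt, seed = config$seed,
                             k = config$k_outer, n_inner = config$n_inner)
    readr::write_csv(
      tidyr::pivot_wider(ablation$summary, names_from = "class",
                         values_from = "balanced_accuracy"),
      file.path(out_dir, "ablation.csv"))
  }

  maps <- purrr::map_dfr(DIAGNOSES, function(dx) {
    population_importance_map(cv$ensembles[[1]], data, dx,
                              steps = config$ig_steps, schema = schema)
  })
  export_importance_tables(maps, file.path(out_dir, "importance.csv"))

  harm <- cv$ensembles[[1]]$harmonization
  wdata <- transform_to_wscores(harm, data)
  statmaps <- purrr::map_dfr(DIAGNOSES, function(dx) {
    patchwise_group_contrast(wdata, schema, dx, q = config$fdr)
  })
  readr::write_csv(statmaps, file.path(out_dir, "statmap.csv"))

  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         k_outer = config$k_outer, n_inner = config$n_inner,
         stage_seeds = list(splits = child_seed(config$seed, 1L))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(list(cv = cv, ablation = ablation, importance = maps,
                 statmaps = statmaps, truth = truth, out_dir = out_dir))
}

#' Audit the pipeline for train/test leakage
#'
#' Re-trains one outer fold twice — once on the original table and once
#' with the fold's held-out test subjects' features grossly perturbed —
#' and passes iff the harmonization coefficients and every trained
#' parameter are bit-identical, proving that test subjects influence
#' neither harmonization nor training. `scope = "all"` deliberately fits
#' the harmonization on all subjects as a negative control, which must
#' fail.
#'
#' @param data Raw feature table.
#' @param schema An [atlas_schema()].
#' @param config A [parallel_net_config()].
#' @param opt An [sgd_spec()].
#' @param seed Master seed (same semantics as [run_nested_cv()]).
#' @param fold_index Outer fold to audit.
#' @param k,n_inner Fold structure.
#' @param scope `"train_only"` (the compliant pipeline) or `"all"`
#'   (negative control).
#' @return A list: `pass`, `perturbed_subjects`, `harmonization_identical`,
#'   `parameters_identical`.
#' @export
audit_leakage <- function(data, schema = default_atlas_schema(),
                          config = parallel_net_config(),
                          opt = sgd_spec(), seed = 1L, fold_index = 1,
                          k = 10, n_inner = k - 1,
                          scope = c("train_only", "all")) {
  scope <- match.arg(scope)
  splits <- make_nested_splits(data$diagnosis, k = k,
                               seed = child_seed(seed, 1L),
                               n_inner = n_inner)
  test_rows <- splits$outer[[fold_index]]$test
  fit1 <- train_outer_fold(data, schema, config, opt, splits, fold_index,
                           seed = seed, scope = scope)
  perturbed <- data
  fcols <- feature_names(schema)
  perturbed[test_rows, fcols] <- perturbed[test_rows, fcols] * 3 + 1000
  fit2 <- train_outer_fold(perturbed, schema, config, opt, splits,
                           fold_index, seed = seed, scope = scope)
  harm_same <- identical(fit1$harmonization$beta, fit2$harmonization$beta) &&
    identical(fit1$harmonization$sigma, fit2$harmonization$sigma)
  strip <- function(members) purrr::map(members, model_params)
  params_same <- identical(strip(fit1$members), strip(fit2$members))
  list(pass = harm_same && params_same,
       perturbed_subjects = data$subject_id[test_rows],
       harmonization_identical = harm_same,
       parameters_identical = params_same)
}
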