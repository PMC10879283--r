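test_that("linear scores attribute exactly w_i * x_i at any step count", {
  w <- c(1.5, -2, 0.5, 0)
  grad_fn <- function(P) matrix(w, nrow(P), length(w), byrow = TRUE)
  x <- c(4, 5, -6, 7)
  for (steps in c(1, 3, 64)) {
    expect_equal(integrated_gradients(grad_fn, x, steps = steps), w * x,
                 tolerance = 1e-12)
  }
  # non-zero baseline: attribution is w * (x - baseline)
  b <- c(1, 1, 1, 1)
  expect_equal(integrated_gradients(grad_fn, x, baseline = b, steps = 4),
               w * (x - b), tolerance = 1e-12)
})

test_that("input equal to baseline receives zero attribution", {
  grad_fn <- function(P) 2 * P  # F(x) = sum(x^2)
  x <- c(0.3, -0.3)
  expect_equal(integrated_gradients(grad_fn, x, baseline = x, steps = 16),
               c(0, 0))
})

test_that("quadratic score integrates to the analytic x^2", {
  # F(x) = x^2 scalar: IG = x * int_0^1 2 a x da = x^2
  grad_fn <- function(P) 2 * P
  x <- 1.7
  expect_equal(integrated_gradients(grad_fn, x, baseline = 0, steps = 256),
               x^2, tolerance = 1e-4)
})

test_that("completeness holds on a real network at 256 steps", {
  model <- build_model(parallel_net_config(seed = 33))
  X <- rand_features(3, seed = 34)
  for (k in 1:3) {
    att <- ig_attribute(model, X, k, steps = 256)
    f_x <- ftdnet:::net_forward(model, X)$logits[, k]
    f_0 <- ftdnet:::net_forward(model, matrix(0, 1, 735))$logits[, k]
    gap <- f_x - f_0
    expect_true(all(abs(rowSums(att) - gap) < 0.01 * pmax(abs(gap), 1e-8)))
  }
})

test_that("attributions ignore a constant added to all logits", {
  model <- build_model(parallel_net_config(seed = 35))
  X <- rand_features(2, seed = 36)
  a1 <- ig_attribute(model, X, "nfvPPA", steps = 32)
  shifted <- model
  last <- length(shifted$fusion)
  shifted$fusion[[last]]$b <- shifted$fusion[[last]]$b + 7
  a2 <- ig_attribute(model = shifted, X, "nfvPPA", steps = 32)
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("batched attribution equals the single-vector path", {
  model <- build_model(parallel_net_config(seed = 37))
  X <- rand_features(2, seed = 38)
  batch <- ig_attribute(model, X, 2, steps = 16)
  single <- integrated_gradients(
    function(P) ftdnet:::logit_input_gradient(model, P, 2),
    X[1, ], steps = 16)
  expect_equal(batch[1, ], single, tolerance = 1e-10)
})

test_that("population maps recover planted temporal atrophy for svPPA", {
  # svPPA is not the w-score reference group, so its planted patches must
  # dominate its own-class importance map
  schema <- default_atlas_schema()
  topo <- default_atrophy_topography(schema)
  cfg <- simulation_config(n_per_class = c(bvFTD = 60, nfvPPA = 40,
                                           svPPA = 35),
                           n_scanners_per_cohort = 1, seed = 44)
  sim <- generate_cohort(cfg, schema, topo)
  splits <- make_nested_splits(sim$data$diagnosis, k = 5, seed = 45,
                               n_inner = 4)
  ens <- ftdnet:::train_outer_fold(sim$data, schema, parallel_net_config(),
                                   sgd_spec(max_epochs = 80, patience = 20),
                                   splits, 1, seed = 46)
  map <- population_importance_map(ens, sim$data, "svPPA", steps = 32,
                                   schema = schema)
  expect_equal(nrow(map), 735)
  thk <- map[map$block == "thickness", ]
  planted <- topo$index[topo$subtype == "svPPA" & topo$index <= 360]
  top <- thk$index[order(-abs(thk$importance))][seq_along(planted)]
  expect_gte(mean(top %in% planted), 0.6)
  # planted patches sit below the reference norm (negative w) and lower
  # values raise the svPPA score, so (x - 0) * grad is positive on average
  expect_gt(mean(thk$importance[thk$index %in% planted]), 0)
})

test_that("importance tables export one row per label per type", {
  schema <- default_atlas_schema()
  maps <- tibble::tibble(
    feature = feature_names(schema),
    label = sub("^(thk|cvol|svol)_", "", feature_names(schema)),
    block = rep(c("thickness", "cortical_volume", "subcortical_volume"),
                c(360, 360, 15)),
    index = 1:735,
    subtype = "svPPA",
    importance = round(rnorm(735) / 20, 8)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_importance_tables(maps, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 735)
  expect_equal(sum(back$block == "thickness"), 360)
  expect_equal(sum(back$block == "cortical_volume"), 360)
  expect_equal(sum(back$block == "subcortical_volume"), 15)
  expect_equal(back$importance, maps$importance, tolerance = 1e-6)
})
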