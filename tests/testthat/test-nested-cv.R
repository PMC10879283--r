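test_that("outer folds stratify 173/63/41 into sizes 27 or 28", {
  labels <- rep(c("bvFTD", "nfvPPA", "svPPA"), c(173, 63, 41))
  sp <- make_nested_splits(labels, k = 10, seed = 3)
  sizes <- lengths(purrr::map(sp$outer, "test"))
  expect_true(all(sizes %in% c(27, 28)))
  all_test <- sort(unlist(purrr::map(sp$outer, "test")))
  expect_equal(all_test, seq_along(labels))  # partition, disjoint
  # per-class deviation from perfect stratification <= 1
  for (fold in sp$outer) {
    cnt <- table(factor(labels[fold$test],
                        levels = c("bvFTD", "nfvPPA", "svPPA")))
    ideal <- c(17.3, 6.3, 4.1)
    expect_true(all(abs(cnt - ideal) <= 1))
  }
  expect_identical(sp, make_nested_splits(labels, k = 10, seed = 3))
})

test_that("inner splits partition the non-test subjects into 9 rotations", {
  labels <- rep(c("bvFTD", "nfvPPA", "svPPA"), c(60, 30, 20))
  sp <- make_nested_splits(labels, k = 10, seed = 5)
  fold <- sp$outer[[4]]
  expect_length(fold$inner, 9)
  non_test <- setdiff(seq_along(labels), fold$test)
  vals <- sort(unlist(purrr::map(fold$inner, "val")))
  expect_equal(vals, sort(non_test))
  for (inner in fold$inner) {
    expect_length(intersect(inner$train, inner$val), 0)
    expect_setequal(c(inner$train, inner$val), non_test)
  }
})

test_that("classes smaller than k are refused", {
  labels <- rep(c("bvFTD", "nfvPPA", "svPPA"), c(40, 9, 20))
  expect_error(make_nested_splits(labels, k = 10, seed = 1), "nfvPPA=9")
})

test_that("training separates strongly atrophied synthetic subtypes", {
  schema <- default_atlas_schema()
  cfg <- simulation_config(n_per_class = c(bvFTD = 40, nfvPPA = 26,
                                           svPPA = 22),
                           n_scanners_per_cohort = 1,
                           atrophy_effect_size = 3, seed = 70)
  sim <- generate_cohort(cfg, schema)
  m <- fit_harmonization(sim$data)
  w <- transform_to_wscores(m, sim$data)
  X <- as.matrix(w[, feature_names(schema)])
  y <- as.integer(w$diagnosis)
  set.seed(71)
  val <- sort(sample(length(y), 22))
  train <- setdiff(seq_along(y), val)
  fit <- train_net(X[train, ], y[train], X[val, ], y[val],
                   parallel_net_config(),
                   sgd_spec(max_epochs = 200, patience = 50), seed = 72)
  expect_gte(fit$best_val_ba, 0.95)
  # independent oracle: multinomial logistic regression on each
  # subtype's mean planted w-score reaches the same separability
  topo <- sim$truth$planted
  summ <- sapply(split(topo$index, topo$subtype),
                 function(ix) rowMeans(X[, ix]))
  df <- data.frame(y = factor(y), summ)
  lr <- nnet::multinom(y ~ ., data = df[train, ], trace = FALSE)
  pred <- predict(lr, df[val, ])
  cm <- confusion_matrix(c("bvFTD", "nfvPPA", "svPPA")[y[val]],
                         c("bvFTD", "nfvPPA", "svPPA")[as.integer(pred)])
  expect_gte(overall_balanced_accuracy(cm), 0.95)
})

test_that("training is deterministic and a zero learning rate is inert", {
  X <- rand_features(40, seed = 80)
  y <- rep(1:3, length.out = 40)
  Xv <- rand_features(12, seed = 81)
  yv <- rep(1:3, length.out = 12)
  cfg <- parallel_net_config(arms = list(thickness = c(16), volume = c(16)),
                             fusion = 8)
  opt <- sgd_spec(max_epochs = 8, patience = 8)
  f1 <- train_net(X, y, Xv, yv, cfg, opt, seed = 9)
  f2 <- train_net(X, y, Xv, yv, cfg, opt, seed = 9)
  expect_identical(ftdnet:::model_params(f1$model),
                   ftdnet:::model_params(f2$model))
  f3 <- train_net(X, y, Xv, yv, cfg, opt, seed = 10)
  expect_false(identical(ftdnet:::model_params(f1$model),
                         ftdnet:::model_params(f3$model)))
  frozen <- train_net(X, y, Xv, yv, cfg,
                      sgd_spec(lr = 0, max_epochs = 5, patience = 5),
                      seed = 9)
  init <- build_model(local({ c2 <- cfg; c2$seed <- 9L; c2 }))
  expect_equal(ftdnet:::model_params(frozen$model),
               ftdnet:::model_params(init), tolerance = 1e-12)
})

test_that("a missing class in training is an error", {
  X <- rand_features(20, seed = 82)
  expect_error(train_net(X, rep(1:2, 10), X[1:6, ], rep(1:3, 2),
                         parallel_net_config()),
               "lacks at least one class")
})

make_constant_member <- function(logit_bias) {
  cfg <- parallel_net_config(arms = list(all = 3), fusion = integer(0),
                             dropout = 0, seed = 1)
  m <- build_model(cfg)
  m$arms$all[[1]]$W[] <- 0
  m$arms$all[[1]]$b <- c(1, 1, 1)
  m$fusion[[1]]$W[] <- 0
  m$fusion[[1]]$b <- logit_bias
  m
}

test_that("ensemble prediction averages member softmax outputs", {
  # 2 decided members + 7 abstaining uniform members:
  # mean probs = (10/27, 10/27, 7/27); tie broken to the lower index
  members <- c(list(make_constant_member(c(50, 0, 0)),
                    make_constant_member(c(0, 50, 0))),
               purrr::map(1:7, ~make_constant_member(c(0, 0, 0))))
  ens <- structure(list(members = members, harmonization = NULL,
                        n_inner = 9L, fold = 1L),
                   class = "trained_ensemble")
  X <- rand_features(2, seed = 83)
  rownames(X) <- c("a", "b")
  pr <- ensemble_predict(ens, X)
  expect_equal(pr$bvFTD, rep(10 / 27, 2), tolerance = 1e-6)
  expect_equal(pr$nfvPPA, rep(10 / 27, 2), tolerance = 1e-6)
  expect_equal(pr$svPPA, rep(7 / 27, 2), tolerance = 1e-6)
  expect_equal(as.character(pr$prediction), c("bvFTD", "bvFTD"))
  expect_equal(pr$bvFTD + pr$nfvPPA + pr$svPPA, rep(1, 2),
               tolerance = 1e-9)

  # nine identical members reduce to the single-member prediction
  one <- build_model(parallel_net_config(seed = 12))
  same <- structure(list(members = rep(list(one), 9),
                         harmonization = NULL, n_inner = 9L, fold = 1L),
                    class = "trained_ensemble")
  expect_equal(unname(as.matrix(ensemble_predict(same, X)[, 2:4])),
               unname(predict(one, X)), tolerance = 1e-12)

  short <- structure(list(members = members[1:5], harmonization = NULL,
                          n_inner = 9L), class = "trained_ensemble")
  expect_error(ensemble_predict(short, X), "exactly 9 members")
})

test_that("balanced accuracy responds to planted effect size", {
  schema <- default_atlas_schema()
  run_ba <- function(d) {
    cfg <- simulation_config(n_per_class = c(bvFTD = 30, nfvPPA = 20,
                                             svPPA = 16),
                             n_scanners_per_cohort = 1,
                             atrophy_effect_size = d, seed = 90)
    sim <- generate_cohort(cfg, schema)
    splits <- make_nested_splits(sim$data$diagnosis, k = 3, seed = 91,
                                 n_inner = 2)
    cv <- run_nested_cv(sim$data, schema,
                        parallel_net_config(),
                        sgd_spec(max_epochs = 60, patience = 15),
                        splits = splits, seed = 92, keep_models = FALSE)
    glance(cv)$overall_balanced_accuracy
  }
  ba0 <- run_ba(0)
  ba2 <- run_ba(2.5)
  expect_gt(ba2, ba0 + 0.12)
  expect_gt(ba2, 0.7)
  expect_lt(ba0, 0.68)
})
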