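test_that("forward pass yields proper probability rows", {
  model <- build_model(parallel_net_config(seed = 4))
  X <- rand_features(4, seed = 2)
  probs <- predict(model, X)
  expect_equal(dim(probs), c(4, 3))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(probs > 0))
})

test_that("initialization is seed-deterministic", {
  a <- build_model(parallel_net_config(seed = 7))
  b <- build_model(parallel_net_config(seed = 7))
  expect_identical(ftdnet:::model_params(a), ftdnet:::model_params(b))
  c <- build_model(parallel_net_config(seed = 8))
  expect_false(identical(ftdnet:::model_params(a),
                         ftdnet:::model_params(c)))
})

test_that("both arms are connected to the output", {
  model <- build_model(parallel_net_config(seed = 5))
  X <- rand_features(2, seed = 3)
  base <- ftdnet:::net_forward(model, X)$logits
  X_novol <- X
  X_novol[, 361:735] <- 0
  expect_false(isTRUE(all.equal(
    ftdnet:::net_forward(model, X_novol)$logits, base)))
  X_nothk <- X
  X_nothk[, 1:360] <- 0
  expect_false(isTRUE(all.equal(
    ftdnet:::net_forward(model, X_nothk)$logits, base)))
})

test_that("ablation configurations consume the right input widths", {
  thk <- build_model(thickness_only_config())
  expect_equal(nrow(thk$arms$thickness[[1]]$W), 360)
  vol <- build_model(volume_only_config())
  expect_equal(nrow(vol$arms$volume[[1]]$W), 375)
  naive <- build_model(naive_concat_config())
  expect_equal(nrow(naive$arms$all[[1]]$W), 735)
  expect_equal(vapply(naive$arms$all, function(l) ncol(l$W), numeric(1)),
               c(256, 64))
  ml <- build_model(parallel_net_config())
  expect_equal(ncol(ml$fusion[[length(ml$fusion)]]$W), 3)
})

test_that("class weights follow the inverse-proportion rule", {
  expect_equal(compute_class_weights(c(10, 10, 10)),
               c(1, 1, 1))
  counts <- c(bvFTD = 173, nfvPPA = 63, svPPA = 41)
  raw <- sum(counts) / (3 * counts)  # N / (K n_c): 0.534, 1.466, 2.252
  expect_equal(round(unname(raw), 3), c(0.534, 1.466, 2.252))
  w <- compute_class_weights(counts)
  expect_equal(mean(w), 1)
  expect_equal(unname(w), unname(raw / mean(raw)))
  expect_equal(compute_class_weights(counts * 2), w)
  expect_error(compute_class_weights(c(5, 0, 3)), ">= 1")
})

test_that("weighted cross-entropy matches its closed forms", {
  # uniform logits over 3 classes: loss = ln 3
  logits <- matrix(0, 5, 3)
  expect_equal(weighted_cross_entropy(logits, c(1, 2, 3, 1, 2)), log(3))
  # true class at overwhelming margin: loss -> 0
  big <- matrix(c(50, 0, 0), 1, 3)
  expect_lt(weighted_cross_entropy(big, 1L), 1e-10)
  # weighted-mean reduction: a single sample's weight cancels
  l1 <- weighted_cross_entropy(big, 1L, weights = c(2, 1, 1))
  l2 <- weighted_cross_entropy(big, 1L, weights = c(1, 1, 1))
  expect_equal(l1, l2)
  expect_error(weighted_cross_entropy(matrix(c(Inf, 0, 0), 1, 3), 1L),
               "non-finite")
})

test_that("loss is symmetric under a consistent class permutation", {
  set.seed(14)
  logits <- matrix(rnorm(12), 4, 3)
  y <- c(1L, 2L, 3L, 2L)
  w <- c(0.5, 1.2, 1.3)
  perm <- c(3L, 1L, 2L)  # new index of old class k is perm[k]
  logits_p <- logits[, order(perm)]
  expect_equal(weighted_cross_entropy(logits, y, w),
               weighted_cross_entropy(logits_p, perm[y], w[order(perm)]))
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(15)
  logits <- matrix(rnorm(9, sd = 0.8), 3, 3)
  y <- c(1L, 3L, 2L)
  w <- compute_class_weights(c(3, 2, 1))
  g <- ftdnet:::wce_gradient(logits, y, w)
  eps <- 1e-6
  g_num <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    lp <- logits; lp[i, j] <- lp[i, j] + eps
    lm <- logits; lm[i, j] <- lm[i, j] - eps
    g_num[i, j] <- (weighted_cross_entropy(lp, y, w) -
                      weighted_cross_entropy(lm, y, w)) / (2 * eps)
  }
  expect_equal(g, g_num, tolerance = 1e-4)
})

test_that("backprop parameter gradients match finite differences", {
  cfg <- parallel_net_config(arms = list(thickness = c(6),
                                         volume = c(5)),
                             fusion = 4, dropout = 0, seed = 3)
  model <- build_model(cfg)
  set.seed(16)
  X <- rand_features(5, seed = 16)
  y <- c(1L, 2L, 3L, 1L, 2L)
  fwd <- ftdnet:::net_forward(model, X)
  grads <- ftdnet:::net_backward(
    model, fwd, ftdnet:::wce_gradient(fwd$logits, y))
  loss_at <- function(m) {
    weighted_cross_entropy(ftdnet:::net_forward(m, X)$logits, y)
  }
  eps <- 1e-6
  for (probe in list(c(1, 3), c(2, 1))) {
    mp <- model; mm <- model
    mp$arms$thickness[[1]]$W[probe[1], probe[2]] <-
      mp$arms$thickness[[1]]$W[probe[1], probe[2]] + eps
    mm$arms$thickness[[1]]$W[probe[1], probe[2]] <-
      mm$arms$thickness[[1]]$W[probe[1], probe[2]] - eps
    expect_equal(grads$arm_grads$thickness[[1]]$W[probe[1], probe[2]],
                 (loss_at(mp) - loss_at(mm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  mp <- model
  mp$fusion[[2]]$b[2] <- mp$fusion[[2]]$b[2] + eps
  mm <- model
  mm$fusion[[2]]$b[2] <- mm$fusion[[2]]$b[2] - eps
  expect_equal(grads$fusion_grads[[2]]$b[2],
               (loss_at(mp) - loss_at(mm)) / (2 * eps), tolerance = 1e-4)
})
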