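test_that("degenerate config collapses to the per-feature baselines", {
  cfg <- simulation_config(
    n_per_class = c(bvFTD = 8, nfvPPA = 4, svPPA = 4),
    covariate_slopes = list(age = c(thickness = 0, volume = 0),
                            sex_male = c(thickness = 0, volume = 0),
                            tiv = c(thickness = 0, volume = 0)),
    batch_effect_sd = c(thickness = 0, volume = 0),
    atrophy_effect_size = 0,
    noise_sd = c(thickness = 1e-9, volume = 1e-9),
    seed = 3)
  sim <- generate_cohort(cfg)
  X <- as.matrix(sim$data[, feature_names(default_atlas_schema())])
  expect_equal(max(abs(sweep(X, 2, sim$truth$baselines))), 0,
               tolerance = 1e-6)
})

test_that("the generator is seed-deterministic", {
  cfg <- simulation_config(n_per_class = c(bvFTD = 12, nfvPPA = 6,
                                           svPPA = 6), seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$cohort_offsets, b$truth$cohort_offsets)
  cfg2 <- simulation_config(n_per_class = c(bvFTD = 12, nfvPPA = 6,
                                            svPPA = 6), seed = 100)
  expect_false(identical(generate_cohort(cfg2)$data, a$data))
})

test_that("planted atrophy realizes the configured effect size", {
  # d = 1.5 on the planted patches, noise_sd = 1, no other structure:
  # empirical standardized group difference should sit near 1.5
  schema <- default_atlas_schema()
  topo <- complementary_atrophy_topography(schema)
  topo <- topo[topo$subtype == "bvFTD", ][1:20, ]
  cfg <- simulation_config(
    n_per_class = c(bvFTD = 500, nfvPPA = 500, svPPA = 2),
    covariate_slopes = list(age = c(thickness = 0, volume = 0),
                            sex_male = c(thickness = 0, volume = 0),
                            tiv = c(thickness = 0, volume = 0)),
    batch_effect_sd = c(thickness = 0, volume = 0),
    atrophy_effect_size = 1.5,
    noise_sd = c(thickness = 1, volume = 1), seed = 21)
  sim <- generate_cohort(cfg, schema, topo)
  X <- as.matrix(sim$data[, feature_names(schema)])
  g <- sim$data$diagnosis == "bvFTD"
  d_hat <- vapply(topo$index, function(j) {
    (mean(X[!g & sim$data$diagnosis == "nfvPPA", j]) - mean(X[g, j])) /
      sqrt((stats::var(X[g, j]) + stats::var(X[!g &
        sim$data$diagnosis == "nfvPPA", j])) / 2)
  }, numeric(1))
  expect_true(all(abs(d_hat - 1.5) < 0.3))
  expect_lt(abs(mean(d_hat) - 1.5), 0.15)
})

test_that("default topography is plausible planted anatomy", {
  schema <- default_atlas_schema()
  topo <- default_atrophy_topography(schema)
  counts <- table(topo$subtype)
  expect_true(all(counts >= 10))
  expect_true(all(topo$index >= 1 & topo$index <= 735))
  # svPPA left-lateralized: more left- than right-hemisphere patches
  sv <- topo[topo$subtype == "svPPA" & topo$index <= 360, ]
  left <- startsWith(sub("^thk_", "", sv$feature), "L_")
  expect_gt(sum(left), sum(!left))
  # partial overlap between bvFTD and nfvPPA, none planted out of range
  bv <- topo$index[topo$subtype == "bvFTD"]
  nf <- topo$index[topo$subtype == "nfvPPA"]
  expect_gt(length(intersect(bv, nf)), 0)
  expect_false(setequal(bv, nf))
})

test_that("raw volume features carry a detectable cohort effect", {
  sim <- tiny_sim()  # batch_effect_sd at defaults (volume 3x thickness)
  X <- as.matrix(sim$data[, feature_names(default_atlas_schema())])
  pv <- vapply(sample(361:720, 40), function(j) {
    summary(stats::aov(X[, j] ~ sim$data$cohort))[[1]]$`Pr(>F)`[1]
  }, numeric(1))
  # planted cohort offsets ~1.5 noise-SD: most sampled volume features react
  expect_gt(mean(pv < 0.05), 0.5)
})

test_that("generator residual spread matches the configured noise SD", {
  cfg <- simulation_config(
    n_per_class = c(bvFTD = 400, nfvPPA = 300, svPPA = 300),
    covariate_slopes = list(age = c(thickness = 0, volume = 0),
                            sex_male = c(thickness = 0, volume = 0),
                            tiv = c(thickness = 0, volume = 0)),
    batch_effect_sd = c(thickness = 0, volume = 0),
    atrophy_effect_size = 0,
    noise_sd = c(thickness = 0.12, volume = 400), seed = 5)
  sim <- generate_cohort(cfg)
  X <- as.matrix(sim$data[, feature_names(default_atlas_schema())])
  sds <- apply(X[, 1:360], 2, stats::sd)
  expect_lt(max(abs(sds - 0.12)), 0.02)
  sds_v <- apply(X[, 361:735], 2, stats::sd)
  expect_lt(max(abs(sds_v - 400)), 60)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_per_class = c(bvFTD = 0, nfvPPA = 5,
                                                 svPPA = 5)), ">= 1")
  expect_error(simulation_config(noise_sd = c(thickness = 0, volume = 1)),
               "noise_sd")
  expect_error(simulation_config(atrophy_effect_size = -1), ">= 0")
})
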