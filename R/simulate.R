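#' Simulation configuration for the synthetic multi-site cohort
#'
#' Defaults reproduce the study conditions of the real aggregated cohort the
#' pipeline is designed for: class sizes 173/63/41 (bvFTD/nfvPPA/svPPA,
#' total 277), age ~ Normal(63.7, 7.7) truncated to \[40, 90\] years, 54.5%
#' male, two cohorts assigned 47.3/52.7%, and education ~ Normal(16, 3)
#' truncated at 8 years. Batch effects are additive per-cohort and
#' per-scanner offsets drawn once per simulation, with volume-type offset SD
#' three times the thickness-type SD (in noise-SD units), so the cohort
#' effect dominates in volume features as it does in real multi-site data.
#' Planted atrophy is a negative shift of `atrophy_effect_size` noise-SDs
#' (Cohen's d) on each planted patch.
#'
#' @param n_per_class Named counts for bvFTD, nfvPPA, svPPA.
#' @param n_cohorts,n_scanners_per_cohort Site structure.
#' @param covariate_slopes Named list per feature type; see defaults.
#' @param batch_effect_sd Cohort-offset SD per feature type, in units of
#'   that type's `noise_sd`. Scanner offsets use half this SD.
#' @param atrophy_effect_size Cohen's d of the planted atrophy shift.
#' @param noise_sd Residual SD per feature type, in feature units
#'   (mm for thickness, mm^3 for volumes).
#' @param volume_nuisance_sd SD (in volume noise-SD units) of a per-subject
#'   global volumetric nuisance factor loading on every volume feature,
#'   emulating residual head-size/acquisition variation that covariate
#'   regression does not remove. 0 (off) by default.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_class = c(bvFTD = 173, nfvPPA = 63, svPPA = 41),
                              n_cohorts = 2,
                              n_scanners_per_cohort = 3,
                              covariate_slopes = list(
                                age = c(thickness = -0.010, volume = -15),
                                sex_male = c(thickness = 0.02, volume = 50),
                                tiv = c(thickness = 0, volume = 0.0015)
                              ),
                              batch_effect_sd = c(thickness = 0.5, volume = 1.5),
                              atrophy_effect_size = 2,
                              noise_sd = c(thickness = 0.12, volume = 400),
                              volume_nuisance_sd = 0,
                              seed = 1L) {
  n_per_class <- n_per_class[DIAGNOSES]
  if (any(is.na(n_per_class)) || any(n_per_class < 1)) {
    stop("`n_per_class` must name all three diagnoses with counts >= 1",
         call. = FALSE)
  }
  if (n_cohorts < 1 || n_scanners_per_cohort < 1) {
    stop("cohort/scanner counts must be >= 1", call. = FALSE)
  }
  if (any(noise_sd <= 0)) stop("`noise_sd` must be > 0", call. = FALSE)
  if (atrophy_effect_size < 0) {
    stop("`atrophy_effect_size` must be >= 0", call. = FALSE)
  }
  if (volume_nuisance_sd < 0) {
    stop("`volume_nuisance_sd` must be >= 0", call. = FALSE)
  }
  if (any(batch_effect_sd < 0)) {
    stop("`batch_effect_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(n_per_class = n_per_class, n_cohorts = as.integer(n_cohorts),
         n_scanners_per_cohort = as.integer(n_scanners_per_cohort),
         covariate_slopes = covariate_slopes,
         batch_effect_sd = batch_effect_sd,
         atrophy_effect_size = atrophy_effect_size,
         noise_sd = noise_sd,
         volume_nuisance_sd = volume_nuisance_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default planted atrophy topography
#'
#' Encodes, schematically on the placeholder parcellation, the canonical
#' atrophy patterns of the three subtypes: bvFTD gets bilateral
#' frontal/insular patches, nfvPPA a left-lateralized inferior
#' frontal/insular set partially overlapping bvFTD's (the two syndromes
#' share insular involvement), and svPPA a strongly left-lateralized
#' anterior temporal set plus left hippocampus and amygdala volumes. Each
#' planted cortical patch is atrophied in both its thickness and its volume
#' feature.
#'
#' @param schema An [atlas_schema()].
#' @return A tibble with columns `subtype`, `feature` (column name),
#'   `index` (position in the 735-feature order) and `sign` (-1, atrophy).
#' @export
default_atrophy_topography <- function(schema = default_atlas_schema()) {
  patches <- list(
    bvFTD  = c(1:12, 181:188),        # bilateral frontal/insular
    nfvPPA = c(9:22, 189:192),        # left inferior frontal, overlaps bvFTD
    svPPA  = c(60:75, 240:243)        # left > right anterior temporal
  )
  subc <- list(bvFTD = integer(), nfvPPA = integer(),
               svPPA = match(c("Left.Hippocampus", "Left.Amygdala"),
                             schema$subcortical_labels))
  topography_from_patches(schema, thickness = patches, volume = patches,
                          subcortical = subc)
}

#' Complementary-signal atrophy topography
#'
#' A stress-test layout in which the discriminative signal is split across
#' feature types: bvFTD is separable from thickness alone, nfvPPA from
#' cortical volume alone, and svPPA needs both blocks. Single-type models
#' then miss part of the signal while fusion models can recover all of it.
#'
#' @inheritParams default_atrophy_topography
#' @return Same shape as [default_atrophy_topography()].
#' @export
complementary_atrophy_topography <- function(schema = default_atlas_schema()) {
  topography_from_patches(
    schema,
    thickness = list(bvFTD = 1:20, nfvPPA = integer(), svPPA = 60:69),
    volume = list(bvFTD = integer(), nfvPPA = c(9:22, 189:192),
                  svPPA = 240:249),
    subcortical = list(bvFTD = integer(), nfvPPA = integer(),
                       svPPA = integer())
  )
}

topography_from_patches <- function(schema, thickness, volume, subcortical) {
  fn <- feature_names(schema)
  rows <- purrr::map(DIAGNOSES, function(dx) {
    idx <- c(thickness[[dx]],
             360L + volume[[dx]],
             720L + subcortical[[dx]])
    tibble::tibble(subtype = dx, feature = fn[idx], index = as.integer(idx),
                   sign = -1)
  })
  dplyr::bind_rows(rows)
}

noise_sd_by_feature <- function(config, schema) {
  blocks <- feature_blocks(schema)
  sds <- numeric(735)
  sds[blocks$thickness] <- config$noise_sd[["thickness"]]
  sds[blocks$volume] <- config$noise_sd[["volume"]]
  sds
}

#' Generate a synthetic multi-site morphometry cohort
#'
#' Each feature value is assembled additively from a per-feature baseline,
#' covariate terms (age and sex for all features; TIV for volume features
#' only), a per-cohort and a per-scanner additive offset drawn once per
#' simulation, the planted subtype atrophy shift, and Gaussian noise.
#' Ground truth (planted indices and effects, batch offsets, coefficients)
#' is returned alongside for recovery experiments.
#'
#' @param config A [simulation_config()].
#' @param schema An [atlas_schema()].
#' @param topography Planted-atrophy tibble, by default
#'   [default_atrophy_topography()].
#' @return A list with elements `data` (feature table tibble) and `truth`
#'   (list: `planted`, `cohort_offsets`, `scanner_offsets`,
#'   `coefficients`, `baselines`, `config`).
#' @examples
#' sim <- generate_cohort(simulation_config(
#'   n_per_class = c(bvFTD = 20, nfvPPA = 10, svPPA = 10), seed = 7))
#' dplyr::count(sim$data, diagnosis)
#' @export
generate_cohort <- function(config = simulation_config(),
                            schema = default_atlas_schema(),
                            topography = default_atrophy_topography(schema)) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_cohort_impl(config, schema, topography))
}

generate_cohort_impl <- function(config, schema, topography) {
  n <- sum(config$n_per_class)
  blocks <- feature_blocks(schema)
  p <- 735L

  # per-feature baselines: plausible adult gray-matter morphometry
  baselines <- numeric(p)
  baselines[blocks$thickness] <- stats::runif(360, 2.0, 3.2)
  baselines[blocks$cortical_volume] <- stats::runif(360, 2000, 8000)
  subc_base <- c(Thalamus = 7000, Caudate = 3500, Putamen = 4500,
                 Pallidum = 1500, Hippocampus = 3800, Amygdala = 1500,
                 Accumbens = 550)
  base15 <- vapply(schema$subcortical_labels, function(lab) {
    if (lab == "Brainstem") return(20000)
    subc_base[[sub("^(Left|Right)\\.", "", lab)]]
  }, numeric(1))
  baselines[blocks$subcortical_volume] <- base15 * stats::runif(15, 0.95, 1.05)

  # metadata
  diagnosis <- rep(DIAGNOSES, times = config$n_per_class)
  age <- rnorm_trunc(n, 63.7, 7.7, 40, 90)
  sex <- ifelse(stats::runif(n) < 0.545, "M", "F")
  cohort_probs <- if (config$n_cohorts == 2) c(0.473, 0.527) else
    rep(1 / config$n_cohorts, config$n_cohorts)
  cohort <- sample(paste0("cohort", seq_len(config$n_cohorts)), n,
                   replace = TRUE, prob = cohort_probs)
  scanner_id <- paste0(cohort, "_scn",
                       sample.int(config$n_scanners_per_cohort, n,
                                  replace = TRUE))
  tiv <- rnorm_trunc(n, ifelse(sex == "M", 1550000, 1350000), 120000,
                     lower = 1e6)
  education <- rnorm_trunc(n, 16, 3, lower = 8)

  sd_f <- noise_sd_by_feature(config, schema)
  type_of <- rep(c("thickness", "volume"), c(360, 375))

  sl <- config$covariate_slopes
  beta_age <- ifelse(type_of == "thickness", sl$age[["thickness"]],
                     sl$age[["volume"]])
  beta_sex <- ifelse(type_of == "thickness", sl$sex_male[["thickness"]],
                     sl$sex_male[["volume"]])
  beta_tiv <- ifelse(type_of == "thickness", sl$tiv[["thickness"]],
                     sl$tiv[["volume"]])

  batch_sd_f <- ifelse(type_of == "thickness",
                       config$batch_effect_sd[["thickness"]],
                       config$batch_effect_sd[["volume"]]) * sd_f
  cohort_offsets <- matrix(stats::rnorm(config$n_cohorts * p, 0,
                                        rep(batch_sd_f, each = config$n_cohorts)),
                           nrow = config$n_cohorts, ncol = p)
  rownames(cohort_offsets) <- paste0("cohort", seq_len(config$n_cohorts))
  scanners <- as.vector(outer(seq_len(config$n_scanners_per_cohort),
                              rownames(cohort_offsets),
                              function(s, co) paste0(co, "_scn", s)))
  scanner_offsets <- matrix(stats::rnorm(length(scanners) * p, 0,
                                         rep(batch_sd_f / 2, each = length(scanners))),
                            nrow = length(scanners), ncol = p)
  rownames(scanner_offsets) <- scanners

  # planted atrophy matrix: subjects x features shift
  atrophy <- matrix(0, n, p)
  d <- config$atrophy_effect_size
  for (dx in DIAGNOSES) {
    rows <- which(diagnosis == dx)
    sub <- topography[topography$subtype == dx, ]
    if (nrow(sub)) {
      atrophy[rows, sub$index] <- atrophy[rows, sub$index] +
        matrix(rep(sub$sign * d * sd_f[sub$index], each = length(rows)),
               nrow = length(rows))
    }
  }

  age_c <- age - 63.7
  tiv_c <- tiv - 1450000
  sex_m <- as.numeric(sex == "M")
  X <- matrix(rep(baselines, each = n), n, p) +
    outer(age_c, beta_age) +
    outer(sex_m, beta_sex) +
    outer(tiv_c, beta_tiv) +
    cohort_offsets[cohort, , drop = FALSE] +
    scanner_offsets[scanner_id, , drop = FALSE] +
    atrophy +
    matrix(stats::rnorm(n * p, 0, rep(sd_f, each = n)), n, p)
  nuisance <- numeric(n)
  if (config$volume_nuisance_sd > 0) {
    nuisance <- stats::rnorm(n, 0, config$volume_nuisance_sd)
    X[, blocks$volume] <- X[, blocks$volume] +
      outer(nuisance, rep(config$noise_sd[["volume"]], 375))
  }

  colnames(X) <- feature_names(schema)
  data <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("sub_%04d", seq_len(n)),
                   diagnosis = diagnosis, age = age, sex = sex,
                   education = education, tiv = tiv, cohort = cohort,
                   scanner_id = scanner_id),
    tibble::as_tibble(X)
  )
  list(
    data = as_feature_tibble(data),
    truth = list(planted = topography,
                 cohort_offsets = cohort_offsets,
                 scanner_offsets = scanner_offsets,
                 coefficients = list(age = beta_age, sex_male = beta_sex,
                                     tiv = beta_tiv),
                 volume_nuisance = nuisance,
                 baselines = baselines,
                 config = config)
  )
}
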