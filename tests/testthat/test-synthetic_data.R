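test_that("cohort labels respect fractions, ranges and the loading model", {
  spec <- synthetic_cohort_spec(n_dancers = 40, female_fraction = 1, seed = 61)
  lab <- sample_cohort_labels(spec)
  expect_true(all(lab$gender == "female"))
  expect_true(all(lab[big_five_traits()] >= 1 & lab[big_five_traits()] <= 5))
  expect_true(all(lab[stomp_genres()] >= 1 & lab[stomp_genres()] <= 7))
  # determinism
  expect_identical(sample_cohort_labels(spec), lab)
  # noiseless preferences are an affine function of the traits
  spec0 <- synthetic_cohort_spec(n_dancers = 15, preference_noise_sd = 0,
                                 seed = 62)
  lab0 <- sample_cohort_labels(spec0)
  pred <- 4 + as.matrix(lab0[big_five_traits()] - 3) %*%
    t(spec0$preference_loadings)
  pred <- pmin(pmax(pred, 1), 7)
  expect_equal(unname(as.matrix(lab0[stomp_genres()])), unname(pred),
               tolerance = 1e-12)
})

test_that("recordings are deterministic and structurally valid", {
  spec <- small_cohort_spec(n_dancers = 3, duration = 2, seed = 63)
  lab <- sample_cohort_labels(spec)
  r1 <- synthesize_recording(lab[2, ], spec, 1)
  r2 <- synthesize_recording(lab[2, ], spec, 1)
  expect_identical(r1$positions, r2$positions)
  r3 <- synthesize_recording(lab[2, ], spec, 2)
  expect_false(identical(r1$positions, r3$positions))
  expect_equal(dim(r1$positions), c(120, 23, 3))
  # recordings survive a disk round trip through the io layer
  f <- withr::local_tempfile(fileext = ".tsv")
  write_marker_recording(r1, f)
  back <- read_marker_recording(f)
  expect_identical(back$positions, r1$positions)
  expect_error(synthesize_recording(lab[1, ],
    synthetic_cohort_spec(duration = 0.01, sampling_rate = 60)),
    "at least 2 frames")
})

test_that("phase coupling raises correntropy between the coupled joints", {
  # same seed, same baseline oscillators; one spec couples the wrists
  # with w = 0.9, the other couples nothing
  common <- list(n_dancers = 1, n_stimuli = 1, duration = 5,
                 sampling_rate = 60, effect_size = 0, gender_effect = 0,
                 noise_sd = 0, seed = 64)
  sp_c <- do.call(synthetic_cohort_spec,
                  c(common, list(coupling_base = 0.9,
                                 trait_joint_sets = list(
                                   extraversion = c("wrist_l", "wrist_r")))))
  sp_u <- do.call(synthetic_cohort_spec,
                  c(common, list(trait_joint_sets = list())))
  lab <- sample_cohort_labels(sp_c)
  kmat <- function(spec) {
    map <- default_joint_map()
    rec <- synthesize_recording(lab[1, ], spec, 1)
    correntropy_matrix(to_local_coordinates(derive_joints(rec, map), map))
  }
  Kc <- kmat(sp_c); Ku <- kmat(sp_u)
  d <- function(K, j) {
    i <- match(paste0("wrist_", c("l", "r")), unique(K$dim_labels$joint))
    mean(vapply(1:3, function(a)
      K$K[(i[1] - 1) * 3 + a, (i[2] - 1) * 3 + a], numeric(1)))
  }
  expect_gt(d(Kc), d(Ku))
})

test_that("generate_cohort produces the full grid and full-length features", {
  spec <- small_cohort_spec(n_dancers = 3, n_stimuli = 2, duration = 2,
                            seed = 65)
  cohort <- generate_cohort(spec)
  expect_length(cohort$recordings, 6)
  expect_identical(cohort$ground_truth, spec$trait_joint_sets)
  data <- cohort_dataset(cohort)
  expect_equal(dim(data$features), c(6, 1770))
  # streaming from the spec matches the materialised cohort
  data2 <- cohort_dataset(spec)
  expect_equal(unname(data2$features), unname(data$features),
               tolerance = 1e-12)
  # different seed differs; same seed identical
  alt <- generate_cohort(small_cohort_spec(n_dancers = 3, n_stimuli = 2,
                                           duration = 2, seed = 66))
  expect_false(identical(alt$recordings[[1]]$positions,
                         cohort$recordings[[1]]$positions))
  again <- generate_cohort(spec)
  expect_identical(again$recordings[[3]]$positions,
                   cohort$recordings[[3]]$positions)
})

test_that("written cohorts carry recordings, labels and ground truth", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(small_cohort_spec(n_dancers = 2, n_stimuli = 1,
                                              duration = 2, seed = 67))
  write_cohort(cohort, dir)
  expect_length(list.files(file.path(dir, "recordings"), pattern = "\\.tsv$"),
                2)
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(lab), 2)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 67)
  expect_true("extraversion" %in% names(gt$ground_truth))
})

test_that("held-out trait recovery is monotone in the effect size", {
  # grouped 5-fold R2 for the embedded trait at three effect levels,
  # median over 5 seeds (desk-scale cohorts: 24 dancers x 2 x 10 s)
  levels <- c(0, 0.12, 0.25)
  med <- vapply(levels, function(es) {
    r2 <- vapply(1:5, function(s) {
      spec <- small_cohort_spec(effect_size = es, seed = 200 + s)
      data <- cohort_dataset(spec)
      folds <- make_folds(nrow(data$features), 5, 200 + s,
                          groups = data$sample_ids$participant)
      crossval_experiment(data, "extraversion", "bayesian",
                          folds)$evaluation$mean_r2
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_lt(med[1], 0.05)
  expect_gt(med[3], 0.5)
})

test_that("preference decoding inherits trait signal transitively", {
  # preferences never enter the kinematics; decoding them still works
  # because they load on traits that do drive the coupling
  spec <- small_cohort_spec(n_dancers = 30, seed = 71)
  data <- cohort_dataset(spec)
  folds <- make_folds(nrow(data$features), 5, 71)
  r <- crossval_experiment(data, "dance", "bayesian", folds)
  expect_gt(r$evaluation$mean_r2, 0)
})

test_that("informative joints rank high in the importance profile", {
  spec <- small_cohort_spec(seed = 72)
  data <- cohort_dataset(spec)
  folds <- make_folds(nrow(data$features), 5, 72,
                      groups = data$sample_ids$participant)
  res <- crossval_experiment(data, "conscientiousness", "bayesian", folds)
  prof <- joint_importance(res$models,
                           target_name = "conscientiousness")$paired12
  ranks <- rank(-prof$values)
  informative <- c("head", "shoulder", "knee")
  expect_lte(max(ranks[match(informative, prof$joint_labels)]), 5)
})
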