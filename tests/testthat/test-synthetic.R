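test_that("the generator is deterministic and holdout-aware", {
  cfg <- library_config(seed = 17)
  l1 <- generate_library(cfg)
  l2 <- generate_library(cfg)
  expect_identical(l1$ground_truth$compounds, l2$ground_truth$compounds)
  expect_identical(l1$compounds$activities, l2$compounds$activities)
  ## holdout cells are absent from the compound set but in the ground truth
  gt <- l1$ground_truth$compounds
  expect_equal(sum(gt$held_out), floor(0.15 * nrow(gt)))
  expect_false(any(gt$compound_id[gt$held_out] %in%
                     l1$compounds$compounds$compound_id))
})

test_that("a 3x3 single-scaffold library reconstructs the intended matrix", {
  lib <- generate_library(library_config(n_scaffolds = 1L,
                                         n_core_variants = 3L,
                                         n_substituents = 3L,
                                         holdout_fraction = 0))
  expect_equal(length(lib$compounds), 9L)
  pipe <- sarm_pipeline(lib$compounds, target_id = "T1")
  gt <- lib$ground_truth$compounds
  cores <- unique(gt$core)
  hit <- Filter(function(m) all(cores %in% m$rows), pipe$matrices)
  expect_length(hit, 1L)
  ## the symmetric scaffold admits both cut orientations under one sub-key,
  ## so the matrix may carry extra analogous rows beyond the intended three
  expect_true(length(hit[[1]]$rows) >= 3L)
  expect_true(all(unique(gt$value) %in% hit[[1]]$cols))
  ## every intended (core, substituent) cell is real in that matrix
  m <- hit[[1]]
  real_keys <- paste(m$rows[m$cells$row], m$cols[m$cells$col])[
    m$cells$status == "real"]
  expect_true(all(paste(gt$core, gt$value) %in% real_keys))
})

test_that("the intended grid is recovered for every scaffold", {
  lib <- generate_library(library_config(seed = 23))
  pipe <- sarm_pipeline(lib$compounds, target_id = "T1")
  gt <- lib$ground_truth$compounds
  recovered <- vapply(unique(gt$scaffold), function(s) {
    cores <- unique(gt$core[gt$scaffold == s])
    any(vapply(pipe$matrices, function(m) all(cores %in% m$rows),
               logical(1)))
  }, logical(1))
  expect_true(all(recovered))
  ## held-out cells surface as virtual cells of the intended matrices
  held <- gt[gt$held_out, ]
  env <- space_envelope(pipe$matrices)
  expect_true(all(held$structure %in% env$structure))
})

test_that("observed potencies follow the declared additive decomposition", {
  lib <- generate_library(library_config(seed = 29, noise_sd = 0))
  gt <- lib$ground_truth
  ci <- (gt$compounds$scaffold - 1L) * gt$config$n_core_variants +
    gt$compounds$variant
  rebuilt <- gt$mu + gt$core_effects$effect[ci] +
    gt$subst_effects$effect[gt$compounds$subst]
  expect_equal(rebuilt, gt$compounds$true_pki)
  expect_equal(gt$compounds$observed_pki, gt$compounds$true_pki)
})

test_that("cliff seeding perturbs exactly the chosen compounds", {
  base <- generate_library(library_config(seed = 41))
  lib <- seed_cliffs(base, n_cliffs = 2L, delta = 3)
  gt <- lib$ground_truth
  expect_equal(nrow(gt$cliffs), 2L)
  moved <- match(gt$cliffs$compound_id, gt$compounds$compound_id)
  before <- base$ground_truth$compounds$true_pki
  expect_equal(gt$compounds$true_pki[moved], before[moved] + 3)
  expect_equal(gt$compounds$true_pki[-moved], before[-moved])
  ## activities moved in lockstep
  act <- lib$compounds$activities
  hit <- act$compound_id %in% gt$cliffs$compound_id
  base_act <- base$compounds$activities
  expect_equal(act$pKi[hit], base_act$pKi[hit] + 3)
  ## n_cliffs = 0 leaves the library untouched
  same <- seed_cliffs(base, n_cliffs = 0L)
  expect_identical(same$compounds$activities, base$compounds$activities)
})

test_that("seeded cliffs are recovered by cliff detection", {
  lib <- seed_cliffs(generate_library(library_config(seed = 43)),
                     n_cliffs = 3L, delta = 3)
  pipe <- sarm_pipeline(lib$compounds, target_id = "T1")
  cl <- do.call(rbind, lapply(pipe$matrices, find_activity_cliffs,
                              threshold = 2))
  expect_true(all(lib$ground_truth$cliffs$compound_id %in%
                    c(cl$id_a, cl$id_b)))
})

test_that("multi-target libraries honor the promiscuity profile", {
  lib <- multi_target_library(library_config(n_scaffolds = 1L, seed = 47),
                              n_targets = 4L, promiscuity_profile = 1)
  prof <- lib$ground_truth$compounds$profile
  expect_true(all(lengths(prof) == 4L))
  ## every compound is annotated on at least one target even at low prob
  lib2 <- multi_target_library(library_config(n_scaffolds = 1L, seed = 48),
                               n_targets = 3L, promiscuity_profile = 0.05)
  expect_true(all(lengths(lib2$ground_truth$compounds$profile) >= 1L))
})
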