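## Synthetic combinatorial libraries with known ground truth.
##
## Compounds are assembled from hand-curated two-attachment ring scaffolds,
## a core-variant group at one site and a substituent at the other:
## R - scaffold - V. Because the scaffolds are pure ring systems, the only
## exocyclic single bonds are the two attachment bonds plus any bonds inside
## the substituent, so the intended (core x substituent) decomposition is
## guaranteed to be among the enumerated fragmentations, and cutting the
## variant from a core is the unique second-level cut — every scaffold's
## variants land in one analogous-series group. Potencies follow the
## additive Free-Wilson structure the prediction module assumes:
## pKi = mu + a(core) + b(substituent), optionally plus interaction and
## i.i.d. Gaussian noise.

scaffold_pool <- c(
  "[1*]c1ccc([2*])cc1",
  "[1*]c1cccc([2*])c1",
  "[1*]c1ccc([2*])nc1",
  "[1*]c1sc([2*])cc1",
  "[1*]c1oc([2*])cc1",
  "[1*]c1ccc2ccc([2*])cc2c1")

variant_pool <- c("[1*]F", "[1*]Cl", "[1*]Br", "[1*]I",
                  "[1*]C", "[1*]O", "[1*]N", "[1*]C#N")

substituent_pool <- c("[1*]C", "[1*]CC", "[1*]CCC", "[1*]CCCC",
                      "[1*]OC", "[1*]OCC", "[1*]CO", "[1*]CCO",
                      "[1*]C(C)C", "[1*]CC(C)C", "[1*]COC", "[1*]CCCCC")

## Element composition of the exocyclic groups; the ground-truth potency is
## a sum of a per-scaffold draw and per-element atomic weights, so that it
## is additive under EVERY admissible fragmentation of the molecule, not
## only the intended core/substituent split — any cut partitions the atom
## sum, hence every matrix the pipeline builds from these libraries carries
## an exactly additive potency surface.
element_pool <- c("C", "O", "N", "F", "Cl", "Br", "I")

variant_comp <- list("F", "Cl", "Br", "I", "C", "O", "N", c("C", "N"))

substituent_comp <- list(
  "C", c("C", "C"), c("C", "C", "C"), c("C", "C", "C", "C"),
  c("O", "C"), c("O", "C", "C"), c("C", "O"), c("C", "C", "O"),
  c("C", "C", "C"), c("C", "C", "C", "C"), c("C", "O", "C"),
  c("C", "C", "C", "C", "C"))

## Largest substituent size; per-element weights are scaled by it so the
## total substituent contribution stays inside `substituent_effects`.
max_subst_atoms <- 5

## Draw the additive effect decomposition: one scaffold-level draw from
## `core_effects` plus per-element atomic weights from
## `substituent_effects / max_subst_atoms`. Core effect = scaffold draw +
## variant composition; substituent effect = substituent composition.
draw_effects <- function(config) {
  a_s <- stats::runif(config$n_scaffolds, config$core_effects[1],
                      config$core_effects[2])
  w <- setNames(stats::runif(length(element_pool),
                             config$substituent_effects[1] / max_subst_atoms,
                             config$substituent_effects[2] / max_subst_atoms),
                element_pool)
  veff <- vapply(variant_comp[seq_len(config$n_core_variants)],
                 function(e) sum(w[e]), numeric(1))
  list(core_effect = rep(a_s, each = config$n_core_variants) +
         rep(veff, times = config$n_scaffolds),
       subst_effect = vapply(substituent_comp[seq_len(config$n_substituents)],
                             function(e) sum(w[e]), numeric(1)),
       scaffold_effect = a_s, weights = w)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic library configuration
#'
#' Defines a combinatorial library of `n_scaffolds` ring scaffolds, each
#' with `n_core_variants` analogous cores (differing by one small group at a
#' single site) and `n_substituents` substituents. The defaults describe the
#' validation conditions used throughout the package tests: 3 scaffolds x 4
#' core variants x 6 substituents with 15% of cells held out, additive
#' potencies around a baseline pKi of 6.5 with core and substituent
#' contributions drawn uniformly from +/- 0.4 log units, and no noise.
#'
#' @param n_scaffolds number of scaffolds (max 6).
#' @param n_core_variants analogous cores per scaffold (max 8).
#' @param n_substituents substituents per scaffold (max 12).
#' @param additive if `FALSE`, a per-cell interaction term drawn uniformly
#'   from +/- 1 pKi unit is added, breaking Free-Wilson additivity.
#' @param mu baseline pKi.
#' @param core_effects,substituent_effects numeric length-2 ranges (pKi
#'   units) for the uniform effect draws.
#' @param noise_sd standard deviation of i.i.d. Gaussian observation noise.
#' @param holdout_fraction fraction of cells withheld from the compound set
#'   (recorded in the ground truth; they surface as virtual cells).
#' @param seed integer seed governing all randomness of the generator.
#' @return object of class `library_config`.
#' @export
library_config <- function(n_scaffolds = 3L, n_core_variants = 4L,
                           n_substituents = 6L, additive = TRUE, mu = 6.5,
                           core_effects = c(-0.4, 0.4),
                           substituent_effects = c(-0.4, 0.4),
                           noise_sd = 0, holdout_fraction = 0.15,
                           seed = 1L) {
  stopifnot(n_scaffolds >= 1, n_scaffolds <= length(scaffold_pool),
            n_core_variants >= 1, n_core_variants <= length(variant_pool),
            n_substituents >= 1, n_substituents <= length(substituent_pool),
            length(core_effects) == 2, length(substituent_effects) == 2,
            noise_sd >= 0, holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 n_core_variants = as.integer(n_core_variants),
                 n_substituents = as.integer(n_substituents),
                 additive = isTRUE(additive), mu = mu,
                 core_effects = core_effects,
                 substituent_effects = substituent_effects,
                 noise_sd = noise_sd, holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "library_config")
}

## Assemble all structures and the effect decomposition; shared between the
## single- and multi-target generators. Deterministic given the config.
build_grid <- function(config) {
  sc <- scaffold_pool[seq_len(config$n_scaffolds)]
  va <- variant_pool[seq_len(config$n_core_variants)]
  su <- substituent_pool[seq_len(config$n_substituents)]
  sgs <- smiles_to_graphs(sc)
  vgs <- smiles_to_graphs(va)
  ugs <- smiles_to_graphs(su)
  core_graphs <- list(); core_key <- character(0)
  grid <- expand.grid(subst = seq_along(su), variant = seq_along(va),
                      scaffold = seq_along(sc))[, 3:1]
  for (s in seq_along(sc)) for (v in seq_along(va)) {
    g <- assemble_from_graphs(sgs[[s]], vgs[v], at = 2L)
    core_graphs[[length(core_graphs) + 1L]] <- g
  }
  core_key <- graphs_to_smiles(core_graphs)
  sub_val <- graphs_to_smiles(ugs)
  cpd_graphs <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- (grid$scaffold[i] - 1L) * length(va) + grid$variant[i]
    assemble_from_graphs(core_graphs[[ci]], ugs[grid$subst[i]], at = 1L)
  })
  grid$structure <- graphs_to_smiles(cpd_graphs)
  grid$core <- core_key[(grid$scaffold - 1L) * length(va) + grid$variant]
  grid$value <- sub_val[grid$subst]
  grid$compound_id <- sprintf("CPD%03d", seq_len(nrow(grid)))
  if (anyDuplicated(grid$structure))
    stop("build_grid: scaffold templates produced duplicate structures")
  grid
}

#' Generate a synthetic combinatorial library with ground truth
#'
#' @param config a [library_config()].
#' @param target_id name of the (single) activity target.
#' @return list with `compounds` (a [compound_set()] of the non-held-out
#'   compounds with observed activities) and `ground_truth`, a list holding
#'   the full grid (`compounds` data.frame with true and observed pKi and
#'   the `held_out` flag), the effect decomposition (`mu`, `core_effects`,
#'   `subst_effects`), and a `cliffs` data.frame (empty until
#'   [seed_cliffs()]).
#' @export
generate_library <- function(config = library_config(), target_id = "T1") {
  stopifnot(inherits(config, "library_config"))
  grid <- build_grid(config)
  n <- nrow(grid)
  gt <- with_seed(config$seed, {
    eff <- draw_effects(config)
    a <- eff$core_effect
    b <- eff$subst_effect
    inter <- if (config$additive) rep(0, n) else stats::runif(n, -1, 1)
    ci <- (grid$scaffold - 1L) * config$n_core_variants + grid$variant
    true <- config$mu + a[ci] + b[grid$subst] + inter
    obs <- true + stats::rnorm(n, 0, config$noise_sd)
    held <- rep(FALSE, n)
    n_hold <- floor(config$holdout_fraction * n)
    if (n_hold > 0) held[sample.int(n, n_hold)] <- TRUE
    list(a = a, b = b, weights = eff$weights, true = true, obs = obs,
         held = held)
  })
  grid$true_pki <- gt$true
  grid$observed_pki <- gt$obs
  grid$held_out <- gt$held
  per_matrix_real <- config$n_core_variants * config$n_substituents *
    (1 - config$holdout_fraction)
  if (per_matrix_real < 3)
    warning("generate_library: expected real cells per matrix below 3; ",
            "matrices may be dropped by the population filters")
  keep <- !grid$held_out
  cset <- compound_set(
    grid$compound_id[keep], grid$structure[keep],
    activities = data.frame(compound_id = grid$compound_id[keep],
                            target_id = target_id,
                            pKi = grid$observed_pki[keep]),
    provenance = sprintf("synthetic library (seed %d)", config$seed),
    canonicalize = FALSE)
  ground_truth <- list(
    config = config, target_id = target_id, compounds = grid,
    mu = config$mu,
    core_effects = data.frame(
      scaffold = rep(seq_len(config$n_scaffolds),
                     each = config$n_core_variants),
      variant = rep(seq_len(config$n_core_variants), config$n_scaffolds),
      effect = gt$a),
    subst_effects = data.frame(subst = seq_len(config$n_substituents),
                               effect = gt$b),
    element_weights = gt$weights,
    cliffs = data.frame(compound_id = character(0), delta = numeric(0)))
  list(compounds = cset, ground_truth = ground_truth)
}

#' Seed activity cliffs into a generated library
#'
#' Adds `delta` pKi units to the true and observed potency of `n_cliffs`
#' randomly chosen non-held-out compounds, recording them in the ground
#' truth. With the default effect ranges, a seeded compound differs from
#' every analog by at least `delta` minus the effect spread, so cliffs of
#' `delta = 3` are guaranteed to exceed the conventional 2-log-unit cliff
#' threshold.
#'
#' @param library list as returned by [generate_library()].
#' @param n_cliffs number of compounds to perturb.
#' @param delta pKi increment (default 3.0).
#' @param seed seed for the choice of compounds (default: config seed + 1).
#' @return modified `list(compounds, ground_truth)`.
#' @export
seed_cliffs <- function(library, n_cliffs, delta = 3.0, seed = NULL) {
  gt <- library$ground_truth
  if (is.null(seed)) seed <- gt$config$seed + 1L
  if (n_cliffs == 0L) return(library)
  pool <- which(!gt$compounds$held_out)
  stopifnot(n_cliffs <= length(pool))
  pick <- with_seed(seed, sample(pool, n_cliffs))
  gt$compounds$true_pki[pick] <- gt$compounds$true_pki[pick] + delta
  gt$compounds$observed_pki[pick] <- gt$compounds$observed_pki[pick] + delta
  gt$cliffs <- data.frame(compound_id = gt$compounds$compound_id[pick],
                          delta = delta)
  ids <- gt$compounds$compound_id[pick]
  act <- library$compounds$activities
  hit <- act$compound_id %in% ids & act$target_id == gt$target_id
  act$pKi[hit] <- act$pKi[hit] + delta
  library$compounds$activities <- act
  library$ground_truth <- gt
  library
}

#' Generate a multi-target synthetic library
#'
#' Per-target core and substituent effects are drawn independently, so each
#' target has its own additive potency surface. Each compound is annotated
#' on a random subset of targets drawn from `promiscuity_profile` (per-
#' target inclusion probabilities, recycled to `n_targets`; every compound
#' is annotated on at least one target).
#'
#' @param config a [library_config()].
#' @param n_targets number of targets (named `T1`, `T2`, ...).
#' @param promiscuity_profile numeric probability (scalar or length
#'   `n_targets`) that a compound is annotated on each target.
#' @return list with `compounds` (a [compound_set()]) and `ground_truth`
#'   (grid plus a `profile` list column of annotated targets per compound).
#' @export
multi_target_library <- function(config = library_config(), n_targets = 3L,
                                 promiscuity_profile = 0.7) {
  stopifnot(n_targets >= 2L)
  prob <- rep_len(promiscuity_profile, n_targets)
  stopifnot(all(prob >= 0 & prob <= 1))
  targets <- sprintf("T%d", seq_len(n_targets))
  grid <- build_grid(config)
  n <- nrow(grid)
  drawn <- with_seed(config$seed, {
    pki <- matrix(NA_real_, n, n_targets, dimnames = list(NULL, targets))
    for (t in seq_len(n_targets)) {
      eff <- draw_effects(config)
      ci <- (grid$scaffold - 1L) * config$n_core_variants + grid$variant
      pki[, t] <- config$mu + eff$core_effect[ci] +
        eff$subst_effect[grid$subst] + stats::rnorm(n, 0, config$noise_sd)
    }
    act <- matrix(stats::runif(n * n_targets) < rep(prob, each = n), n)
    none <- !rowSums(act)
    act[cbind(which(none), sample.int(n_targets, sum(none), replace = TRUE))] <- TRUE
    held <- rep(FALSE, n)
    n_hold <- floor(config$holdout_fraction * n)
    if (n_hold > 0) held[sample.int(n, n_hold)] <- TRUE
    list(pki = pki, act = act, held = held)
  })
  grid$held_out <- drawn$held
  grid$profile <- lapply(seq_len(n), function(i) targets[drawn$act[i, ]])
  keep <- which(!grid$held_out)
  act_rows <- do.call(rbind, lapply(keep, function(i) {
    tg <- targets[drawn$act[i, ]]
    data.frame(compound_id = grid$compound_id[i], target_id = tg,
               pKi = drawn$pki[i, tg])
  }))
  cset <- compound_set(grid$compound_id[keep], grid$structure[keep],
                       activities = act_rows,
                       provenance = sprintf(
                         "synthetic multi-target library (seed %d)",
                         config$seed),
                       canonicalize = FALSE)
  list(compounds = cset,
       ground_truth = list(config = config, targets = targets,
                           compounds = grid, pki = drawn$pki))
}
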