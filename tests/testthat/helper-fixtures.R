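## Shared fixtures: permissive constraints, hand-built compound sets with a
## known matrix topology, and a deterministic random-molecule generator.

## Size limits relaxed; the larger-fragment-as-key rule stays on.
permissive <- function() {
  fragmentation_constraints(max_value_heavy_atoms = 99L,
                            min_key_heavy_atoms = 1L,
                            key_must_be_larger = TRUE)
}

## A 3x3 combinatorial grid on a pyridine scaffold: variants F/Cl/Br at one
## ring site (analogous cores), substituents ethyl/propyl/butyl at the
## other. The two sites are inequivalent, so the substituent-side and
## variant-side cut orientations index under different sub-keys and the
## intended matrix stays a clean variants x substituents grid. `fill`
## selects which (variant, substituent) cells exist; `pki` gives their
## potencies in the same order.
grid_set <- function(fill = cbind(rep(1:3, each = 3), rep(1:3, times = 3)),
                     pki = NULL, target = "T1") {
  variants <- c("F", "Cl", "Br")
  substituents <- c("CC", "CCC", "CCCC")
  smi <- vapply(seq_len(nrow(fill)), function(i)
    sprintf("%sc1ccc(%s)nc1", substituents[fill[i, 2]],
            variants[fill[i, 1]]), character(1))
  ids <- sprintf("G%d%d", fill[, 1], fill[, 2])
  if (is.null(pki)) pki <- seq(5, by = 0.25, length.out = nrow(fill))
  compound_set(ids, smi,
               activities = data.frame(compound_id = ids, target_id = target,
                                       pKi = pki))
}

## Pipeline over the grid set; returns the matrix built on the intended
## second-level key (substituent site [1*], variant site [9*]) — the one
## whose rows are the variant cores.
grid_matrix <- function(fill = cbind(rep(1:3, each = 3), rep(1:3, times = 3)),
                        pki = NULL, min_real = 3L) {
  cs <- grid_set(fill, pki)
  pipe <- sarm_pipeline(cs, target_id = "T1", min_real = min_real)
  skey <- sarmatrix:::graphs_to_smiles(
    sarmatrix:::smiles_to_graphs("[1*]c1ccc([9*])nc1"))
  hit <- Filter(function(m) identical(m$second_level_key, skey),
                pipe$matrices)
  expect_length(hit, 1L)
  hit[[1]]
}

## Deterministic random molecules: a two-attachment connector filled with
## terminal blocks, occasionally nested one level. All building blocks are
## achiral and parse cleanly; sizes stay modest so brute-force enumeration
## over all cut subsets is fast.
random_molecules <- function(n, seed = 1) {
  connectors <- c("[1*]C([2*])C", "[1*]CC[2*]", "[1*]c1ccc([2*])cc1",
                  "[1*]N([2*])C", "[1*]CCC[2*]", "[1*]c1ccc([2*])nc1")
  terminals <- c("[1*]C", "[1*]CC", "[1*]CCO", "[1*]OC", "[1*]C(C)C",
                 "[1*]c1ccccc1", "[1*]C1CCCCC1", "[1*]CF", "[1*]C(=O)C",
                 "[1*]CCN", "[1*]c1ccncc1", "[1*]C(=O)OC")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    con <- sample(connectors, 1)
    if (stats::runif(1) < 0.3) {     # nest once: terminal is itself composite
      sub <- reassemble(sample(connectors, 1), sample(terminals, 1), at = 1L)
      sub <- canonical_fragment(sub)
      reassemble(con, c(sub, sample(terminals, 1)))
    } else {
      reassemble(con, sample(terminals, 2, replace = TRUE))
    }
  }, character(1))
}

## Transpose a matrix object: swap rows/columns of the cells (used for the
## neighborhood symmetry property; structural fields follow along).
transpose_sarm <- function(m) {
  tm <- m
  tm$rows <- m$cols; tm$cols <- m$rows
  tm$row_dist <- rep(NA_character_, length(m$cols))
  tm$col_values <- NULL
  cells <- m$cells
  r <- cells$row; cells$row <- cells$col; cells$col <- r
  tm$cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  tm
}
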