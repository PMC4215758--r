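## A hand-made matrix object sidesteps the chemistry when only the potency
## pattern matters: cells are laid out on an r x c grid with given pKi.
toy_matrix <- function(pki, id = "M1") {
  nr <- nrow(pki); nc <- ncol(pki)
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, 2:1]
  cells <- data.frame(
    row = grid$row, col = grid$col,
    status = ifelse(is.na(pki[cbind(grid$row, grid$col)]), "virtual", "real"),
    compound_id = sprintf("%s_c%d%d", id, grid$row, grid$col),
    pKi = pki[cbind(grid$row, grid$col)],
    structure = sprintf("STR_%s_%d_%d", id, grid$row, grid$col),
    known_elsewhere = FALSE)
  cells$compound_id[cells$status == "virtual"] <- NA_character_
  structure(list(matrix_id = id, amms_id = id, level = 1L, target_id = "T1",
                 second_level_key = "[9*]X", rows = sprintf("core%d", 1:nr),
                 row_dist = sprintf("d%d", 1:nr),
                 cols = sprintf("val%d", 1:nc),
                 col_values = as.list(sprintf("val%d", 1:nc)),
                 cells = cells),
            class = "sarm")
}

test_that("analog pairs enumerate row and column neighbors once each", {
  m <- toy_matrix(matrix(c(5, 6, 7, 8), 2, 2))
  p <- analog_pairs(m)
  expect_equal(nrow(p), 4L)               # 2 row-wise + 2 column-wise
  expect_equal(sum(p$axis == "row"), 2L)
  ## single annotated cell: no pairs
  expect_equal(nrow(analog_pairs(toy_matrix(matrix(c(5, NA, NA, NA), 2, 2)))),
               0L)
})

test_that("pair counts match the combinatorial oracle on random patterns", {
  set.seed(42)
  for (rep in 1:5) {
    pki <- matrix(ifelse(stats::runif(20) < 0.6, stats::rnorm(20, 7), NA),
                  4, 5)
    m <- toy_matrix(pki)
    k_r <- rowSums(!is.na(pki)); k_c <- colSums(!is.na(pki))
    expect_equal(nrow(analog_pairs(m)),
                 sum(choose(k_r, 2)) + sum(choose(k_c, 2)))
  }
})

test_that("discontinuity is the mean analog-pair potency difference", {
  ## flat SAR -> 0
  expect_equal(discontinuity_score(toy_matrix(matrix(7, 2, 2))), 0)
  ## exactly one pair with delta 2
  expect_equal(discontinuity_score(toy_matrix(matrix(c(5, 7, NA, NA), 2, 2))),
               2)
  ## three disjoint same-row pairs with deltas 0.1, 0.3, 3.6 -> mean 4/3
  pki <- matrix(NA_real_, 3, 6)
  pki[1, 1:2] <- c(5.0, 5.1)
  pki[2, 3:4] <- c(6.0, 6.3)
  pki[3, 5:6] <- c(7.0, 10.6)
  m <- toy_matrix(pki)
  expect_equal(sort(analog_pairs(m)$delta_p), c(0.1, 0.3, 3.6))
  expect_equal(discontinuity_score(m), 4 / 3)
  ## no pairs -> NA, and ranking excludes the matrix with a notice
  empty <- toy_matrix(matrix(c(7, NA, NA, NA), 2, 2))
  expect_true(is.na(discontinuity_score(empty)))
  expect_message(rk <- rank_matrices(list(empty), "discontinuity"),
                 "excluded")
  expect_equal(nrow(rk), 0L)
})

test_that("discontinuity is invariant to permutation and potency shifts", {
  set.seed(7)
  pki <- matrix(stats::rnorm(12, 7), 3, 4)
  m <- toy_matrix(pki)
  base <- discontinuity_score(m)
  ## row/column permutation
  perm <- toy_matrix(pki[c(3, 1, 2), c(2, 4, 1, 3)])
  expect_equal(discontinuity_score(perm), base)
  ## adding a constant to every pKi
  expect_equal(discontinuity_score(toy_matrix(pki + 1.7)), base)
})

test_that("activity cliffs use an inclusive threshold and sort descending", {
  m <- toy_matrix(matrix(c(5, 7, 9, NA), 2, 2))
  cl <- find_activity_cliffs(m, threshold = 2)
  expect_equal(cl$delta_p, c(4, 2))       # includes the boundary pair
  expect_equal(nrow(find_activity_cliffs(m, threshold = 4.5)), 0L)
})

test_that("SAR transfer detects parallel potency progression", {
  m <- toy_matrix(rbind(c(5, 6, 7), c(6, 7, 8)))
  ev <- detect_sar_transfer(m)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$correlation, 1)
  expect_equal(ev$offset, 1)
  expect_equal(ev$n_shared, 3L)
  ## translation invariance of the correlation
  m2 <- toy_matrix(rbind(c(5, 6, 7), c(6, 7, 8)) + 2)
  expect_equal(detect_sar_transfer(m2)$correlation, 1)
  ## too few shared columns
  expect_equal(nrow(detect_sar_transfer(
    toy_matrix(rbind(c(5, 6, NA), c(6, 7, NA))))), 0L)
  ## anti-correlated rows are not transfer events
  expect_equal(nrow(detect_sar_transfer(
    toy_matrix(rbind(c(5, 6, 7), c(8, 7, 6))))), 0L)
})

test_that("additive noise-free rows always show perfect transfer", {
  a <- c(0, 0.3, -0.2); b <- c(0, 0.4, 0.9, 1.4)
  m <- toy_matrix(outer(a, b, `+`) + 7)
  ev <- detect_sar_transfer(m)
  expect_equal(nrow(ev), choose(3, 2))
  expect_true(all(ev$correlation == 1))
})

test_that("preferred cores require consistent potency and support", {
  m <- toy_matrix(rbind(c(7.2, 7.9, 8.1),     # preferred
                        c(7.2, 6.1, NA),      # one weak analog
                        c(9.0, NA, NA)))      # single annotation: no support
  pref <- preferred_cores(m, potency_cut = 7.0)
  expect_equal(pref$row, 1L)
})

test_that("ranking is stable with deterministic tie-breaking", {
  m1 <- toy_matrix(matrix(c(5, 7, NA, NA), 2, 2), id = "B")  # delta 2
  m2 <- toy_matrix(matrix(c(5, 5.1, NA, NA), 2, 2), id = "A")
  m3 <- toy_matrix(matrix(c(5, 7, NA, NA), 2, 2), id = "A2") # tie with B
  rk <- rank_matrices(list(m1, m2, m3), "discontinuity")
  expect_equal(rk$matrix_id, c("A2", "B", "A"))   # tie broken by id
  expect_equal(rk$rank, 1:3)
  ## top_k larger than the list returns everything
  expect_equal(nrow(rank_matrices(list(m1, m2), "discontinuity",
                                  top_k = 10)), 2L)
  ## continuity is the negation
  rkc <- rank_matrices(list(m1, m2), "continuity")
  expect_equal(rkc$matrix_id[1], "A")
})
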