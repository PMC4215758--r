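## toy_matrix from test-analytics.R is not visible across files; a local
## copy lives in helper scope would be cleaner, so rebuild it here.
nbh_toy <- function(pki, id = "M1", structures = NULL) {
  nr <- nrow(pki); nc <- ncol(pki)
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, 2:1]
  if (is.null(structures))
    structures <- matrix(sprintf("STR_%d_%d",
                                 rep(seq_len(nr), each = nc),
                                 rep(seq_len(nc), nr)),
                         nr, nc, byrow = TRUE)
  cells <- data.frame(
    row = grid$row, col = grid$col,
    status = ifelse(is.na(pki[cbind(grid$row, grid$col)]), "virtual", "real"),
    compound_id = sprintf("%s_c%d_%d", id, grid$row, grid$col),
    pKi = pki[cbind(grid$row, grid$col)],
    structure = structures[cbind(grid$row, grid$col)],
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

test_that("a 2x2 matrix with one virtual cell has exactly one neighborhood", {
  m <- nbh_toy(matrix(c(7, 6, 5, NA), 2, 2))   # (2,2) virtual
  nb <- find_neighborhoods("STR_2_2", list(m))
  expect_equal(nrow(nb), 1L)
  ## E shares the column (6 at (1,2))... orientation: E=(rp,c), G=(r,cp),
  ## D=(rp,cp); here r=2,c=2, rp=1,cp=1: pE=5? matrix fills column-wise:
  ## (1,1)=7,(2,1)=6,(1,2)=5 -> E=(1,2)=5, G=(2,1)=6, D=(1,1)=7
  expect_equal(predict_from_neighborhood(nb), 5 + 6 - 7)
})

test_that("a 3x3 matrix with 8 real cells yields 4 neighborhoods", {
  pki <- matrix(c(7, 6, 5, 6.5, 5.5, 4.5, 8, 7, NA), 3, 3)
  m <- nbh_toy(pki)
  nb <- find_neighborhoods("STR_3_3", list(m))
  ## brute force: (rp, cp) over rows 1:2 x cols 1:2, all annotated
  expect_equal(nrow(nb), 4L)
  expect_setequal(paste(nb$rp, nb$cp), c("1 1", "1 2", "2 1", "2 2"))
})

test_that("neighborhoods pool across matrices and deduplicate by triple", {
  m1 <- nbh_toy(matrix(c(7, 6, 5, NA), 2, 2), id = "A")
  ## same virtual structure, disjoint compounds: 2 NBHs total
  m2 <- nbh_toy(matrix(c(4, 5, 6, NA), 2, 2), id = "B")
  m2$cells$structure[1:3] <- paste0("OTHER_", 1:3)
  m2$cells$structure[4] <- "STR_2_2"
  nb <- find_neighborhoods("STR_2_2", list(m1, m2))
  expect_equal(nrow(nb), 2L)
  ## identical compound triple in an overlapping matrix: counted once
  m3 <- nbh_toy(matrix(c(7, 6, 5, NA), 2, 2), id = "A")  # same ids as m1
  nb2 <- find_neighborhoods("STR_2_2", list(m1, m3))
  expect_equal(nrow(nb2), 1L)
})

test_that("the additive prediction rule evaluates exactly", {
  nb <- data.frame(pE = 7, pG = 6, pD = 5)
  expect_equal(predict_from_neighborhood(nb), 8)
  ## cancellation: pE = pD -> prediction = pG
  expect_equal(predict_from_neighborhood(data.frame(pE = 5, pG = 6.3,
                                                    pD = 5)), 6.3)
})

test_that("prediction summaries aggregate mean and sample sd", {
  s <- aggregate_predictions("X", data.frame(pE = c(8, 8, 8),
                                             pG = c(7, 7, 7),
                                             pD = c(7, 7, 7)))
  expect_equal(s$mean_pred, 8); expect_equal(s$sd_pred, 0)
  expect_equal(s$n_nbh, 3L)
  s1 <- aggregate_predictions("X", data.frame(pE = 8, pG = 7, pD = 7))
  expect_true(is.na(s1$sd_pred)); expect_equal(s1$n_nbh, 1L)
  s2 <- aggregate_predictions("X", data.frame(pE = c(7, 9), pG = c(7, 7),
                                              pD = c(7, 7)))
  expect_equal(s2$mean_pred, 8); expect_equal(s2$sd_pred, sqrt(2))
})

test_that("transposing a matrix leaves neighborhood predictions unchanged", {
  pki <- matrix(c(7, 6, 5, 6.5, 5.5, 4.5, 8, 7, NA), 3, 3)
  m <- nbh_toy(pki)
  nb <- find_neighborhoods("STR_3_3", list(m))
  nb_t <- find_neighborhoods("STR_3_3", list(transpose_sarm(m)))
  expect_equal(nrow(nb_t), nrow(nb))
  expect_setequal(round(predict_from_neighborhood(nb_t), 10),
                  round(predict_from_neighborhood(nb), 10))
})

test_that("exact recovery on the additive noise-free library", {
  lib <- generate_library(library_config(n_scaffolds = 1L, seed = 13))
  pipe <- sarm_pipeline(lib$compounds, target_id = "T1")
  preds <- predict_virtuals(pipe$matrices)
  gt <- lib$ground_truth$compounds
  held <- gt[gt$held_out, ]
  hit <- match(held$structure, preds$vc_structure)
  expect_false(anyNA(hit))
  expect_lt(max(abs(preds$mean_pred[hit] - held$true_pki)), 1e-9)
  expect_true(all(preds$sd_pred[hit] < 1e-9, na.rm = TRUE))
})

test_that("candidate prioritization applies the applicability filters", {
  sm <- data.frame(vc_structure = c("V1", "V2", "V3", "V4"),
                   mean_pred = c(8.2, 7.1, 9.0, 8.5),
                   sd_pred = c(0.1, 0.2, 0.9, 0.1),
                   n_nbh = c(3L, 4L, 5L, 2L))
  sm$source_matrices <- list("CONT", "CONT", "CONT", "CONT")
  flat <- nbh_toy(matrix(c(7, 7.05, 7.1, NA), 2, 2), id = "CONT")
  ## V3 fails max_sd, V4 fails min_nbh
  rk <- prioritize_candidates(sm, list(flat))
  expect_equal(rk$vc_structure, c("V1", "V2"))   # ranked by mean desc
  ## a VC only in discontinuous matrices is excluded
  rough <- nbh_toy(matrix(c(4, 9, 5.5, NA), 2, 2), id = "ROUGH")
  sm2 <- sm[1, ]; sm2$source_matrices <- list("ROUGH")
  expect_equal(nrow(prioritize_candidates(sm2, list(rough))), 0L)
})

test_that("guilt-by-association collects virtual neighbors of cliff partners", {
  ## cliff between (1,1)=9 and (1,2)=5; potent partner (1,1) has virtual
  ## neighbors at (1,3) [same row] and (3,1) [same column]
  pki <- matrix(c(9, 6, NA, 5, 6.2, 6.4, NA, 6.1, 6.3), 3, 3)
  m <- nbh_toy(pki)
  g <- guilt_by_association(list(m), cliff_threshold = 2)
  expect_setequal(g$vc_structure, c("STR_1_3", "STR_3_1"))
  expect_true(all(g$max_delta == 4))
  expect_true(all(g$partner_potency == 9))
  ## no cliffs -> empty
  expect_equal(nrow(guilt_by_association(
    list(nbh_toy(matrix(c(7, 7.2, 7.1, NA), 2, 2))))), 0L)
  ## a virtual adjacent to two cliffs appears once with both provenances
  pki2 <- matrix(c(9, 6, NA, 5, 6.2, 9.1, NA, 6.1, 5.0), 3, 3)
  ## cliffs: (1,1)vs(1,2) delta 4; (3,2)=9.1 vs (3,3)=5.0... fills column-
  ## wise: col1=(9,6,NA), col2=(5,6.2,9.1), col3=(NA,6.1,5.0)
  g2 <- guilt_by_association(list(nbh_toy(pki2)), cliff_threshold = 2)
  v13 <- g2[g2$vc_structure == "STR_1_3", ]
  expect_equal(nrow(v13), 1L)
  expect_true(v13$n_cliffs >= 2L)
})
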