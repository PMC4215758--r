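## Neighborhood-based Free-Wilson potency prediction for virtual compounds,
## consistency assessment over multiple neighborhoods, and candidate
## selection including guilt-by-association picks near activity cliffs.

## All (E, G, D) completions of the virtual cells of one matrix.
## E shares the virtual cell's substituent (same column, row rp), G its core
## (same row, column cp), D combines E's core with G's substituent (rp, cp).
matrix_neighborhoods <- function(m) {
  empty <- data.frame(matrix_id = character(0), vc_structure = character(0),
                      row = integer(0), col = integer(0), rp = integer(0),
                      cp = integer(0), e_id = character(0),
                      g_id = character(0), d_id = character(0),
                      pE = numeric(0), pG = numeric(0), pD = numeric(0))
  n_rows <- length(m$rows); n_cols <- length(m$cols)
  ann <- matrix(FALSE, n_rows, n_cols)
  P <- matrix(NA_real_, n_rows, n_cols)
  ID <- matrix(NA_character_, n_rows, n_cols)
  sel <- m$cells$status == "real" & !is.na(m$cells$pKi)
  ann[cbind(m$cells$row[sel], m$cells$col[sel])] <- TRUE
  P[cbind(m$cells$row[sel], m$cells$col[sel])] <- m$cells$pKi[sel]
  ID[cbind(m$cells$row[sel], m$cells$col[sel])] <- m$cells$compound_id[sel]
  virt <- m$cells[m$cells$status == "virtual", , drop = FALSE]
  if (!nrow(virt)) return(empty)
  res <- list()
  for (k in seq_len(nrow(virt))) {
    r <- virt$row[k]; cc <- virt$col[k]
    rps <- which(ann[, cc]); cps <- which(ann[r, ])
    if (!length(rps) || !length(cps)) next
    combo <- expand.grid(rp = rps, cp = cps)
    combo <- combo[ann[cbind(combo$rp, combo$cp)], , drop = FALSE]
    if (!nrow(combo)) next
    res[[length(res) + 1L]] <- data.frame(
      matrix_id = m$matrix_id, vc_structure = virt$structure[k],
      row = r, col = cc, rp = combo$rp, cp = combo$cp,
      e_id = ID[cbind(combo$rp, cc)], g_id = ID[cbind(r, combo$cp)],
      d_id = ID[cbind(combo$rp, combo$cp)],
      pE = P[cbind(combo$rp, cc)], pG = P[cbind(r, combo$cp)],
      pD = P[cbind(combo$rp, combo$cp)])
  }
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

## Neighborhoods pooled over matrices, deduplicated per virtual structure by
## the unordered (E, G, D) compound triple — the same triple can recur in
## overlapping matrices and would otherwise inflate n_nbh.
pooled_neighborhoods <- function(matrices) {
  nb <- do.call(rbind, lapply(matrices, matrix_neighborhoods))
  if (is.null(nb) || !nrow(nb)) {
    return(data.frame(matrix_id = character(0), vc_structure = character(0),
                      row = integer(0), col = integer(0), rp = integer(0),
                      cp = integer(0), e_id = character(0),
                      g_id = character(0), d_id = character(0),
                      pE = numeric(0), pG = numeric(0), pD = numeric(0)))
  }
  triple <- vapply(seq_len(nrow(nb)), function(i)
    paste(sort(c(nb$e_id[i], nb$g_id[i], nb$d_id[i])), collapse = "\r"),
    character(1))
  nb[!duplicated(paste(nb$vc_structure, triple, sep = "\n")), , drop = FALSE]
}

#' Neighborhoods of a virtual compound
#'
#' A neighborhood (NBH) of a virtual cell X is a triple of real,
#' potency-annotated cells: E in the same column (sharing X's substituent),
#' G in the same row (sharing X's core), and D at their intersection
#' (combining E's core with G's substituent). Qualifying NBHs are collected
#' across all matrices containing a virtual cell with the same canonical
#' structure and deduplicated by the unordered compound triple.
#'
#' @param vc canonical structure string of the virtual compound.
#' @param matrices list of `sarm` objects.
#' @return data.frame with one row per NBH: `matrix_id`, `row`, `col`,
#'   `rp`, `cp`, `e_id`, `g_id`, `d_id`, `pE`, `pG`, `pD`.
#' @export
find_neighborhoods <- function(vc, matrices) {
  nb <- pooled_neighborhoods(matrices)
  nb <- nb[nb$vc_structure == vc, , drop = FALSE]
  rownames(nb) <- NULL
  nb
}

#' Free-Wilson prediction from a neighborhood
#'
#' Under additivity of (logarithmic) core and substituent contributions the
#' potency of the virtual compound is `pE + pG - pD`: the sum of the
#' potencies of the two real neighbors sharing its substituent and core,
#' minus the potency of the compound combining the other core and
#' substituent.
#'
#' @param nbh data.frame of neighborhoods (columns `pE`, `pG`, `pD`).
#' @return numeric vector of predicted pKi values, one per row.
#' @export
predict_from_neighborhood <- function(nbh) {
  nbh$pE + nbh$pG - nbh$pD
}

#' Aggregate per-neighborhood predictions for one virtual compound
#'
#' @param vc canonical structure of the virtual compound.
#' @param nbhs data.frame of its neighborhoods (see [find_neighborhoods()]).
#' @return list with `vc_structure`, `predictions`, `mean_pred`, `sd_pred`
#'   (sample standard deviation; `NA` for a single NBH), `n_nbh`.
#' @export
aggregate_predictions <- function(vc, nbhs) {
  preds <- predict_from_neighborhood(nbhs)
  list(vc_structure = vc, predictions = preds,
       mean_pred = if (length(preds)) mean(preds) else NA_real_,
       sd_pred = if (length(preds) >= 2L) stats::sd(preds) else NA_real_,
       n_nbh = length(preds))
}

#' Predict all virtual compounds of a matrix collection
#'
#' Pools qualifying neighborhoods across all matrices, predicts each
#' virtual compound from each of its neighborhoods, and summarizes
#' per-compound consistency.
#'
#' @param matrices list of `sarm` objects.
#' @return data.frame with one row per virtual structure: `vc_structure`,
#'   `mean_pred`, `sd_pred`, `n_nbh`, `source_matrices` (list column).
#' @export
predict_virtuals <- function(matrices) {
  nb <- pooled_neighborhoods(matrices)
  empty <- data.frame(vc_structure = character(0), mean_pred = numeric(0),
                      sd_pred = numeric(0), n_nbh = integer(0))
  empty$source_matrices <- list()
  if (!nrow(nb)) return(empty)
  nb$pred <- predict_from_neighborhood(nb)
  sp <- split(nb, nb$vc_structure)
  res <- data.frame(
    vc_structure = names(sp),
    mean_pred = vapply(sp, function(d) mean(d$pred), numeric(1)),
    sd_pred = vapply(sp, function(d)
      if (nrow(d) >= 2L) stats::sd(d$pred) else NA_real_, numeric(1)),
    n_nbh = vapply(sp, nrow, integer(1)))
  res$source_matrices <- lapply(sp, function(d) unique(d$matrix_id))
  rownames(res) <- NULL
  res
}

#' Prioritize virtual compounds for design
#'
#' Applies the applicability-domain filters to per-compound prediction
#' summaries: at least `min_nbh` qualifying neighborhoods, prediction
#' standard deviation at most `max_sd`, and at least one source matrix
#' representing a continuous SAR region (discontinuity score at most
#' `continuity_limit`). Survivors are ranked by predicted potency
#' (descending), ties by ascending standard deviation.
#'
#' @param summaries data.frame from [predict_virtuals()].
#' @param matrices the matrices the summaries were computed from.
#' @param min_nbh minimum number of neighborhoods (default 3).
#' @param max_sd maximum prediction standard deviation in pKi units.
#' @param continuity_limit maximum source-matrix discontinuity score.
#' @return filtered, ranked data.frame (same columns plus `rank`).
#' @export
prioritize_candidates <- function(summaries, matrices, min_nbh = 3L,
                                  max_sd = 0.5, continuity_limit = 1.0) {
  disc <- setNames(vapply(matrices, discontinuity_score, numeric(1)),
                   vapply(matrices, function(m) m$matrix_id, character(1)))
  ok_matrix <- vapply(summaries$source_matrices, function(ids) {
    d <- disc[ids]
    any(!is.na(d) & d <= continuity_limit)
  }, logical(1))
  keep <- summaries$n_nbh >= min_nbh &
    !is.na(summaries$sd_pred) & summaries$sd_pred <= max_sd & ok_matrix
  res <- summaries[keep, , drop = FALSE]
  res <- res[order(-res$mean_pred, res$sd_pred, res$vc_structure), ,
             drop = FALSE]
  if (nrow(res)) res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Guilt-by-association candidates near activity cliffs
#'
#' For every activity cliff in the matrices, collects the virtual cells
#' sharing a row or a column with the cliff's more potent partner. These
#' candidates fall outside the additivity applicability domain, so no
#' numeric potency prediction is attached; each entry carries the cliff
#' magnitude and the potent partner's potency instead. A virtual compound
#' adjacent to several cliffs appears once, with all provenances listed.
#'
#' @param matrices list of `sarm` objects.
#' @param cliff_threshold minimum pKi difference of a cliff (default 2.0).
#' @return data.frame with one row per virtual structure: `vc_structure`,
#'   `n_cliffs`, `max_delta`, `partner_potency` (highest among its cliff
#'   partners), `provenance` (list column of data.frames with `matrix_id`,
#'   `partner_id`, `partner_potency`, `cliff_delta`).
#' @export
guilt_by_association <- function(matrices, cliff_threshold = 2.0) {
  recs <- list()
  for (m in matrices) {
    cl <- find_activity_cliffs(m, cliff_threshold)
    if (!nrow(cl)) next
    pki <- matrix(NA_real_, length(m$rows), length(m$cols))
    sel <- m$cells$status == "real" & !is.na(m$cells$pKi)
    pki[cbind(m$cells$row[sel], m$cells$col[sel])] <- m$cells$pKi[sel]
    virt <- m$cells[m$cells$status == "virtual", , drop = FALSE]
    if (!nrow(virt)) next
    for (i in seq_len(nrow(cl))) {
      a_p <- pki[cl$row_a[i], cl$col_a[i]]; b_p <- pki[cl$row_b[i], cl$col_b[i]]
      if (a_p >= b_p) {
        pr <- cl$row_a[i]; pc <- cl$col_a[i]; pid <- cl$id_a[i]; pp <- a_p
      } else {
        pr <- cl$row_b[i]; pc <- cl$col_b[i]; pid <- cl$id_b[i]; pp <- b_p
      }
      adj <- virt[virt$row == pr | virt$col == pc, , drop = FALSE]
      if (!nrow(adj)) next
      recs[[length(recs) + 1L]] <- data.frame(
        vc_structure = adj$structure, matrix_id = m$matrix_id,
        partner_id = pid, partner_potency = pp, cliff_delta = cl$delta_p[i])
    }
  }
  recs <- do.call(rbind, recs)
  empty <- data.frame(vc_structure = character(0), n_cliffs = integer(0),
                      max_delta = numeric(0), partner_potency = numeric(0))
  empty$provenance <- list()
  if (is.null(recs) || !nrow(recs)) return(empty)
  recs <- recs[!duplicated(recs), , drop = FALSE]
  sp <- split(recs, recs$vc_structure)
  res <- data.frame(
    vc_structure = names(sp),
    n_cliffs = vapply(sp, nrow, integer(1)),
    max_delta = vapply(sp, function(d) max(d$cliff_delta), numeric(1)),
    partner_potency = vapply(sp, function(d) max(d$partner_potency),
                             numeric(1)))
  res$provenance <- lapply(sp, function(d) {
    d$vc_structure <- NULL; rownames(d) <- NULL; d
  })
  res <- res[order(-res$partner_potency, res$vc_structure), , drop = FALSE]
  rownames(res) <- NULL
  res
}
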