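## Matrix-level SAR information content: analog pairs, continuity /
## discontinuity, activity cliffs, SAR transfer, preferred cores, ranking.

#' Analog pairs of a matrix
#'
#' All unordered pairs of potency-annotated real cells that share a row
#' (same core, different substituent) or share a column (same substituent,
#' different core). Each such pair is a matched molecular pair within the
#' matrix; `delta_p` is the absolute pKi difference.
#'
#' @param sarm a `sarm` object.
#' @return data.frame with `matrix_id`, `id_a`, `id_b`, `row_a`, `col_a`,
#'   `row_b`, `col_b`, `axis` (`"row"` or `"col"`), `delta_p`.
#' @export
analog_pairs <- function(sarm) {
  ann <- sarm$cells[sarm$cells$status == "real" & !is.na(sarm$cells$pKi), ,
                    drop = FALSE]
  res <- list()
  pair_up <- function(d, axis) {
    if (nrow(d) < 2L) return(NULL)
    idx <- utils::combn(seq_len(nrow(d)), 2L)
    data.frame(matrix_id = sarm$matrix_id,
               id_a = d$compound_id[idx[1, ]], id_b = d$compound_id[idx[2, ]],
               row_a = d$row[idx[1, ]], col_a = d$col[idx[1, ]],
               row_b = d$row[idx[2, ]], col_b = d$col[idx[2, ]],
               axis = axis,
               delta_p = abs(d$pKi[idx[1, ]] - d$pKi[idx[2, ]]))
  }
  for (r in unique(ann$row))
    res[[length(res) + 1L]] <- pair_up(ann[ann$row == r, , drop = FALSE], "row")
  for (cc in unique(ann$col))
    res[[length(res) + 1L]] <- pair_up(ann[ann$col == cc, , drop = FALSE], "col")
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(matrix_id = character(0), id_a = character(0),
                      id_b = character(0), row_a = integer(0),
                      col_a = integer(0), row_b = integer(0),
                      col_b = integer(0), axis = character(0),
                      delta_p = numeric(0))
  rownames(res) <- NULL
  res
}

#' SAR discontinuity score of a matrix
#'
#' Mean absolute pKi difference over all analog pairs, in log units: 0 for
#' a perfectly flat SAR, large for matrices rich in potency jumps between
#' analogs. The continuity score used for ranking is its negation. Returns
#' `NA` when the matrix has no analog pair (fewer than two annotated cells
#' sharing an axis); such matrices are excluded from ranking.
#'
#' @param sarm a `sarm` object.
#' @return non-negative numeric, or `NA` if undefined.
#' @export
discontinuity_score <- function(sarm) {
  p <- analog_pairs(sarm)
  if (!nrow(p)) return(NA_real_)
  mean(p$delta_p)
}

#' Activity cliffs in a matrix
#'
#' Analog pairs whose potency difference reaches the cliff threshold
#' (inclusive), sorted by decreasing difference. The default of 2 pKi units
#' (100-fold) follows the prevailing activity-cliff convention.
#'
#' @param sarm a `sarm` object.
#' @param threshold minimum `delta_p` in pKi units (default 2.0).
#' @return data.frame as [analog_pairs()], filtered and sorted.
#' @export
find_activity_cliffs <- function(sarm, threshold = 2.0) {
  p <- analog_pairs(sarm)
  p <- p[p$delta_p >= threshold, , drop = FALSE]
  p <- p[order(-p$delta_p, p$id_a, p$id_b), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' SAR transfer events between analog series
#'
#' For every unordered pair of rows with at least `min_shared` columns
#' annotated in both, computes the Spearman rank correlation of the paired
#' potencies (rank correlation honors "similar potency progression" without
#' assuming linearity). Pairs at or above `min_corr` are reported with the
#' mean potency offset between the series.
#'
#' @param sarm a `sarm` object.
#' @param min_shared minimum shared annotated columns (default 3).
#' @param min_corr minimum rank correlation (default 0.8).
#' @return data.frame with `matrix_id`, `row_a`, `row_b`, `core_a`,
#'   `core_b`, `n_shared`, `correlation`, `offset` (mean pKi of row_b minus
#'   row_a over shared columns).
#' @export
detect_sar_transfer <- function(sarm, min_shared = 3L, min_corr = 0.8) {
  empty <- data.frame(matrix_id = character(0), row_a = integer(0),
                      row_b = integer(0), core_a = character(0),
                      core_b = character(0), n_shared = integer(0),
                      correlation = numeric(0), offset = numeric(0))
  ann <- sarm$cells[sarm$cells$status == "real" & !is.na(sarm$cells$pKi), ,
                    drop = FALSE]
  n_rows <- length(sarm$rows)
  if (n_rows < 2L || !nrow(ann)) return(empty)
  P <- matrix(NA_real_, n_rows, length(sarm$cols))
  P[cbind(ann$row, ann$col)] <- ann$pKi
  res <- list()
  for (i in seq_len(n_rows - 1L)) for (j in seq(i + 1L, n_rows)) {
    shared <- which(!is.na(P[i, ]) & !is.na(P[j, ]))
    if (length(shared) < min_shared) next
    rho <- suppressWarnings(
      stats::cor(P[i, shared], P[j, shared], method = "spearman"))
    if (is.na(rho) || rho < min_corr) next
    res[[length(res) + 1L]] <- data.frame(
      matrix_id = sarm$matrix_id, row_a = i, row_b = j,
      core_a = sarm$rows[i], core_b = sarm$rows[j],
      n_shared = length(shared), correlation = rho,
      offset = mean(P[j, shared] - P[i, shared]))
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Preferred cores of a matrix
#'
#' Rows (analog series) that consistently produce potent compounds: every
#' annotated cell at or above `potency_cut`, with at least two annotated
#' cells as support.
#'
#' @param sarm a `sarm` object.
#' @param potency_cut pKi threshold.
#' @return data.frame with `row`, `core`, `n_annotated`, `min_pKi`.
#' @export
preferred_cores <- function(sarm, potency_cut) {
  ann <- sarm$cells[sarm$cells$status == "real" & !is.na(sarm$cells$pKi), ,
                    drop = FALSE]
  res <- lapply(seq_along(sarm$rows), function(r) {
    p <- ann$pKi[ann$row == r]
    if (length(p) >= 2L && all(p >= potency_cut))
      data.frame(row = r, core = sarm$rows[r], n_annotated = length(p),
                 min_pKi = min(p))
    else NULL
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(row = integer(0), core = character(0),
                      n_annotated = integer(0), min_pKi = numeric(0))
  rownames(res) <- NULL
  res
}

#' Rank matrices by an SAR criterion
#'
#' Scores each matrix and returns a stable descending ranking, ties broken
#' by matrix id. Criteria: `discontinuity` (mean analog-pair potency
#' difference), `continuity` (its negation), `transfer` (number of SAR
#' transfer events), `preferred_core` (number of preferred rows). Matrices
#' whose score is undefined (no analog pairs) are excluded with a notice.
#'
#' @param matrices list of `sarm` objects.
#' @param criterion one of `"discontinuity"`, `"continuity"`, `"transfer"`,
#'   `"preferred_core"`.
#' @param top_k keep the first `top_k` entries (default all).
#' @param potency_cut pKi cut for `preferred_core` (default 7).
#' @param ... passed to [detect_sar_transfer()] for `transfer`.
#' @return data.frame with `rank`, `matrix_id`, `criterion`, `score`.
#' @export
rank_matrices <- function(matrices,
                          criterion = c("discontinuity", "continuity",
                                        "transfer", "preferred_core"),
                          top_k = Inf, potency_cut = 7.0, ...) {
  criterion <- match.arg(criterion)
  ids <- vapply(matrices, function(m) m$matrix_id, character(1))
  score <- vapply(matrices, function(m) {
    switch(criterion,
           discontinuity = discontinuity_score(m),
           continuity = -discontinuity_score(m),
           transfer = as.numeric(nrow(detect_sar_transfer(m, ...))),
           preferred_core = as.numeric(nrow(preferred_cores(m, potency_cut))))
  }, numeric(1))
  drop <- is.na(score)
  if (any(drop))
    message("rank_matrices: excluded ", sum(drop),
            " matrix/matrices with undefined score: ",
            paste(ids[drop], collapse = ", "))
  ids <- ids[!drop]; score <- score[!drop]
  ord <- order(-score, ids)
  res <- data.frame(rank = seq_along(ord), matrix_id = ids[ord],
                    criterion = rep_len(criterion, length(ord)),
                    score = score[ord])
  utils::head(res, n = if (is.finite(top_k)) top_k else nrow(res))
}
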