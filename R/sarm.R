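## SAR matrix construction: analogous cores as rows, substituent
## combinations as columns, real and virtual cells, and the overlap /
## coverage statistics.

#' Build SAR matrices from A_MMS groups
#'
#' Turns each structurally analogous series group into a SAR matrix: rows
#' are the distinct cores (ordered by canonical core string), columns the
#' union of substituent combinations over all member series (ordered by
#' canonical combination string), and every (row, column) pair holds exactly
#' one cell. A cell is real when a data-set compound occupies that
#' core/substituent combination, otherwise virtual; virtual structures are
#' generated by reassembly, and virtuals whose structure matches a real
#' data-set compound elsewhere are flagged `known_elsewhere`. Real compounds
#' lacking a pKi for the chosen target stay real but unannotated.
#'
#' @param amms_list list of `amms` objects from [identify_amms()].
#' @param cset the [compound_set()] supplying structures and activities.
#' @param target_id activity column to annotate cells with.
#' @param min_rows minimum number of rows (analog series) per matrix.
#' @param min_real minimum number of real cells per matrix.
#' @return list of `sarm` objects. Each has `matrix_id`, `amms_id`, `level`,
#'   `target_id`, `second_level_key`, `rows` (core strings), `row_dist`
#'   (distinguishing substructures), `cols` (combination strings),
#'   `col_values` (list of tuples) and `cells` (row-major data.frame with
#'   `row`, `col`, `status`, `compound_id`, `pKi`, `structure`,
#'   `known_elsewhere`).
#' @export
build_sarms <- function(amms_list, cset, target_id, min_rows = 2L,
                        min_real = 3L) {
  stopifnot(inherits(cset, "compound_set"))
  targets <- available_targets(cset)
  if (!target_id %in% targets)
    stop("build_sarms: unknown target '", target_id, "'; available: ",
         paste(targets, collapse = ", "), call. = FALSE)
  pki <- activity_map(cset, target_id)
  out <- list()
  for (a in amms_list) {
    m <- build_one_matrix(a, cset, min_rows, min_real)
    if (is.null(m)) next
    m$target_id <- target_id
    m$cells$pKi <- unname(pki[m$cells$compound_id])
    out[[length(out) + 1L]] <- m
  }
  out
}

## Structural skeleton shared by SARM and CSM construction. Returns NULL
## when the matrix fails the population filters.
build_one_matrix <- function(a, cset, min_rows, min_real) {
  rows <- sort(unique(a$entries$core))
  if (length(rows) < min_rows) return(NULL)
  cols <- sort(unique(a$entries$values_str))
  n_real <- nrow(unique(a$entries[c("core", "values_str")]))
  if (n_real < min_real) return(NULL)
  grid <- expand.grid(col = seq_along(cols), row = seq_along(rows))[, 2:1]
  key <- paste(rows[grid$row], cols[grid$col], sep = "\r")
  ekey <- paste(a$entries$core, a$entries$values_str, sep = "\r")
  if (anyDuplicated(ekey)) {
    warning("build_sarms: multiple compounds in one cell of ", a$amms_id,
            "; keeping the first")
    a$entries <- a$entries[!duplicated(ekey), , drop = FALSE]
    ekey <- ekey[!duplicated(ekey)]
  }
  hit <- match(key, ekey)
  cells <- data.frame(
    row = grid$row, col = grid$col,
    status = ifelse(is.na(hit), "virtual", "real"),
    compound_id = a$entries$compound_id[hit],
    pKi = NA_real_,
    structure = NA_character_,
    known_elsewhere = FALSE,
    stringsAsFactors = FALSE)
  real <- !is.na(hit)
  cells$structure[real] <-
    cset$compounds$structure[match(cells$compound_id[real],
                                   cset$compounds$compound_id)]
  ## virtual structures by batched reassembly
  virt <- which(!real)
  if (length(virt)) {
    frags <- unique(c(rows, unlist(strsplit(cols, "|", fixed = TRUE))))
    fgs <- smiles_to_graphs(frags)
    names(fgs) <- frags
    tuples <- strsplit(cols, "|", fixed = TRUE)
    assembled <- lapply(virt, function(i) {
      gk <- fgs[[rows[cells$row[i]]]]
      tv <- tuples[[cells$col[i]]]
      assemble_from_graphs(gk, fgs[tv], at = attachment_labels(gk))
    })
    cells$structure[virt] <- graphs_to_smiles(assembled)
    cells$known_elsewhere[virt] <-
      cells$structure[virt] %in% cset$compounds$structure
  }
  dist <- a$members$dist_value[match(rows, a$members$core)]
  structure(list(matrix_id = a$amms_id, amms_id = a$amms_id,
                 level = a$level, target_id = NA_character_,
                 second_level_key = a$second_level_key,
                 rows = rows, row_dist = dist, cols = cols,
                 col_values = strsplit(cols, "|", fixed = TRUE),
                 cells = cells),
            class = "sarm")
}

#' @export
print.sarm <- function(x, ...) {
  s <- sarm_stats(x)
  cat(sprintf(
    "<sarm %s> level %d, target %s: %d x %d, %d real (%d annotated), %d virtual\n",
    x$matrix_id, x$level, x$target_id, s$n_rows, s$n_columns, s$n_matrix,
    sum(x$cells$status == "real" & !is.na(x$cells$pKi)),
    sum(x$cells$status == "virtual")))
  cat("  overlap:", round(s$matrix_overlap, 3),
      " coverage:", round(s$coverage, 3), "\n")
  invisible(x)
}

#' Virtual cells of a matrix
#'
#' Returns the unexplored core/substituent combinations of a matrix, with
#' structures generated by reassembly. Virtuals whose structure coincides
#' with a real data-set compound elsewhere carry `known_elsewhere = TRUE`
#' (they remain virtual in this matrix).
#'
#' @param sarm a `sarm` (or `csm`) object.
#' @return data.frame of virtual cells (subset of `sarm$cells`).
#' @export
enumerate_virtuals <- function(sarm) {
  sarm$cells[sarm$cells$status == "virtual", , drop = FALSE]
}

#' Row overlap of a matrix column
#'
#' `RO = (n_col - 1) / (#rows - 1)` where `n_col` is the number of data-set
#' compounds present in the column: 0 for a column populated in a single
#' row (no overlap), 1 for a column populated in every row (complete
#' overlap).
#'
#' @param sarm a `sarm` object.
#' @param column column index (or canonical combination string).
#' @return numeric score in \[0, 1\].
#' @export
row_overlap <- function(sarm, column) {
  n_rows <- length(sarm$rows)
  if (n_rows < 2L)
    stop("row_overlap: undefined for a single-row matrix", call. = FALSE)
  if (is.character(column)) column <- match(column, sarm$cols)
  if (is.na(column) || column < 1L || column > length(sarm$cols))
    stop("row_overlap: no such column", call. = FALSE)
  n_col <- sum(sarm$cells$status == "real" & sarm$cells$col == column)
  (n_col - 1) / (n_rows - 1)
}

#' Matrix overlap
#'
#' The average of the row-overlap values over all columns of the matrix.
#'
#' @param sarm a `sarm` object.
#' @return numeric score in \[0, 1\].
#' @export
matrix_overlap <- function(sarm) {
  mean(vapply(seq_along(sarm$cols), function(j) row_overlap(sarm, j),
              numeric(1)))
}

#' Matrix coverage
#'
#' `C = n_matrix / (#rows * #columns)`: the proportion of cells populated
#' with real compounds.
#'
#' @param sarm a `sarm` object.
#' @return numeric in (0, 1\].
#' @export
matrix_coverage <- function(sarm) {
  sum(sarm$cells$status == "real") /
    (length(sarm$rows) * length(sarm$cols))
}

#' Summary statistics of a matrix
#'
#' @param sarm a `sarm` object.
#' @return list with `n_rows`, `n_columns`, `n_matrix` (real cells),
#'   `n_virtual`, `n_col` (per-column real counts), `row_overlaps`,
#'   `matrix_overlap`, `coverage`.
#' @export
sarm_stats <- function(sarm) {
  n_rows <- length(sarm$rows); n_cols <- length(sarm$cols)
  n_col <- vapply(seq_len(n_cols), function(j)
    sum(sarm$cells$status == "real" & sarm$cells$col == j), integer(1))
  ro <- if (n_rows >= 2L) (n_col - 1) / (n_rows - 1) else rep(NA_real_, n_cols)
  list(n_rows = n_rows, n_columns = n_cols,
       n_matrix = sum(n_col), n_virtual = n_rows * n_cols - sum(n_col),
       n_col = n_col, row_overlaps = ro, matrix_overlap = mean(ro),
       coverage = sum(n_col) / (n_rows * n_cols))
}

#' Chemical space envelope
#'
#' The union of virtual compounds over a collection of matrices,
#' deduplicated by canonical structure; each entry lists its source
#' matrices.
#'
#' @param matrices list of `sarm` objects.
#' @return data.frame with `structure`, `n_sources` and `sources` (list
#'   column of matrix ids).
#' @export
space_envelope <- function(matrices) {
  vc <- do.call(rbind, lapply(matrices, function(m) {
    v <- enumerate_virtuals(m)
    if (!nrow(v)) return(NULL)
    data.frame(structure = v$structure, matrix_id = m$matrix_id)
  }))
  if (is.null(vc) || !nrow(vc)) {
    d <- data.frame(structure = character(0), n_sources = integer(0))
    d$sources <- list()
    return(d)
  }
  sp <- split(vc$matrix_id, vc$structure)
  d <- data.frame(structure = names(sp),
                  n_sources = lengths(lapply(sp, unique)))
  d$sources <- lapply(sp, unique)
  rownames(d) <- NULL
  d[order(d$structure), , drop = FALSE]
}
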