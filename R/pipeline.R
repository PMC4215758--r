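## End-to-end orchestration: compounds -> fragment index -> series ->
## analogous series groups -> matrices.

#' Run the full SAR matrix pipeline
#'
#' Fragments the compound set at the requested cut levels, detects matched
#' molecular series, groups series with structurally analogous cores, and
#' builds one potency-annotated matrix per group. Levels are processed
#' independently: single-, dual- and triple-cut matrices are generated
#' separately.
#'
#' @param cset a [compound_set()].
#' @param target_id activity column for cell annotation; default: the only
#'   target present (error if several).
#' @param levels cut levels to process (subset of 1:3; default 1).
#' @param constraints a [fragmentation_constraints()].
#' @param min_rows,min_real matrix population filters (see [build_sarms()]).
#' @param min_series minimum member series per analogous group.
#' @return list with `index`, `series`, `amms`, `matrices` and a `counts`
#'   summary (compounds, fragmentations, series, groups, matrices, virtual
#'   cells).
#' @export
sarm_pipeline <- function(cset, target_id = NULL, levels = 1L,
                          constraints = fragmentation_constraints(),
                          min_rows = 2L, min_real = 3L, min_series = 2L) {
  stopifnot(inherits(cset, "compound_set"))
  targets <- available_targets(cset)
  if (is.null(target_id)) {
    if (length(targets) != 1L)
      stop("sarm_pipeline: specify target_id; available: ",
           paste(targets, collapse = ", "), call. = FALSE)
    target_id <- targets
  }
  index <- build_index(cset, levels = levels, constraints = constraints)
  series <- matched_series(index)
  amms <- identify_amms(series, constraints = constraints,
                        min_series = min_series)
  matrices <- build_sarms(amms, cset, target_id, min_rows = min_rows,
                          min_real = min_real)
  n_frag <- sum(vapply(index, nrow, integer(1)))
  n_vc <- sum(vapply(matrices, function(m)
    sum(m$cells$status == "virtual"), integer(1)))
  list(index = index, series = series, amms = amms, matrices = matrices,
       counts = c(compounds = nrow(cset$compounds),
                  fragmentations = n_frag, series = length(series),
                  amms = length(amms), matrices = length(matrices),
                  virtual_cells = n_vc))
}

#' Run the multi-target (CSM) pipeline
#'
#' As [sarm_pipeline()], but builds compound series matrices carrying
#' per-cell target profiles instead of single-target potency annotations.
#'
#' @param cset a [compound_set()] with at least two targets.
#' @param levels,constraints,min_rows,min_real,min_series as in
#'   [sarm_pipeline()].
#' @param activity_threshold optional pKi cut defining "active against".
#' @return list with `index`, `series`, `amms`, `matrices` (list of `csm`).
#' @export
csm_pipeline <- function(cset, levels = 1L,
                         constraints = fragmentation_constraints(),
                         activity_threshold = NULL,
                         min_rows = 2L, min_real = 3L, min_series = 2L) {
  index <- build_index(cset, levels = levels, constraints = constraints)
  series <- matched_series(index)
  amms <- identify_amms(series, constraints = constraints,
                        min_series = min_series)
  matrices <- build_csm(amms, cset, activity_threshold = activity_threshold,
                        min_rows = min_rows, min_real = min_real)
  list(index = index, series = series, amms = amms, matrices = matrices)
}
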