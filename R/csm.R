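## Compound series matrices (CSMs): the multi-target variant of the SAR
## matrix, with per-cell target profiles, promiscuity degrees, and
## deconvolution into single-target matrices.

#' Build compound series matrices over multi-target annotations
#'
#' Identical structural skeleton to [build_sarms()], but each real cell
#' carries the set of targets its compound is annotated against (optionally
#' restricted to annotations with pKi at or above `activity_threshold`).
#' The promiscuity degree of a cell is the size of that set.
#'
#' @param amms_list list of `amms` objects.
#' @param cset a [compound_set()] with annotations on at least two targets.
#' @param activity_threshold optional pKi cut defining "active against";
#'   default: any annotation counts.
#' @param min_rows,min_real population filters as in [build_sarms()].
#' @return list of `csm` objects; like `sarm` but cells carry a
#'   `target_profile` list column, and the object records `targets` and
#'   per-target compound counts in `target_summary`.
#' @export
build_csm <- function(amms_list, cset, activity_threshold = NULL,
                      min_rows = 2L, min_real = 3L) {
  stopifnot(inherits(cset, "compound_set"))
  targets <- available_targets(cset)
  if (length(targets) < 2L)
    stop("build_csm: multi-target annotations required (found ",
         length(targets), " target); use build_sarms() for single-target ",
         "data", call. = FALSE)
  act <- cset$activities
  if (!is.null(activity_threshold))
    act <- act[act$pKi >= activity_threshold, , drop = FALSE]
  profiles <- split(act$target_id, act$compound_id)
  pki_by_target <- lapply(setNames(targets, targets), function(tg)
    activity_map(cset, tg))
  out <- list()
  for (a in amms_list) {
    m <- build_one_matrix(a, cset, min_rows, min_real)
    if (is.null(m)) next
    real <- m$cells$status == "real"
    prof <- vector("list", nrow(m$cells))
    prof[real] <- lapply(m$cells$compound_id[real], function(id)
      sort(unique(profiles[[id]])))
    prof[real][vapply(prof[real], is.null, logical(1))] <- list(character(0))
    m$cells$target_profile <- prof
    m$targets <- targets
    ids <- unique(m$cells$compound_id[real])
    m$target_summary <- data.frame(
      target_id = targets,
      n_compounds = vapply(targets, function(tg)
        sum(ids %in% names(pki_by_target[[tg]])), integer(1)))
    m$pki_by_target <- pki_by_target
    class(m) <- c("csm", "sarm")
    out[[length(out) + 1L]] <- m
  }
  out
}

#' @export
print.csm <- function(x, ...) {
  s <- sarm_stats(x)
  cat(sprintf("<csm %s> level %d: %d x %d, %d real, %d virtual, %d targets\n",
              x$matrix_id, x$level, s$n_rows, s$n_columns, s$n_matrix,
              s$n_virtual, length(x$targets)))
  invisible(x)
}

#' Promiscuity degree of matrix cells
#'
#' The number of targets each real cell's compound is annotated active
#' against: 0 for annotated-nowhere real cells, `NA` for virtual cells.
#'
#' @param csm a `csm` object.
#' @return integer vector aligned with `csm$cells`.
#' @export
promiscuity_degree <- function(csm) {
  stopifnot(inherits(csm, "csm"))
  deg <- rep(NA_integer_, nrow(csm$cells))
  real <- csm$cells$status == "real"
  deg[real] <- lengths(csm$cells$target_profile[real])
  deg
}

#' Deconvolute a CSM into single-target SAR matrices
#'
#' Produces one SAR matrix per target with the identical row/column skeleton
#' and real/virtual status. A real cell is potency-annotated when the
#' compound's profile contains the target (threshold semantics of the CSM
#' apply); real cells without an annotation for that target keep `pKi = NA`
#' — they are rendered gray, not demoted to virtual.
#'
#' @param csm a `csm` object.
#' @return named list of `sarm` objects, one per target.
#' @export
deconvolute_csm <- function(csm) {
  stopifnot(inherits(csm, "csm"))
  out <- list()
  for (tg in csm$targets) {
    m <- csm
    class(m) <- "sarm"
    m$target_id <- tg
    real <- m$cells$status == "real"
    has <- real & vapply(seq_len(nrow(m$cells)), function(i)
      real[i] && tg %in% m$cells$target_profile[[i]], logical(1))
    pki <- rep(NA_real_, nrow(m$cells))
    pki[has] <- unname(csm$pki_by_target[[tg]][m$cells$compound_id[has]])
    m$cells$pKi <- pki
    m$cells$target_profile <- NULL
    m$targets <- NULL; m$target_summary <- NULL; m$pki_by_target <- NULL
    out[[tg]] <- m
  }
  out
}

#' Rebuild target profiles from deconvoluted matrices
#'
#' Inverse of [deconvolute_csm()] at the annotation level: the profile of
#' each real cell is the set of targets whose single-target matrix
#' annotates it. Used to verify that deconvolution preserves annotations
#' exactly.
#'
#' @param sarm_map named list of `sarm` objects sharing one skeleton.
#' @return list of character vectors aligned with the cells of the first
#'   matrix (`NULL` entries for virtual cells).
#' @export
rebuild_profiles <- function(sarm_map) {
  stopifnot(length(sarm_map) >= 1L)
  n <- nrow(sarm_map[[1]]$cells)
  prof <- vector("list", n)
  real <- sarm_map[[1]]$cells$status == "real"
  prof[real] <- list(character(0))
  for (tg in names(sarm_map)) {
    ann <- which(real & !is.na(sarm_map[[tg]]$cells$pKi))
    for (i in ann) prof[[i]] <- sort(c(prof[[i]], tg))
  }
  prof
}
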