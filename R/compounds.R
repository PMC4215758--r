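## Compound set container and I/O: SMILES/SDF input, activity tables,
## canonicalization and duplicate merging.

#' Construct a compound set
#'
#' A compound set holds uniquely identified, canonicalized structures plus a
#' long-format activity table (compound, target, pKi). Structures are
#' canonicalized on construction; records with identical canonical
#' structures are merged (first identifier becomes primary, the others are
#' kept in `aka`) and their activities unioned.
#'
#' @param compound_id character vector of unique identifiers.
#' @param structure character vector of SMILES (canonicalized here).
#' @param activities optional data.frame with columns `compound_id`,
#'   `target_id`, `pKi`.
#' @param provenance free-text origin note.
#' @param canonicalize set `FALSE` only when structures are already in the
#'   package canonical form.
#' @return object of class `compound_set`: list with elements `compounds`
#'   (data.frame `compound_id`, `structure`, `aka` list column),
#'   `activities`, `provenance`.
#' @export
compound_set <- function(compound_id, structure, activities = NULL,
                         provenance = "", canonicalize = TRUE) {
  stopifnot(length(compound_id) == length(structure))
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id))
    stop("compound_set: duplicate compound_id(s): ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "),
         call. = FALSE)
  canon <- if (canonicalize) canonical_structure(structure) else structure
  ## merge identical structures: first id is primary
  first <- !duplicated(canon)
  aka <- lapply(canon[first], function(s)
    compound_id[!first & canon == s])
  if (any(!first))
    message("compound_set: merged ", sum(!first),
            " duplicate structure(s) into existing records")
  id_map <- setNames(rep(compound_id[first], times = 1), canon[first])
  comp <- data.frame(compound_id = compound_id[first], structure = canon[first],
                     stringsAsFactors = FALSE)
  comp$aka <- aka
  cs <- structure(list(compounds = comp,
                       activities = empty_activities(),
                       provenance = provenance),
                  class = "compound_set")
  if (!is.null(activities)) {
    ## redirect activities of merged duplicates to the primary id
    alias <- setNames(rep(comp$compound_id, lengths(comp$aka)),
                      unlist(comp$aka))
    hit <- activities$compound_id %in% names(alias)
    activities$compound_id[hit] <- alias[activities$compound_id[hit]]
    cs <- attach_activities(cs, activities)
  }
  cs
}

empty_activities <- function() {
  data.frame(compound_id = character(0), target_id = character(0),
             pKi = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds, %d activity annotations on %d target(s)\n",
              nrow(x$compounds), nrow(x$activities),
              length(unique(x$activities$target_id))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.compound_set <- function(x) nrow(x$compounds)

#' Parse compounds from a SMILES or SD file
#'
#' `.smi` files carry one record per line, `SMILES<TAB>ID` (a single space
#' separator is also accepted). SDF input is converted record-wise; the
#' molecule title is used as identifier. Unreadable records are skipped with
#' a warning; the parse is fatal only if no record survives. Duplicate
#' structures are merged as in [compound_set()].
#'
#' @param path input file.
#' @param format `"smi"` or `"sdf"` (default guessed from the extension).
#' @return a [compound_set()].
#' @export
parse_compounds <- function(path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("parse_compounds: no such file: ", path,
                               call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.sdf?$", path, ignore.case = TRUE)) "sdf" else "smi"
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1))
    ids[is.na(ids)] <- paste0("line", which(is.na(ids)))
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    out <- ob_convert("SDF", "CAN", paste0(txt, "\n"))
    recs <- strsplit(out, "\n", fixed = TRUE)[[1]]
    recs <- recs[nzchar(recs)]
    parts <- strsplit(recs, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p)
      if (length(p) >= 2 && nzchar(p[2])) p[2] else NA_character_,
      character(1))
    ids[is.na(ids)] <- paste0("rec", which(is.na(ids)))
  }
  canon <- canonical_structure(smi, on_error = "na")
  bad <- is.na(canon)
  if (all(bad)) stop("parse_compounds: no readable record in ", path,
                     call. = FALSE)
  if (any(bad))
    warning("parse_compounds: skipped ", sum(bad), " unreadable record(s): ",
            paste(ids[bad], collapse = ", "), call. = FALSE)
  message(sprintf("parse_compounds: %d parsed, %d skipped", sum(!bad),
                  sum(bad)))
  compound_set(ids[!bad], canon[!bad], provenance = path,
               canonicalize = FALSE)
}

#' Write a compound set to a SMILES file
#'
#' @param cset a [compound_set()].
#' @param path output path; one `SMILES<TAB>ID` line per compound.
#' @export
write_smi <- function(cset, path) {
  stopifnot(inherits(cset, "compound_set"))
  writeLines(paste(cset$compounds$structure, cset$compounds$compound_id,
                   sep = "\t"), path)
  invisible(path)
}

#' Attach activity annotations to a compound set
#'
#' Merges rows of an activity table (columns `compound_id`, `target_id`,
#' `pKi`) onto matching records. Replicate measurements for the same
#' (compound, target) are aggregated by the arithmetic mean on the pKi (log)
#' scale, consistent with the logarithmic additivity used for prediction.
#' Rows with non-numeric pKi are rejected with a warning; rows referencing
#' unknown compounds are reported and dropped.
#'
#' @param cset a [compound_set()].
#' @param table data.frame or path to a CSV with a header line.
#' @return the compound set with merged activities.
#' @export
attach_activities <- function(cset, table) {
  stopifnot(inherits(cset, "compound_set"))
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_id", "pKi")
  if (!all(need %in% names(table)))
    stop("attach_activities: table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tab <- data.frame(compound_id = as.character(table$compound_id),
                    target_id = as.character(table$target_id),
                    pKi = suppressWarnings(as.numeric(table$pKi)))
  bad <- !is.finite(tab$pKi)
  if (any(bad)) {
    warning("attach_activities: rejected ", sum(bad),
            " row(s) with non-numeric pKi", call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  unknown <- !(tab$compound_id %in% cset$compounds$compound_id)
  if (any(unknown)) {
    warning("attach_activities: ", sum(unknown),
            " row(s) reference unknown compound_id(s): ",
            paste(unique(tab$compound_id[unknown]), collapse = ", "),
            call. = FALSE)
    tab <- tab[!unknown, , drop = FALSE]
  }
  merged <- rbind(cset$activities, tab)
  if (nrow(merged)) {
    agg <- stats::aggregate(pKi ~ compound_id + target_id, data = merged,
                            FUN = mean)
    agg <- agg[order(agg$compound_id, agg$target_id), , drop = FALSE]
    rownames(agg) <- NULL
    cset$activities <- agg
  }
  cset
}

## pKi lookup: named vector structure -> pKi for one target
activity_map <- function(cset, target_id) {
  act <- cset$activities[cset$activities$target_id == target_id, ,
                         drop = FALSE]
  setNames(act$pKi, act$compound_id)
}

available_targets <- function(cset) sort(unique(cset$activities$target_id))
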