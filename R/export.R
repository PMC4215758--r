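## Color-coded export of matrices: potency spectrum (red -> yellow ->
## green), promiscuity shading (white -> dark blue), HTML / TSV / JSON.

#' Color scale for matrix cells
#'
#' @param kind `"potency"` (red -> yellow -> green over a pKi range) or
#'   `"promiscuity"` (white -> dark blue over a target-count range).
#' @param range numeric `(low, high)`; defaults are filled per matrix when
#'   `mode = "per_matrix"`.
#' @param mode `"per_matrix"` (range from the matrix's annotated cells) or
#'   `"global"` (use `range` as given).
#' @return object of class `color_scale`.
#' @export
color_scale <- function(kind = c("potency", "promiscuity"), range = NULL,
                        mode = c("per_matrix", "global")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  if (!is.null(range)) {
    stopifnot(length(range) == 2, range[1] < range[2])
  } else if (mode == "global") {
    range <- if (kind == "potency") c(4, 10) else c(0, 10)
  }
  structure(list(kind = kind, range = range, mode = mode),
            class = "color_scale")
}

#' Potency color of a cell
#'
#' Piecewise-linear interpolation from red (range low) through yellow
#' (midpoint) to green (range high); values outside the range are clamped.
#' `NA` (unannotated real cells) maps to gray.
#'
#' @param p numeric pKi value(s).
#' @param scale a [color_scale()] with a resolved `range`.
#' @return integer matrix with columns `r`, `g`, `b` (0-255), one row per
#'   value.
#' @export
potency_color <- function(p, scale = color_scale(range = c(4, 10))) {
  stopifnot(inherits(scale, "color_scale"), !is.null(scale$range))
  lo <- scale$range[1]; hi <- scale$range[2]
  x <- pmin(pmax((p - lo) / (hi - lo), 0), 1)
  col <- t(vapply(x, function(xi) {
    if (is.na(xi)) return(c(200L, 200L, 200L))
    if (xi <= 0.5) {            # red -> yellow
      c(255L, as.integer(round(510 * xi)), 0L)
    } else {                    # yellow -> green
      c(as.integer(round(510 * (1 - xi))), 255L, 0L)
    }
  }, integer(3)))
  colnames(col) <- c("r", "g", "b")
  col
}

#' Promiscuity color of a cell
#'
#' Linear white-to-dark-blue shading by target count, clamped to the scale
#' range.
#'
#' @param degree integer promiscuity degree(s).
#' @param scale a [color_scale()] of kind `"promiscuity"`.
#' @return integer matrix with columns `r`, `g`, `b`.
#' @export
promiscuity_color <- function(degree,
                              scale = color_scale("promiscuity",
                                                  range = c(0, 10))) {
  stopifnot(inherits(scale, "color_scale"), !is.null(scale$range))
  x <- pmin(pmax((degree - scale$range[1]) /
                   (scale$range[2] - scale$range[1]), 0), 1)
  col <- t(vapply(x, function(xi) {
    if (is.na(xi)) return(c(255L, 255L, 255L))
    as.integer(round(c(255 - 215 * xi, 255 - 215 * xi, 255 - 115 * xi)))
  }, integer(3)))
  colnames(col) <- c("r", "g", "b")
  col
}

resolve_scale <- function(m, scale) {
  if (is.null(scale))
    scale <- color_scale(if (inherits(m, "csm")) "promiscuity" else "potency")
  if (!is.null(scale$range)) return(scale)
  if (scale$kind == "potency") {
    p <- m$cells$pKi[m$cells$status == "real"]
    p <- p[!is.na(p)]
    scale$range <- if (length(p) >= 2L && diff(range(p)) > 0) range(p)
                   else c(4, 10)
  } else {
    deg <- promiscuity_degree(m)
    hi <- max(1L, max(deg, na.rm = TRUE))
    scale$range <- c(0, hi)
  }
  scale
}

#' Export a matrix to HTML, TSV or JSON
#'
#' The HTML export mimics a medicinal-chemistry R-group table: rows are
#' cores (structure strings shown), columns substituent combinations, cells
#' color-coded by potency (or promiscuity for a CSM) with compound id and
#' annotation in the tooltip. TSV and JSON exports are bit-stable for fixed
#' input: cell ordering is row-major over the deterministic row/column
#' layout.
#'
#' @param m a `sarm` or `csm` object.
#' @param path output file.
#' @param format `"html"`, `"tsv"` or `"json"` (default from extension).
#' @param scale optional [color_scale()]; default: potency scale over the
#'   matrix's annotated range, promiscuity scale for a CSM.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(m, path, format = c("auto", "html", "tsv", "json"),
                          scale = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(sub(".*\\.", "", path))
  stopifnot(format %in% c("html", "tsv", "json"))
  cells <- m$cells
  ord <- order(cells$row, cells$col)
  cells <- cells[ord, , drop = FALSE]
  is_csm <- inherits(m, "csm")
  if (format == "tsv") {
    flat <- cells
    if (is_csm)
      flat$target_profile <- vapply(flat$target_profile, function(p)
        paste(p, collapse = ","), character(1))
    flat$core <- m$rows[flat$row]
    flat$values <- m$cols[flat$col]
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(path))
  }
  if (format == "json") {
    payload <- list(matrix_id = m$matrix_id, level = m$level,
                    target_id = m$target_id,
                    second_level_key = m$second_level_key,
                    rows = m$rows, row_dist = m$row_dist, columns = m$cols,
                    stats = sarm_stats(m), cells = cells)
    if (is_csm) payload$targets <- m$targets
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  scale <- resolve_scale(m, scale)
  fill <- if (is_csm) promiscuity_color(promiscuity_degree(m)[ord], scale)
          else potency_color(cells$pKi, scale)
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<style>table{border-collapse:collapse;font-family:monospace}",
            "td,th{border:1px solid #999;padding:4px 6px}</style>",
            sprintf("</head><body><h3>%s (level %d%s)</h3>", m$matrix_id,
                    m$level,
                    if (is_csm) sprintf(", %d targets", length(m$targets))
                    else sprintf(", target %s", m$target_id)),
            "<table>",
            paste0("<tr><th></th>",
                   paste0("<th>", m$cols, "</th>", collapse = ""), "</tr>"))
  for (r in seq_along(m$rows)) {
    row_cells <- which(cells$row == r)
    tds <- vapply(row_cells, function(i) {
      if (cells$status[i] == "virtual")
        return(sprintf("<td title='virtual: %s'></td>", cells$structure[i]))
      tip <- if (is_csm)
        sprintf("%s [%s]", cells$compound_id[i],
                paste(cells$target_profile[[i]], collapse = ","))
      else
        sprintf("%s pKi=%s", cells$compound_id[i],
                ifelse(is.na(cells$pKi[i]), "n/a",
                       format(cells$pKi[i], digits = 3)))
      sprintf("<td style='background:rgb(%d,%d,%d)' title='%s'>%s</td>",
              fill[i, 1], fill[i, 2], fill[i, 3], tip, cells$compound_id[i])
    }, character(1))
    html <- c(html, paste0("<tr><th>", m$rows[r], "</th>",
                           paste(tds, collapse = ""), "</tr>"))
  }
  html <- c(html, "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}
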