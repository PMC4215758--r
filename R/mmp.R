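## Matched molecular series (first fragmentation level) and structurally
## analogous series (second level: core MMPs sharing a sub-key).

#' Matched molecular series from a fragment index
#'
#' Groups the fragment index by canonical key: all compounds indexed under
#' one key form a matched molecular series (MMS), and any two members of a
#' series form a matched molecular pair — they differ only at the cut
#' site(s). Series of size one are retained; they can still contribute a
#' sparsely populated matrix row.
#'
#' @param index a `fragment_index` from [build_index()].
#' @param level restrict to one cut level (default: all levels present).
#' @return list of `matched_series` objects: each a list with `key`,
#'   `level`, and `members` (data.frame `values_str`, `values`,
#'   `compound_id`).
#' @export
matched_series <- function(index, level = NULL) {
  stopifnot(inherits(index, "fragment_index"))
  lvs <- if (is.null(level)) names(index) else as.character(level)
  out <- list()
  for (lv in lvs) {
    tab <- index[[lv]]
    if (is.null(tab) || !nrow(tab)) next
    for (k in unique(tab$key)) {
      sub <- tab[tab$key == k, , drop = FALSE]
      ## identical (key, value-combination) from distinct compounds means a
      ## structure collision (should not happen in a deduplicated set)
      dup <- duplicated(sub$values_str)
      if (any(dup)) {
        warning("matched_series: dropping ", sum(dup),
                " duplicate value-combination(s) under key ", k)
        sub <- sub[!dup, , drop = FALSE]
      }
      out[[length(out) + 1L]] <- structure(
        list(key = k, level = as.integer(lv),
             members = data.frame(values_str = sub$values_str,
                                  compound_id = sub$compound_id) |>
               (\(d) { d$values <- sub$values; d })()),
        class = "matched_series")
    }
  }
  out
}

#' Second-level (core MMP) index of series cores
#'
#' Single-cut fragments every series core, retaining only cuts for which the
#' resulting sub-key keeps all original attachment points of the core and
#' the removed distinguishing substructure carries none of them. Results are
#' indexed by canonical sub-key: cores sharing a sub-key differ only at a
#' single site and are structural analogs. The second-level cut site is
#' written `[9*]` to keep it distinct from first-level attachment points.
#'
#' @param series list of `matched_series` from [matched_series()].
#' @param constraints a [fragmentation_constraints()]; only
#'   `max_value_heavy_atoms` applies to the distinguishing substructure.
#' @return data.frame with one row per qualifying (core, cut): columns
#'   `level`, `core`, `sub_key`, `dist_value`, `perm` (list column: the
#'   label permutation mapping the core's attachment labels into the
#'   sub-key frame).
#' @export
core_second_level_index <- function(series,
                                    constraints = fragmentation_constraints()) {
  if (!length(series)) stop("core_second_level_index: empty series list",
                            call. = FALSE)
  cores <- unique(data.frame(
    core = vapply(series, function(s) s$key, character(1)),
    level = vapply(series, function(s) s$level, integer(1))))
  graphs <- smiles_to_graphs(cores$core)
  rows <- list(); batch <- list(); pend <- list()
  for (i in seq_len(nrow(cores))) {
    g <- graphs[[i]]
    if (is.null(g)) next
    L <- cores$level[i]
    cutb <- cuttable_bonds(g)
    if (!length(cutb)) next
    ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
    ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
    stars <- which(g$atoms$elem == "*")
    heavy <- !(g$atoms$elem %in% c("H", "*"))
    for (b in cutb) {
      memb <- igraph::components(igraph::delete_edges(ig, b))$membership
      star_comp <- unique(memb[stars])
      if (length(star_comp) != 1L) next   # attachment points must stay together
      a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]
      key_side <- if (memb[a1] == star_comp) a1 else a2
      val_side <- if (memb[a1] == star_comp) a2 else a1
      val_heavy <- sum(heavy[memb == memb[val_side]])
      if (val_heavy > constraints$max_value_heavy_atoms) next
      gsub <- induced_fragment(g, which(memb == star_comp),
                               data.frame(inside = key_side, label = 9L))
      gval <- induced_fragment(g, which(memb == memb[val_side]),
                               data.frame(inside = val_side, label = 1L))
      perms <- label_perms(L)
      kidx <- integer(length(perms))
      for (j in seq_along(perms)) {
        batch[[length(batch) + 1L]] <-
          relabel_attachments(gsub, perms[[j]], permutable = seq_len(L))
        kidx[j] <- length(batch)
      }
      batch[[length(batch) + 1L]] <- gval
      pend[[length(pend) + 1L]] <- list(core = cores$core[i], level = L,
                                        kidx = kidx, vidx = length(batch),
                                        perms = perms)
    }
  }
  empty <- data.frame(level = integer(0), core = character(0),
                      sub_key = character(0), dist_value = character(0))
  empty$perm <- list()
  if (!length(pend)) return(empty)
  strs <- graphs_to_smiles(batch)
  rows <- lapply(pend, function(p) {
    ks <- strs[p$kidx]
    if (anyNA(ks) || is.na(strs[p$vidx])) return(NULL)
    best <- which(ks == min(ks))[1]
    r <- data.frame(level = p$level, core = p$core, sub_key = ks[best],
                    dist_value = strs[p$vidx])
    r$perm <- list(p$perms[[best]])
    r
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) return(empty)
  dup <- duplicated(paste(rows$level, rows$core, rows$sub_key,
                          rows$dist_value, sep = "\r"))
  rows <- rows[!dup, , drop = FALSE]
  rows <- rows[order(rows$level, rows$sub_key, rows$core, rows$dist_value), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Identify structurally analogous matched molecular series (A_MMS)
#'
#' Groups matched molecular series whose cores share a second-level sub-key,
#' i.e. whose cores are distinguished by a structural modification at a
#' single site. A series can belong to multiple groups, one per qualifying
#' second-level cut. Each group carries its member series' substituent
#' tuples re-expressed in the sub-key's canonical attachment frame, so that
#' matrix columns align across analogous cores.
#'
#' @param series list of `matched_series`.
#' @param constraints a [fragmentation_constraints()].
#' @param min_series minimum number of member series per group (default 2).
#' @return list of `amms` objects: each a list with `amms_id`, `level`,
#'   `second_level_key`, `members` (data.frame `core`, `dist_value`),
#'   `entries` (data.frame `core`, `values_str`, `values`, `compound_id`,
#'   tuples in the sub-key frame).
#' @export
identify_amms <- function(series, constraints = fragmentation_constraints(),
                          min_series = 2L) {
  idx2 <- core_second_level_index(series, constraints)
  if (!nrow(idx2)) return(list())
  skey <- vapply(series, function(s) paste0(s$level, "\r", s$key),
                 character(1))
  out <- list()
  for (lv in unique(idx2$level)) {
    sub <- idx2[idx2$level == lv, , drop = FALSE]
    counter <- 0L
    for (sk in unique(sub$sub_key)) {
      grp <- sub[sub$sub_key == sk, , drop = FALSE]
      ## a core can reach the same sub-key via symmetric cuts; one row each
      grp <- grp[!duplicated(grp$core), , drop = FALSE]
      if (nrow(grp) < min_series) next
      entries <- do.call(rbind, lapply(seq_len(nrow(grp)), function(j) {
        s <- series[[match(paste0(lv, "\r", grp$core[j]), skey)]]
        perm <- grp$perm[[j]]
        vals <- lapply(s$members$values, function(v) {
          w <- character(length(v)); w[perm] <- v; w
        })
        d <- data.frame(core = grp$core[j],
                        values_str = vapply(vals, paste, character(1),
                                            collapse = "|"),
                        compound_id = s$members$compound_id)
        d$values <- vals
        d
      }))
      counter <- counter + 1L
      out[[length(out) + 1L]] <- structure(
        list(amms_id = sprintf("L%d_%04d", lv, counter),
             level = lv, second_level_key = sk,
             members = data.frame(core = grp$core,
                                  dist_value = grp$dist_value),
             entries = entries),
        class = "amms")
    }
  }
  out
}

#' @export
print.amms <- function(x, ...) {
  cat(sprintf("<amms %s> level %d, %d analogous series, %d compounds\n  sub-key: %s\n",
              x$amms_id, x$level, nrow(x$members), nrow(x$entries),
              x$second_level_key))
  invisible(x)
}

#' Write an A_MMS table to TSV
#'
#' @param amms_list list of `amms` objects.
#' @param path output file path.
#' @export
write_amms <- function(amms_list, path) {
  rows <- do.call(rbind, lapply(amms_list, function(a) {
    m <- merge(a$entries[c("core", "compound_id", "values_str")],
               a$members, by = "core")
    data.frame(amms_id = a$amms_id, level = a$level,
               second_level_key = a$second_level_key,
               core = m$core, distinguishing_value = m$dist_value,
               values = m$values_str, compound_id = m$compound_id)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
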