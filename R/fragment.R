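## Systematic exocyclic single-bond fragmentation (single, dual, triple cut)
## producing key (core) / value (substituent) records, and the per-level
## fragment index that all series and matrix construction builds on.

#' Fragmentation constraints
#'
#' Size filters applied to candidate fragmentations. A cut is retained only
#' if every substituent (value) fragment has at most `max_value_heavy_atoms`
#' heavy atoms, the core (key) has at least `min_key_heavy_atoms`, and — when
#' `key_must_be_larger` — the key carries at least half of the molecule's
#' heavy atoms. The defaults mirror common matched-molecular-pair practice;
#' they are deliberately configurable because series and matrix counts on
#' real data sets depend on them.
#'
#' @param max_value_heavy_atoms maximum heavy atoms per substituent fragment.
#' @param min_key_heavy_atoms minimum heavy atoms in the core fragment.
#' @param key_must_be_larger require key heavy atoms >= total/2.
#' @return object of class `fragmentation_constraints`.
#' @export
fragmentation_constraints <- function(max_value_heavy_atoms = 13L,
                                      min_key_heavy_atoms = 5L,
                                      key_must_be_larger = TRUE) {
  stopifnot(max_value_heavy_atoms >= 1, min_key_heavy_atoms >= 1)
  structure(list(max_value_heavy_atoms = max_value_heavy_atoms,
                 min_key_heavy_atoms = min_key_heavy_atoms,
                 key_must_be_larger = isTRUE(key_must_be_larger)),
            class = "fragmentation_constraints")
}

## Bonds eligible for cutting: single order, acyclic (bridges of the bond
## graph), joining two heavy atoms. Returns integer bond indices.
cuttable_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(integer(0))
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
  br <- as.integer(igraph::bridges(ig))
  heavy <- !(g$atoms$elem %in% c("H", "*"))
  which(g$bonds$order == 1L & heavy[g$bonds$a1] & heavy[g$bonds$a2] &
          seq_len(nb) %in% br)
}

## Core enumeration on a parsed graph. Returns a data.frame with columns
## key, values (list of character), values_str, key_heavy; deduplicated by
## canonical (key, values) identity. One batched Open Babel call.
enumerate_on_graph <- function(g, level, constraints) {
  empty <- data.frame(key = character(0), values_str = character(0),
                      key_heavy = integer(0))
  empty$values <- list()
  cutb <- cuttable_bonds(g)
  if (length(cutb) < level) return(empty)
  heavy <- !(g$atoms$elem %in% c("H", "*"))
  total_heavy <- sum(heavy)
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
  subsets <- utils::combn(cutb, level, simplify = FALSE)

  cand <- list()     # per candidate: key graph perms + value graphs
  batch <- list()    # graphs to convert, in order
  for (S in subsets) {
    memb <- igraph::components(igraph::delete_edges(ig, S))$membership
    ends <- cbind(memb[g$bonds$a1[S]], memb[g$bonds$a2[S]])
    comp_sizes <- tapply(heavy, memb, sum)
    key_cands <- Reduce(intersect, lapply(seq_len(level), function(i) ends[i, ]))
    if (level >= 2L && length(key_cands) > 1L) key_cands <- key_cands[1]
    for (kc in key_cands) {
      val_comps <- vapply(seq_len(level), function(i)
        if (ends[i, 1] == kc) ends[i, 2] else ends[i, 1], numeric(1))
      key_heavy <- comp_sizes[[as.character(kc)]]
      val_heavy <- vapply(val_comps, function(vc)
        comp_sizes[[as.character(vc)]], numeric(1))
      if (any(val_heavy > constraints$max_value_heavy_atoms)) next
      if (key_heavy < constraints$min_key_heavy_atoms) next
      if (constraints$key_must_be_larger && 2 * key_heavy < total_heavy) next
      key_atoms <- which(memb == kc)
      key_cuts <- data.frame(
        inside = vapply(seq_len(level), function(i) {
          a <- g$bonds$a1[S[i]]; b <- g$bonds$a2[S[i]]
          if (memb[a] == kc) a else b
        }, integer(1)),
        label = seq_len(level))
      gk <- induced_fragment(g, key_atoms, key_cuts)
      perms <- label_perms(level)
      kidx <- integer(length(perms))
      for (j in seq_along(perms)) {
        batch[[length(batch) + 1L]] <-
          relabel_attachments(gk, perms[[j]], permutable = seq_len(level))
        kidx[j] <- length(batch)
      }
      vidx <- integer(level)
      for (i in seq_len(level)) {
        a <- g$bonds$a1[S[i]]; b <- g$bonds$a2[S[i]]
        vin <- if (memb[a] == kc) b else a
        gv <- induced_fragment(g, which(memb == val_comps[i]),
                               data.frame(inside = vin, label = 1L))
        batch[[length(batch) + 1L]] <- gv
        vidx[i] <- length(batch)
      }
      cand[[length(cand) + 1L]] <- list(kidx = kidx, vidx = vidx,
                                        key_heavy = key_heavy, perms = perms)
    }
  }
  if (!length(cand)) return(empty)
  strs <- graphs_to_smiles(batch)
  rows <- lapply(cand, function(cc) {
    ks <- strs[cc$kidx]
    if (anyNA(ks)) return(NULL)
    best <- which(ks == min(ks))[1]
    perm <- cc$perms[[best]]
    vals <- strs[cc$vidx]
    if (anyNA(vals)) return(NULL)
    ordered <- character(length(vals))
    ordered[perm] <- vals           # value at old label i moves to perm[i]
    data.frame(key = ks[best], values_str = paste(ordered, collapse = "|"),
               key_heavy = cc$key_heavy)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows)) return(empty)
  dup <- duplicated(paste(rows$key, rows$values_str, sep = "\r"))
  rows <- rows[!dup, , drop = FALSE]
  rows$values <- strsplit(rows$values_str, "|", fixed = TRUE)
  rownames(rows) <- NULL
  rows
}

#' Enumerate fragmentations of a compound
#'
#' Systematically deletes `level` exocyclic single bonds (1 = single cut,
#' 2 = dual, 3 = triple) between heavy atoms. Each qualifying cut set yields
#' one fragmentation: a connected key (core) fragment carrying all attachment
#' points, and `level` single-attachment value (substituent) fragments
#' ordered by attachment label. For multi-cuts, cut sets in which no single
#' fragment carries all attachment points are discarded — the core must host
#' every substituent. Size constraints are applied as post-hoc filters.
#'
#' @param compound a SMILES string.
#' @param level integer 1, 2 or 3: number of bonds cut simultaneously.
#' @param constraints a [fragmentation_constraints()] object.
#' @param compound_id optional identifier carried into the result.
#' @return data.frame with columns `compound_id`, `level`, `key`,
#'   `values` (list column), `values_str`, `key_heavy`. Zero rows when the
#'   molecule has no qualifying cut set (not an error).
#' @examples
#' \donttest{
#' enumerate_fragmentations("CCc1ccccc1", level = 1,
#'   fragmentation_constraints(min_key_heavy_atoms = 1))
#' }
#' @export
enumerate_fragmentations <- function(compound, level,
                                     constraints = fragmentation_constraints(),
                                     compound_id = NA_character_) {
  if (!level %in% 1:3) stop("level must be 1, 2 or 3", call. = FALSE)
  g <- if (inherits(compound, "mol_graph")) compound else {
    gg <- smiles_to_graphs(normalize_attachments(compound))[[1]]
    if (is.null(gg))
      stop("enumerate_fragmentations: could not parse '", compound, "'",
           call. = FALSE)
    gg
  }
  if (count_heavy(g) < 2L)
    stop("enumerate_fragmentations: compound must have >= 2 heavy atoms",
         call. = FALSE)
  res <- enumerate_on_graph(g, as.integer(level), constraints)
  if (nrow(res)) {
    res <- cbind(data.frame(compound_id = compound_id,
                            level = as.integer(level)), res)
  } else {
    res <- data.frame(compound_id = character(0), level = integer(0),
                      key = character(0), values_str = character(0),
                      key_heavy = integer(0))
    res$values <- list()
  }
  res
}

#' Build per-level fragment indexes for a compound set
#'
#' Fragments every compound at each requested cut level and indexes the
#' results by canonical key. The index is the basis for matched molecular
#' series detection: all compounds sharing a key form one series.
#'
#' @param cset a [compound_set()].
#' @param levels integer vector, subset of 1:3.
#' @param constraints a [fragmentation_constraints()] object.
#' @return object of class `fragment_index`: a named list (one element per
#'   level, names `"1"`, `"2"`, `"3"`) of data.frames with columns
#'   `compound_id`, `level`, `key`, `values_str`, `values`, `key_heavy`.
#' @export
build_index <- function(cset, levels = 1L,
                        constraints = fragmentation_constraints()) {
  stopifnot(inherits(cset, "compound_set"))
  if (!length(levels)) {
    warning("build_index: empty `levels`; returning empty index")
    return(structure(list(), constraints = constraints,
                     class = "fragment_index"))
  }
  stopifnot(all(levels %in% 1:3))
  if (!nrow(cset$compounds)) stop("build_index: empty compound set")
  graphs <- smiles_to_graphs(cset$compounds$structure)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad))
    warning("build_index: ", sum(bad), " compound(s) failed to parse; skipped")
  out <- list()
  for (lv in sort(unique(as.integer(levels)))) {
    per <- lapply(which(!bad), function(i) {
      r <- enumerate_on_graph(graphs[[i]], lv, constraints)
      if (nrow(r))
        cbind(data.frame(compound_id = cset$compounds$compound_id[i],
                         level = lv), r)
      else NULL
    })
    per <- per[!vapply(per, is.null, logical(1))]
    tab <- if (length(per)) do.call(rbind, per) else {
      t0 <- data.frame(compound_id = character(0), level = integer(0),
                       key = character(0), values_str = character(0),
                       key_heavy = integer(0))
      t0$values <- list()
      t0
    }
    tab <- tab[order(tab$key, tab$values_str, tab$compound_id), , drop = FALSE]
    rownames(tab) <- NULL
    out[[as.character(lv)]] <- tab
  }
  structure(out, constraints = constraints, class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  cat("<fragment_index>\n")
  for (lv in names(x)) {
    cat(sprintf("  level %s: %d fragmentations, %d distinct keys, %d compounds\n",
                lv, nrow(x[[lv]]), length(unique(x[[lv]]$key)),
                length(unique(x[[lv]]$compound_id))))
  }
  invisible(x)
}

#' Write a fragment index to TSV
#'
#' One row per fragmentation: level, key, value_1..value_3, compound_id.
#'
#' @param index a `fragment_index`.
#' @param path output file path.
#' @export
write_fragment_index <- function(index, path) {
  rows <- do.call(rbind, lapply(names(index), function(lv) {
    tab <- index[[lv]]
    vals <- t(vapply(tab$values, function(v) c(v, rep("", 3 - length(v)))[1:3],
                     character(3)))
    if (!nrow(tab)) vals <- matrix(character(0), ncol = 3)
    data.frame(level = tab$level, key = tab$key,
               value_1 = vals[, 1], value_2 = vals[, 2], value_3 = vals[, 3],
               compound_id = tab$compound_id)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
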