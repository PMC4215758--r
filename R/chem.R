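## Core chemistry layer: canonicalization, molecular graphs, fragments.
##
## All structure comparison in the package is string equality of canonical
## isomeric SMILES produced by Open Babel (via ChemmineOB). Fragments carry
## attachment points as isotope-labelled dummy atoms: [1*], [2*], [3*] for
## first-level cut sites and [9*] for the second-level (core MMP) cut site.
## The older map-style notation [*:1] is accepted on input and converted.

#' @importFrom stats setNames
NULL

## ---- Open Babel conversion -------------------------------------------------

ob_convert <- function(from, to, text) {
  ChemmineOB::convertFormat(from, to, text)
}

## Normalize attachment-point notation: [*:1] -> [1*], bare [*] -> [1*] only
## when it is the sole attachment point.
normalize_attachments <- function(s) {
  s <- gsub("\\[\\*:([0-9])\\]", "[\\1*]", s)
  one_bare <- !grepl("\\[[0-9]\\*\\]", s) &
    vapply(gregexpr("\\[\\*\\]", s),
           function(m) sum(m > 0) == 1L, logical(1))
  s[one_bare] <- sub("\\[\\*\\]", "[1*]", s[one_bare])
  s
}

## Vectorized canonical SMILES via one batched Open Babel call.
## Returns a character vector aligned with `smiles`; failures are NA.
## A malformed record can abort the rest of the stream, so entries missing
## from the batch output are retried individually before being declared
## unparsable.
canon_smiles_vec <- function(smiles, retry = TRUE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  src <- paste0(smiles, " zz", seq_len(n), "\n", collapse = "")
  out <- ob_convert("SMI", "CAN", src)
  res <- rep(NA_character_, n)
  if (length(out) && nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) < 2L) next
      idx <- suppressWarnings(as.integer(sub("^zz", "", p[2])))
      if (!is.na(idx)) res[idx] <- p[1]
    }
  }
  if (retry && anyNA(res) && n > 1L) {
    for (i in which(is.na(res)))
      res[i] <- canon_smiles_vec(smiles[i], retry = FALSE)
  }
  res
}

#' Canonical structure string
#'
#' Converts one or more structure line notations (SMILES) to the package-wide
#' canonical isomeric form. Canonicalization is idempotent and invariant to
#' input atom ordering, so two notations of the same molecular graph map to
#' the same string; every structure comparison downstream (matrix cell
#' identity, virtual-compound deduplication) is string equality on this form.
#'
#' Multi-fragment inputs (salts, mixtures) are reduced to their largest
#' organic component with a warning, since fragmentation assumes a single
#' connected molecule.
#'
#' @param text character vector of SMILES strings.
#' @param on_error `"stop"` (default) to raise an error naming the offending
#'   input, or `"na"` to return `NA` for unparsable entries.
#' @param strip_salts keep only the largest organic fragment of
#'   multi-fragment inputs (default `TRUE`).
#' @return character vector of canonical SMILES.
#' @examples
#' \donttest{
#' canonical_structure(c("OCC", "C1=CC=CC=C1"))
#' }
#' @export
canonical_structure <- function(text, on_error = c("stop", "na"),
                                strip_salts = TRUE) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(text))
  res <- canon_smiles_vec(text)
  bad <- is.na(res)
  if (any(bad) && on_error == "stop") {
    stop("canonical_structure: could not parse input(s): ",
         paste(sprintf("'%s' (entry %d)", text[bad], which(bad)),
               collapse = ", "), call. = FALSE)
  }
  dotted <- which(!is.na(res) & grepl(".", res, fixed = TRUE))
  if (length(dotted)) {
    if (strip_salts) {
      warning("multi-fragment input(s); keeping largest organic fragment: ",
              paste(text[dotted], collapse = ", "), call. = FALSE)
      res[dotted] <- vapply(res[dotted], largest_organic_fragment,
                            character(1), USE.NAMES = FALSE)
    } else if (on_error == "stop") {
      stop("canonical_structure: multi-fragment input(s): ",
           paste(text[dotted], collapse = ", "), call. = FALSE)
    } else {
      res[dotted] <- NA_character_
    }
  }
  res
}

largest_organic_fragment <- function(canon) {
  parts <- strsplit(canon, ".", fixed = TRUE)[[1]]
  gs <- smiles_to_graphs(parts)
  nheavy <- vapply(gs, function(g) {
    if (is.null(g)) return(0L) else count_heavy(g)
  }, integer(1))
  has_c <- vapply(gs, function(g) {
    !is.null(g) && any(g$atoms$elem %in% c("C"))
  }, logical(1))
  pool <- if (any(has_c)) which(has_c) else seq_along(parts)
  best <- pool[order(-nheavy[pool], parts[pool])][1]
  canon_smiles_vec(parts[best])
}

## ---- Molecular graphs ------------------------------------------------------

## A mol_graph is list(atoms = data.frame(elem, charge, iso), bonds =
## data.frame(a1, a2, order)). Attachment points are elem "*" with the label
## in `iso`. Explicit hydrogens, when present in the input, are retained but
## never counted as heavy atoms and never cut.

mol_graph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

count_heavy <- function(g) sum(!(g$atoms$elem %in% c("H", "*")))

attachment_labels <- function(g) sort(g$atoms$iso[g$atoms$elem == "*"])

parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb) return(NULL)
  al <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    elem   = trimws(substr(al, 32, 34)),
    charge = 0L, iso = 0L,
    stringsAsFactors = FALSE)
  bl <- if (nb > 0) lines[4L + na + seq_len(nb)] else character(0)
  bonds <- data.frame(
    a1 = as.integer(substr(bl, 1, 3)),
    a2 = as.integer(substr(bl, 4, 6)),
    order = as.integer(substr(bl, 7, 9)))
  for (ml in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    toks <- strsplit(trimws(ml), "[[:space:]]+")[[1]]
    kind <- toks[2]; np <- as.integer(toks[3])
    for (k in seq_len(np)) {
      a <- as.integer(toks[2 + 2 * k]); v <- as.integer(toks[3 + 2 * k])
      if (kind == "CHG") atoms$charge[a] <- v else atoms$iso[a] <- v
    }
  }
  mol_graph(atoms, bonds)
}

## title is returned on the first line of each record, used for alignment.
graph_to_molblock <- function(g, title = "m") {
  na <- nrow(g$atoms); nb <- nrow(g$bonds)
  out <- c(title, " sarmatrix", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
           sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   g$atoms$elem))
  if (nb > 0)
    out <- c(out, sprintf("%3d%3d%3d  0", g$bonds$a1, g$bonds$a2, g$bonds$order))
  prop_lines <- function(idx, val, tag) {
    res <- character(0)
    while (length(idx)) {
      k <- min(8L, length(idx))
      res <- c(res, paste0(sprintf("M  %s%3d", tag, k),
                           paste0(sprintf("%4d%4d", idx[seq_len(k)],
                                          val[seq_len(k)]), collapse = "")))
      idx <- idx[-seq_len(k)]; val <- val[-seq_len(k)]
    }
    res
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) out <- c(out, prop_lines(chg, g$atoms$charge[chg], "CHG"))
  iso <- which(g$atoms$iso != 0L)
  if (length(iso)) out <- c(out, prop_lines(iso, g$atoms$iso[iso], "ISO"))
  c(out, "M  END", "$$$$")
}

## SMILES -> list of mol_graph (NULL where parsing failed), batched; as
## above, entries missing from the batch output are retried singly.
smiles_to_graphs <- function(smiles, retry = TRUE) {
  n <- length(smiles)
  if (n == 0L) return(list())
  src <- paste0(smiles, " zz", seq_len(n), "\n", collapse = "")
  out <- ob_convert("SMI", "SDF", src)
  res <- vector("list", n)
  if (length(out) && nzchar(out)) {
    recs <- strsplit(out, "$$$$\n", fixed = TRUE)[[1]]
    for (rec in recs) {
      rec <- sub("^\n+", "", rec)
      if (!nzchar(trimws(rec))) next
      title <- strsplit(rec, "\n", fixed = TRUE)[[1]][1]
      idx <- suppressWarnings(as.integer(sub("^zz", "", trimws(title))))
      if (is.na(idx)) next
      res[[idx]] <- parse_molblock(rec)
    }
  }
  if (retry && n > 1L) {
    for (i in which(vapply(res, is.null, logical(1))))
      res[i] <- smiles_to_graphs(smiles[i], retry = FALSE)
  }
  res
}

## list of mol_graph -> canonical SMILES vector (NA where failed), batched.
graphs_to_smiles <- function(graphs) {
  n <- length(graphs)
  if (n == 0L) return(character(0))
  blocks <- unlist(lapply(seq_len(n), function(i)
    graph_to_molblock(graphs[[i]], title = paste0("zz", i))))
  out <- ob_convert("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  res <- rep(NA_character_, n)
  if (!length(out) || !nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (p in strsplit(lines, "\t", fixed = TRUE)) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^zz", "", p[2])))
    if (!is.na(idx)) res[idx] <- p[1]
  }
  res
}

## ---- Fragment construction -------------------------------------------------

## Extract the fragment induced by `atom_idx`, adding one dummy atom per cut.
## `cuts` is a data.frame(inside = atom index within atom_idx (original
## numbering), label = attachment label).
induced_fragment <- function(g, atom_idx, cuts) {
  remap <- setNames(seq_along(atom_idx), atom_idx)
  atoms <- g$atoms[atom_idx, , drop = FALSE]
  keep <- g$bonds$a1 %in% atom_idx & g$bonds$a2 %in% atom_idx
  bonds <- g$bonds[keep, , drop = FALSE]
  bonds$a1 <- remap[as.character(bonds$a1)]
  bonds$a2 <- remap[as.character(bonds$a2)]
  for (k in seq_len(nrow(cuts))) {
    atoms <- rbind(atoms, data.frame(elem = "*", charge = 0L,
                                     iso = cuts$label[k]))
    bonds <- rbind(bonds, data.frame(a1 = remap[as.character(cuts$inside[k])],
                                     a2 = nrow(atoms), order = 1L))
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  mol_graph(atoms, bonds)
}

## Relabel attachment points: new label = perm[old label] for labels in
## `permutable`; others untouched.
relabel_attachments <- function(g, perm, permutable = seq_along(perm)) {
  sel <- g$atoms$elem == "*" & g$atoms$iso %in% permutable
  g$atoms$iso[sel] <- perm[g$atoms$iso[sel]]
  g
}

label_perms <- function(L) {
  if (L == 1L) return(list(1L))
  if (L == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

#' Canonical fragment string
#'
#' Canonicalizes a fragment (a structure carrying one or more attachment
#' points written as `[1*]`, `[2*]`, ... or `[*:n]`). The result is invariant
#' to input atom ordering. For fragments with two or more attachment points
#' the labels are renumbered so that the canonical string is the
#' lexicographically smallest over all label permutations; the permutation
#' applied is returned as attribute `"perm"` (`perm[i]` is the new label of
#' old label `i`), so that substituent tuples can be re-ordered consistently.
#'
#' @param fragment a single fragment SMILES with >= 1 attachment point.
#' @return canonical fragment string with attribute `"perm"`.
#' @export
canonical_fragment <- function(fragment) {
  stopifnot(is.character(fragment), length(fragment) == 1L)
  fragment <- normalize_attachments(fragment)
  g <- smiles_to_graphs(fragment)[[1]]
  if (is.null(g))
    stop("canonical_fragment: could not parse '", fragment, "'", call. = FALSE)
  labs <- attachment_labels(g)
  L <- length(labs)
  if (L == 0L)
    stop("canonical_fragment: '", fragment, "' has no attachment point",
         call. = FALSE)
  ## compact existing labels to 1..L first (order-preserving)
  compact <- setNames(seq_len(L), labs)
  sel <- g$atoms$elem == "*"
  g$atoms$iso[sel] <- compact[as.character(g$atoms$iso[sel])]
  perms <- label_perms(L)
  cand <- lapply(perms, function(p) relabel_attachments(g, p))
  strs <- graphs_to_smiles(cand)
  best <- which(strs == min(strs))[1]
  structure(strs[best], perm = setNames(perms[[best]], labs))
}

## Internal: canonicalize a key fragment graph whose permutable labels are
## 1..L (label 9, the second-level cut site, is held fixed). Returns
## list(key = string, perm = integer L-vector).
canonical_key_graph <- function(g, L) {
  if (L <= 1L) {
    return(list(key = graphs_to_smiles(list(g)), perm = 1L))
  }
  perms <- label_perms(L)
  cand <- lapply(perms, function(p)
    relabel_attachments(g, p, permutable = seq_len(L)))
  strs <- graphs_to_smiles(cand)
  best <- which(strs == min(strs))[1]
  list(key = strs[best], perm = perms[[best]])
}

#' Reassemble a key and substituent fragments into a structure
#'
#' Forms single bonds between attachment point `at[i]` of the key and the
#' (single) attachment point of `values[[i]]`, removes the dummy atoms, and
#' returns the canonical structure. When all attachment points of the key are
#' filled the result is a molecule; filling a subset yields a fragment that
#' retains the remaining attachment points. This is both the virtual-compound
#' generator and the fragmentation round-trip oracle.
#'
#' @param key fragment string whose attachment points are to be substituted.
#' @param values character vector of single-attachment fragments.
#' @param at integer labels of the key attachment points to fill; default all
#'   labels in increasing order.
#' @return canonical SMILES of the assembled structure.
#' @export
reassemble <- function(key, values, at = NULL) {
  key <- normalize_attachments(key)
  values <- normalize_attachments(unlist(values))
  gs <- smiles_to_graphs(c(key, values))
  gk <- gs[[1]]
  if (is.null(gk)) stop("reassemble: could not parse key '", key, "'",
                        call. = FALSE)
  labs <- attachment_labels(gk)
  if (is.null(at)) at <- labs
  if (length(values) != length(at))
    stop("reassemble: key expects ", length(at), " value(s) at (",
         paste(at, collapse = ","), "), got ", length(values), call. = FALSE)
  if (!all(at %in% labs))
    stop("reassemble: key has no attachment point(s) ",
         paste(setdiff(at, labs), collapse = ","), call. = FALSE)
  gvs <- gs[-1]
  bad <- vapply(gvs, is.null, logical(1))
  if (any(bad))
    stop("reassemble: could not parse value(s) ",
         paste(values[bad], collapse = ", "), call. = FALSE)
  g <- assemble_from_graphs(gk, gvs, at)
  out <- graphs_to_smiles(list(g))
  if (is.na(out)) stop("reassemble: assembly failed for key '", key, "'",
                       call. = FALSE)
  out
}

## Graph-level assembly: join value graphs onto the key's attachment points
## `at`, return the merged graph with the consumed dummies removed.
assemble_from_graphs <- function(gk, gvs, at) {
  atoms <- gk$atoms; bonds <- gk$bonds
  join_a <- integer(0); join_b <- integer(0)
  drop <- integer(0)
  for (j in seq_along(at)) {
    gv <- gvs[[j]]
    vstars <- which(gv$atoms$elem == "*")
    if (length(vstars) != 1L)
      stop("assemble: value fragment must carry exactly one attachment point",
           call. = FALSE)
    off <- nrow(atoms)
    atoms <- rbind(atoms, gv$atoms)
    vb <- gv$bonds; vb$a1 <- vb$a1 + off; vb$a2 <- vb$a2 + off
    bonds <- rbind(bonds, vb)
    kstar <- which(gk$atoms$elem == "*" & gk$atoms$iso == at[j])
    join_a <- c(join_a, other_end(gk$bonds, kstar))
    join_b <- c(join_b, other_end(gv$bonds, vstars) + off)
    drop <- c(drop, kstar, vstars + off)
  }
  bonds <- rbind(bonds, data.frame(a1 = join_a, a2 = join_b, order = 1L))
  drop_atoms(mol_graph(atoms, bonds), drop)
}

other_end <- function(bonds, atom) {
  hit <- which(bonds$a1 == atom | bonds$a2 == atom)
  if (length(hit) != 1L) stop("attachment point must have exactly one bond")
  if (bonds$a1[hit] == atom) bonds$a2[hit] else bonds$a1[hit]
}

drop_atoms <- function(g, idx) {
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  remap <- setNames(seq_along(keep), keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  sel <- g$bonds$a1 %in% keep & g$bonds$a2 %in% keep
  bonds <- g$bonds[sel, , drop = FALSE]
  bonds$a1 <- remap[as.character(bonds$a1)]
  bonds$a2 <- remap[as.character(bonds$a2)]
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  mol_graph(atoms, bonds)
}
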