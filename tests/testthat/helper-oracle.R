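## Independent brute-force oracles. These re-derive fragmentations and MMPs
## from first principles — plain-R breadth-first search for connectivity and
## ring detection, exhaustive subset enumeration — sharing only the SMILES
## serialization layer with the implementation under test.

## Adjacency list from a bond table.
adj_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  adj
}

## Connected component labels after removing the bonds in `cut` (BFS).
bfs_components <- function(g, cut = integer(0)) {
  n <- nrow(g$atoms)
  keep <- setdiff(seq_len(nrow(g$bonds)), cut)
  adj <- vector("list", n)
  for (b in keep) {
    a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

## A bond is acyclic iff removing it disconnects its endpoints.
oracle_acyclic_bonds <- function(g) {
  vapply(seq_len(nrow(g$bonds)), function(b) {
    comp <- bfs_components(g, b)
    comp[g$bonds$a1[b]] != comp[g$bonds$a2[b]]
  }, logical(1))
}

## Exhaustive fragmentation: every `level`-subset of acyclic single bonds
## between heavy atoms, key-connectivity rule, size constraints, canonical
## label choice by minimum over permutations. Returns sorted
## "key SPACE values_str" strings for set comparison.
oracle_fragmentations <- function(smiles, level, constraints) {
  g <- sarmatrix:::smiles_to_graphs(smiles)[[1]]
  heavy <- !(g$atoms$elem %in% c("H", "*"))
  total <- sum(heavy)
  ok <- g$bonds$order == 1L & heavy[g$bonds$a1] & heavy[g$bonds$a2] &
    oracle_acyclic_bonds(g)
  cand_bonds <- which(ok)
  if (length(cand_bonds) < level) return(character(0))
  out <- character(0)
  for (S in utils::combn(cand_bonds, level, simplify = FALSE)) {
    comp <- bfs_components(g, S)
    touch <- lapply(seq_len(level), function(i)
      c(comp[g$bonds$a1[S[i]]], comp[g$bonds$a2[S[i]]]))
    all_comps <- Reduce(intersect, touch)
    key_comps <- if (level == 1L) all_comps else all_comps
    for (kc in key_comps) {
      key_heavy <- sum(heavy[comp == kc])
      val_comps <- vapply(seq_len(level), function(i)
        setdiff(touch[[i]], kc)[1], numeric(1))
      if (anyNA(val_comps)) next
      val_heavy <- vapply(val_comps, function(vc) sum(heavy[comp == vc]),
                          numeric(1))
      if (any(val_heavy > constraints$max_value_heavy_atoms)) next
      if (key_heavy < constraints$min_key_heavy_atoms) next
      if (constraints$key_must_be_larger && 2 * key_heavy < total) next
      ## key fragment, all label permutations; values with label 1
      kg_base <- sarmatrix:::induced_fragment(
        g, which(comp == kc),
        data.frame(inside = vapply(seq_len(level), function(i) {
          a <- g$bonds$a1[S[i]]
          if (comp[a] == kc) a else g$bonds$a2[S[i]]
        }, integer(1)), label = seq_len(level)))
      perms <- sarmatrix:::label_perms(level)
      kstrs <- sarmatrix:::graphs_to_smiles(lapply(perms, function(p)
        sarmatrix:::relabel_attachments(kg_base, p, seq_len(level))))
      best <- which(kstrs == min(kstrs))[1]
      vstrs <- sarmatrix:::graphs_to_smiles(lapply(seq_len(level), function(i) {
        a <- g$bonds$a1[S[i]]
        vin <- if (comp[a] == kc) g$bonds$a2[S[i]] else a
        sarmatrix:::induced_fragment(g, which(comp == val_comps[i]),
                                     data.frame(inside = vin, label = 1L))
      }))
      ordered <- character(level)
      ordered[perms[[best]]] <- vstrs
      out <- c(out, paste(kstrs[best], paste(ordered, collapse = "|")))
    }
  }
  sort(unique(out))
}

## Engine output in the same "key SPACE values_str" form.
engine_fragmentations <- function(smiles, level, constraints) {
  f <- enumerate_fragmentations(smiles, level, constraints)
  sort(unique(paste(f$key, f$values_str)))
}

## O(n^2) pairwise MMP detection: two compounds form an MMP iff they share a
## key (same canonical core, different value combination) at the given
## level. Returns sorted "idA<idB" pair labels.
oracle_mmps <- function(cset, level, constraints) {
  per <- lapply(seq_len(nrow(cset$compounds)), function(i)
    enumerate_fragmentations(cset$compounds$structure[i], level, constraints,
                             compound_id = cset$compounds$compound_id[i]))
  ids <- cset$compounds$compound_id
  pairs <- character(0)
  n <- length(ids)
  if (n < 2) return(pairs)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (length(intersect(per[[i]]$key, per[[j]]$key))) {
      ab <- sort(c(ids[i], ids[j]))
      pairs <- c(pairs, paste(ab[1], ab[2], sep = "<"))
    }
  }
  sort(unique(pairs))
}

## MMPs implied by the series route: all member pairs of every series.
series_mmps <- function(cset, level, constraints) {
  idx <- build_index(cset, levels = level, constraints = constraints)
  ser <- matched_series(idx)
  pairs <- character(0)
  for (s in ser) {
    ids <- s$members$compound_id
    if (length(ids) < 2) next
    comb <- utils::combn(sort(ids), 2)
    pairs <- c(pairs, paste(comb[1, ], comb[2, ], sep = "<"))
  }
  sort(unique(pairs))
}

## Batched round-trip check: every fragmentation of `smiles` at `level`
## reassembles to the parent canonical structure.
roundtrip_all <- function(smiles, level, constraints) {
  f <- enumerate_fragmentations(smiles, level, constraints)
  if (!nrow(f)) return(TRUE)
  frag_strs <- unique(c(f$key, unlist(f$values)))
  gs <- sarmatrix:::smiles_to_graphs(frag_strs)
  names(gs) <- frag_strs
  built <- lapply(seq_len(nrow(f)), function(i) {
    gk <- gs[[f$key[i]]]
    sarmatrix:::assemble_from_graphs(gk, gs[f$values[[i]]],
                                     at = sarmatrix:::attachment_labels(gk))
  })
  all(sarmatrix:::graphs_to_smiles(built) == canonical_structure(smiles))
}
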