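# BRICS fragmentation on the atom graph.
#
# The retrosynthetic BRICS scheme (Degen et al., ChemMedChem 2008) defines
# sixteen chemical environments (L1..L16) and a table of environment pairs
# whose connecting acyclic bond may be cleaved.  We identify the cleavable
# bonds on the original heavy-atom graph and take connected components of
# what remains as the fragments, so the result is always a partition of
# the atom set -- no dummy/attachment atoms are introduced.  Formal
# charges are not tracked by the parser, so all atoms are treated as
# neutral when matching environments (the aromatic-nitrogen environment
# L9 requires charge zero).

# Precompute per-atom context used by the environment predicates.
brics_context <- function(graph) {
  n <- graph$num_atoms
  bl <- graph$bond_list
  bt <- if (nrow(bl) > 0) graph$bond_features[, 1L] else integer(0)
  elem <- graph$element
  arom <- graph$aromatic_atom
  if (is.null(elem) || is.null(arom)) {
    stop("graph lacks element/aromaticity annotations; use parse_smiles()")
  }

  ring_bond <- rep(FALSE, nrow(bl))
  if (nrow(bl) > 0) {
    ig <- igraph::make_graph(edges = as.vector(t(bl)), n = n,
                             directed = FALSE)
    br <- igraph::bridges(ig)
    ring_bond[] <- TRUE
    ring_bond[as.integer(br)] <- FALSE
  }
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    ring_atom[unique(as.vector(bl[ring_bond, , drop = FALSE]))] <- TRUE
  }

  # incidence: for each atom, indices of its bonds and the partner atom
  inc <- vector("list", n)
  if (nrow(bl) > 0) {
    for (b in seq_len(nrow(bl))) {
      u <- bl[b, 1L]; v <- bl[b, 2L]
      inc[[u]] <- c(inc[[u]], b)
      inc[[v]] <- c(inc[[v]], b)
    }
  }
  partner <- function(b, a) if (bl[b, 1L] == a) bl[b, 2L] else bl[b, 1L]

  list(n = n, bl = bl, bt = bt, elem = elem, arom = arom,
       ring_bond = ring_bond, ring_atom = ring_atom,
       deg = vapply(inc, length, integer(1)), inc = inc, partner = partner)
}

# Evaluate all sixteen BRICS environments for every atom; returns a
# logical matrix atoms x 16.
brics_environments <- function(ctx) {
  n <- ctx$n
  E <- matrix(FALSE, n, 16L)
  elem <- ctx$elem; arom <- ctx$arom; deg <- ctx$deg
  bt <- ctx$bt; ring_bond <- ctx$ring_bond; ring_atom <- ctx$ring_atom

  for (a in seq_len(n)) {
    bonds <- ctx$inc[[a]]
    nb <- vapply(bonds, function(b) ctx$partner(b, a), integer(1))
    btypes <- bt[bonds]
    rings <- ring_bond[bonds]
    nb_elem <- elem[nb]
    nb_arom <- arom[nb]

    has_dblO <- any(btypes == 2L & nb_elem == "O")
    # single-or-aromatic bond to C/N/O (the SMARTS default bond order)
    sa_CNO <- btypes %in% c(1L, 4L) & nb_elem %in% c("C", "N", "O")
    single_acyclic <- btypes == 1L & !rings

    if (elem[a] == "C" && !arom[a]) {
      # L1: acyl carbon, three heavy neighbors, =O plus a C/N/O neighbor
      E[a, 1L] <- deg[a] == 3L && has_dblO && any(sa_CNO)
      # L4: sp3-ish carbon with an acyclic single bond to carbon
      E[a, 4L] <- deg[a] != 1L && !any(btypes == 2L) &&
        any(single_acyclic & nb_elem == "C")
      # L6: acyclic acyl carbon bonded to C/N/O via acyclic single bond
      E[a, 6L] <- deg[a] == 3L && !ring_atom[a] && has_dblO &&
        any(single_acyclic & nb_elem %in% c("C", "N", "O"))
      # L7: alkene carbon (degree 2-3) with a single bond to carbon
      E[a, 7L] <- deg[a] %in% c(2L, 3L) && any(btypes == 1L & nb_elem == "C")
      # L8: acyclic carbon, all bonds single, not terminal
      E[a, 8L] <- !ring_atom[a] && deg[a] != 1L && all(btypes == 1L)
      # L13: ring carbon between a C/N/O/S and a heteroatom, single ring bonds
      inA <- btypes == 1L & rings & !nb_arom & nb_elem %in% c("C", "N", "O", "S")
      inB <- inA & nb_elem %in% c("N", "O", "S")
      E[a, 13L] <- sum(inB) >= 1L && sum(inA) >= 2L
      # L15: ring carbon flanked by two ring carbons via single bonds
      E[a, 15L] <- sum(btypes == 1L & rings & !nb_arom & nb_elem == "C") >= 2L
    }
    if (elem[a] == "C" && arom[a]) {
      aromAny <- btypes == 4L & nb_arom & nb_elem %in% c("C", "N", "O", "S")
      aromHet <- aromAny & nb_elem %in% c("N", "O", "S")
      # L14: aromatic carbon adjacent to an aromatic heteroatom
      E[a, 14L] <- sum(aromHet) >= 1L && sum(aromAny) >= 2L
      # L16: aromatic carbon between two aromatic carbons
      E[a, 16L] <- sum(btypes == 4L & nb_arom & nb_elem == "C") >= 2L
    }
    if (elem[a] == "O" && !arom[a]) {
      # L3: ether-like oxygen with an acyclic single bond to carbon
      E[a, 3L] <- deg[a] == 2L && any(single_acyclic & nb_elem == "C")
    }
    if (elem[a] == "N" && !arom[a]) {
      lactam <- FALSE
      if (ring_atom[a]) {
        for (k in seq_along(bonds)) {
          if (!rings[k] || nb_elem[k] != "C") next
          cb <- ctx$inc[[nb[k]]]
          if (any(bt[cb] == 2L &
                  elem[vapply(cb, function(b) ctx$partner(b, nb[k]),
                              integer(1))] == "O")) {
            lactam <- TRUE
            break
          }
        }
      }
      # L5: amine nitrogen -- no double bonds, only C/S single-bond
      # partners, and not a lactam nitrogen
      E[a, 5L] <- deg[a] != 1L && !any(btypes == 2L) &&
        !any(btypes == 1L & !(nb_elem %in% c("C", "S"))) && !lactam
      # L10: cyclic amide nitrogen
      if (ring_atom[a]) {
        acylRing <- vapply(seq_along(bonds), function(k) {
          if (!rings[k] || nb_elem[k] != "C" || nb_arom[k]) return(FALSE)
          cb <- ctx$inc[[nb[k]]]
          any(bt[cb] == 2L &
                elem[vapply(cb, function(b) ctx$partner(b, nb[k]),
                            integer(1))] == "O")
        }, logical(1))
        # one ring bond to an acyl carbon and a second ring bond to a
        # C/N/O/S (which may itself be another acyl carbon)
        otherRing <- rings & !nb_arom & nb_elem %in% c("C", "N", "O", "S")
        E[a, 10L] <- any(acylRing) && sum(otherRing) >= 2L
      }
    }
    if (elem[a] == "N" && arom[a]) {
      aromOk <- btypes == 4L & nb_arom & nb_elem %in% c("C", "N", "O", "S")
      E[a, 9L] <- sum(aromOk) >= 2L
    }
    if (elem[a] == "S" && !arom[a]) {
      E[a, 11L] <- deg[a] == 2L && any(single_acyclic & nb_elem == "C")
      E[a, 12L] <- deg[a] == 4L && sum(btypes == 2L & nb_elem == "O") >= 2L &&
        any(btypes %in% c(1L, 4L) & nb_elem == "C")
    }
  }
  E
}

# Environment pairs whose connecting bond is cleavable; all pairs use an
# acyclic single bond except (7,7) which cleaves an acyclic double bond.
.brics_pairs <- rbind(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 14), c(5, 16), c(5, 13), c(5, 15),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16),
  c(16, 16)
)

#' Find BRICS-cleavable bonds
#'
#' Identifies the acyclic bonds of a molecule whose two end atoms match a
#' compatible pair of BRICS chemical environments.  These are the bonds a
#' retrosynthetic decomposition would break.
#'
#' @param graph A `molecular_graph` from [parse_smiles()].
#' @return Integer matrix with one row per cleavable bond (two atom
#'   indices, smaller first); zero rows if nothing is cleavable.
#' @export
brics_bonds <- function(graph) {
  validate_graph(graph)
  empty <- matrix(integer(0), 0L, 2L)
  if (nrow(graph$bond_list) == 0L) return(empty)
  ctx <- brics_context(graph)
  E <- brics_environments(ctx)
  cut <- logical(nrow(ctx$bl))
  for (b in seq_len(nrow(ctx$bl))) {
    if (ctx$ring_bond[b]) next
    u <- ctx$bl[b, 1L]; v <- ctx$bl[b, 2L]
    if (ctx$bt[b] == 1L) {
      for (p in seq_len(nrow(.brics_pairs))) {
        i <- .brics_pairs[p, 1L]; j <- .brics_pairs[p, 2L]
        if ((E[u, i] && E[v, j]) || (E[v, i] && E[u, j])) {
          cut[b] <- TRUE
          break
        }
      }
    } else if (ctx$bt[b] == 2L) {
      cut[b] <- E[u, 7L] && E[v, 7L]
    }
  }
  if (!any(cut)) return(empty)
  m <- ctx$bl[cut, , drop = FALSE]
  cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
}

#' Partition a molecule's atoms into BRICS fragments
#'
#' Deletes all BRICS-cleavable bonds (see [brics_bonds()]) and takes the
#' connected components of the remaining graph as fragments.  Fragments
#' are indexed in order of their smallest contained atom index, so the
#' assignment is deterministic.  A molecule with no cleavable bond is a
#' single fragment; disconnected input components fragment independently.
#'
#' @param graph A `molecular_graph`.
#' @return A `fragment_assignment`: list with `fragment_of_atom` (integer
#'   vector, one 1-based fragment index per atom) and `num_fragments`.
#' @export
brics_partition <- function(graph) {
  validate_graph(graph)
  stopifnot(graph$num_atoms >= 1L)
  cuts <- brics_bonds(graph)
  bl <- graph$bond_list
  if (nrow(bl) > 0 && nrow(cuts) > 0) {
    key <- paste(pmin(bl[, 1], bl[, 2]), pmax(bl[, 1], bl[, 2]))
    keep <- !(key %in% paste(cuts[, 1], cuts[, 2]))
    bl <- bl[keep, , drop = FALSE]
  }
  ig <- igraph::make_graph(edges = as.vector(t(bl)), n = graph$num_atoms,
                           directed = FALSE)
  comp <- igraph::components(ig)$membership
  # reindex components by smallest atom index
  first_atom <- tapply(seq_along(comp), comp, min)
  rank <- rank(first_atom)
  fa <- as.integer(rank[comp])
  structure(list(fragment_of_atom = fa,
                 num_fragments = max(fa)),
            class = "fragment_assignment")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat("<fragment_assignment> ", x$num_fragments, " fragment(s): ",
      paste(x$fragment_of_atom, collapse = " "), "\n", sep = "")
  invisible(x)
}
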