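# Discrete molecular graphs as padded one-hot tensors, and the probabilistic
# (soft) graphs emitted by the decoder. A molecular graph holds an m x p node
# matrix (atom type | formal charge | explicit-H one-hot blocks) and a
# symmetric m x m x q edge tensor over {single, double, triple, none}.
# Padding rows are one-hot on atom type "none", charge 0 and H-count 0;
# diagonal entries and edges touching a "none" node are one-hot on bond type
# "none", so every tensor cell has a defined value for the losses.

#' Construct a molecular graph from atom and bond tables
#'
#' @param atoms Data frame with columns `elem` (element symbol), `charge`
#'   (formal charge) and `h` (explicit hydrogen count), one row per heavy atom
#'   in input order.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1 = single, 2 = double, 3 = triple).
#' @param vocab A [feature_vocabulary()].
#' @return An object of class `molecular_graph` with fields `node` (m x p
#'   binary matrix), `edge` (m x m x q binary array), `n_heavy`, `atoms`,
#'   `bonds` and `vocab`.
#' @export
molecular_graph <- function(atoms, bonds, vocab) {
  stopifnot(inherits(vocab, "feature_vocab"))
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  m <- vocab$max_nodes
  if (n > m)
    abort_size(sprintf("molecule has %d heavy atoms but the vocabulary allows at most %d", n, m))
  a_idx <- match(atoms$elem, vocab$atom_types)
  c_idx <- match(as.integer(atoms$charge), vocab$formal_charges)
  h_idx <- match(as.integer(atoms$h), vocab$explicit_h_counts)
  if (anyNA(a_idx) || any(atoms$elem == "none"))
    abort_vocabulary("atom type outside the vocabulary")
  if (anyNA(c_idx)) abort_vocabulary("formal charge outside the vocabulary")
  if (anyNA(h_idx)) abort_vocabulary("explicit hydrogen count outside the vocabulary")
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n | bonds$i == bonds$j))
      abort_shape("bond endpoints out of range")
    if (!all(bonds$order %in% 1:3))
      abort_kekulization("bond order outside {single, double, triple}")
  }

  node <- matrix(0, m, vocab$p)
  node[cbind(seq_len(m), vocab$atom_cols[c(a_idx, rep(vocab$none_atom, m - n))])] <- 1
  node[cbind(seq_len(m), vocab$charge_cols[c(c_idx, rep(vocab$charge0, m - n))])] <- 1
  node[cbind(seq_len(m), vocab$h_cols[c(h_idx, rep(vocab$h0, m - n))])] <- 1

  edge <- array(0, dim = c(m, m, vocab$q))
  edge[, , vocab$none_bond] <- 1
  bond_channel <- match(c("single", "double", "triple"), vocab$bond_types)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]; ch <- bond_channel[bonds$order[r]]
      edge[i, j, ] <- 0; edge[j, i, ] <- 0
      edge[i, j, ch] <- 1; edge[j, i, ch] <- 1
    }
  }

  structure(list(node = node, edge = edge, n_heavy = n,
                 atoms = data.frame(elem = as.character(atoms$elem),
                                    charge = as.integer(atoms$charge),
                                    h = as.integer(atoms$h),
                                    stringsAsFactors = FALSE),
                 bonds = data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                                    order = as.integer(bonds$order)),
                 vocab = vocab),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$n_heavy, "heavy atoms,", nrow(x$bonds), "bonds, m =",
      x$vocab$max_nodes, "\n")
  invisible(x)
}

#' Featurize a parsed molecule into a one-hot molecular graph
#'
#' Molecules must already be kekulized (as produced by [parse_smiles()]); the
#' atom order of the input is preserved, absent bonds and padding nodes use
#' the `"none"` entries.
#'
#' @param mol A `parsed_mol` (from [parse_smiles()]) or a single SMILES string.
#' @param vocab A [feature_vocabulary()].
#' @return A [molecular_graph()].
#' @export
featurize <- function(mol, vocab) {
  if (is.character(mol)) {
    if (length(mol) != 1L) abort_format("featurize takes a single SMILES string")
    parsed <- suppressWarnings(parse_smiles(mol))[[1]]
    if (is.null(parsed)) abort_kekulization(sprintf("could not parse/kekulize '%s'", mol))
    mol <- parsed
  }
  if (!inherits(mol, "parsed_mol")) abort_format("mol must be a parsed_mol or SMILES string")
  molecular_graph(mol$atoms, mol$bonds, vocab)
}

#' Embed a discrete molecular graph as a probabilistic graph
#'
#' The one-hot tensors are reinterpreted as degenerate categorical
#' distributions; [decode_graph()] is its left inverse.
#'
#' @param g A [molecular_graph()].
#' @return A `probabilistic_graph`.
#' @export
one_hot <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  probabilistic_graph(g$node, g$edge, g$vocab, check = FALSE)
}

#' Construct a probabilistic graph
#'
#' @param node m x p matrix; each of the three one-hot blocks of each row must
#'   be a probability simplex (sum 1 within 1e-5).
#' @param edge m x m x q array, symmetric in its first two indices, each (i,j)
#'   slice a probability simplex.
#' @param vocab A [feature_vocabulary()].
#' @param check Validate the invariants (default TRUE).
#' @return An object of class `probabilistic_graph`.
#' @export
probabilistic_graph <- function(node, edge, vocab, check = TRUE) {
  stopifnot(inherits(vocab, "feature_vocab"))
  m <- vocab$max_nodes
  check_shape(all(dim(node) == c(m, vocab$p)), "node matrix must be m x p")
  check_shape(all(dim(edge) == c(m, m, vocab$q)), "edge tensor must be m x m x q")
  if (check) {
    tol <- 1e-5
    if (any(node < -tol) || any(node > 1 + tol) || any(edge < -tol) || any(edge > 1 + tol))
      abort_domain("probabilities must lie in [0, 1]")
    for (cols in list(vocab$atom_cols, vocab$charge_cols, vocab$h_cols)) {
      if (any(abs(rowSums(node[, cols, drop = FALSE]) - 1) > tol))
        abort_domain("each node one-hot block must sum to 1")
    }
    slice_sums <- apply(edge, c(1, 2), sum)
    if (any(abs(slice_sums - 1) > tol))
      abort_domain("each edge slice must sum to 1")
    for (ch in seq_len(vocab$q)) {
      if (!isTRUE(all.equal(edge[, , ch], t(edge[, , ch]), tolerance = 0)))
        abort_domain("edge tensor must be exactly symmetric")
    }
  }
  structure(list(node = node, edge = edge, vocab = vocab),
            class = "probabilistic_graph")
}

#' @export
print.probabilistic_graph <- function(x, ...) {
  cat("<probabilistic_graph> m =", x$vocab$max_nodes, " p =", x$vocab$p,
      " q =", x$vocab$q, "\n")
  invisible(x)
}

block_argmax <- function(mat, ties_lowest = TRUE) {
  max.col(mat, ties.method = "first")
}

#' Discretize a probabilistic graph by block-wise argmax
#'
#' Each one-hot block is replaced by its argmax (ties break to the lowest
#' vocabulary index); nodes whose atom-type argmax is `"none"` are dropped with
#' all incident edges, and the surviving nodes are compacted in order.
#'
#' @param pg A `probabilistic_graph`.
#' @param vocab Vocabulary; defaults to the one stored in `pg`.
#' @param largest_fragment If TRUE, keep only the largest connected component
#'   of the decoded graph (lowest-index component on ties). Default FALSE:
#'   possibly disconnected graphs are returned whole and judged whole by the
#'   validity reward.
#' @return A [molecular_graph()] (possibly empty).
#' @export
decode_graph <- function(pg, vocab = pg$vocab, largest_fragment = FALSE) {
  stopifnot(inherits(pg, "probabilistic_graph"))
  m <- vocab$max_nodes
  a_idx <- block_argmax(pg$node[, vocab$atom_cols, drop = FALSE])
  c_idx <- block_argmax(pg$node[, vocab$charge_cols, drop = FALSE])
  h_idx <- block_argmax(pg$node[, vocab$h_cols, drop = FALSE])
  keep <- which(a_idx != vocab$none_atom)
  atoms <- data.frame(elem = vocab$atom_types[a_idx[keep]],
                      charge = vocab$formal_charges[c_idx[keep]],
                      h = vocab$explicit_h_counts[h_idx[keep]],
                      stringsAsFactors = FALSE)
  bond_order <- match(vocab$bond_types, c("single", "double", "triple"))  # NA for none
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  k <- length(keep)
  if (k >= 2) {
    pr <- pair_index(k)
    lin <- (keep[pr[, 2]] - 1L) * m + keep[pr[, 1]]  # linear index into an m x m slice
    em <- matrix(0, nrow(pr), vocab$q)
    for (ch in seq_len(vocab$q)) {
      sl <- pg$edge[, , ch]
      em[, ch] <- sl[lin]
    }
    ch_arg <- block_argmax(em)  # ties -> lowest index
    ord <- bond_order[ch_arg]
    sel <- which(!is.na(ord))
    bonds <- data.frame(i = pr[sel, 1], j = pr[sel, 2], order = ord[sel])
  }
  g <- molecular_graph(atoms, bonds, vocab)
  if (largest_fragment && g$n_heavy > 0) {
    comp <- graph_components(g)
    sizes <- tabulate(comp)
    keep2 <- which(comp == which.max(sizes))
    g <- subgraph_of(g, keep2)
  }
  g
}

# Connected-component labels over heavy atoms (1-based, in discovery order).
graph_components <- function(g) {
  n <- g$n_heavy
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      adj[[g$bonds$i[r]]] <- c(adj[[g$bonds$i[r]]], g$bonds$j[r])
      adj[[g$bonds$j[r]]] <- c(adj[[g$bonds$j[r]]], g$bonds$i[r])
    }
  }
  lab <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (comp[v] == 0L) { comp[v] <- lab; queue <- c(queue, v) }
    }
  }
  comp
}

subgraph_of <- function(g, keep) {
  remap <- integer(g$n_heavy); remap[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  molecular_graph(g$atoms[keep, , drop = FALSE], b, g$vocab)
}

#' Relabel the nodes of a molecular graph
#'
#' Utility for permutation-invariance checks: node `i` of the result is node
#' `perm[i]` of the input.
#'
#' @param g A [molecular_graph()].
#' @param perm A permutation of `1:g$n_heavy`.
#' @return A [molecular_graph()] over the same vocabulary.
#' @export
permute_graph <- function(g, perm) {
  stopifnot(inherits(g, "molecular_graph"), length(perm) == g$n_heavy)
  inv <- integer(g$n_heavy); inv[perm] <- seq_len(g$n_heavy)
  b <- g$bonds
  if (nrow(b) > 0) { b$i <- inv[b$i]; b$j <- inv[b$j] }
  molecular_graph(g$atoms[perm, , drop = FALSE], b, g$vocab)
}

explicit_valences <- function(g) {
  ev <- g$atoms$h
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      ev[g$bonds$i[r]] <- ev[g$bonds$i[r]] + g$bonds$order[r]
      ev[g$bonds$j[r]] <- ev[g$bonds$j[r]] + g$bonds$order[r]
    }
  }
  ev
}

#' Chemical validity reward
#'
#' The external reward R: returns 1 when the graph passes the sanitization
#' rule -- every atom's explicit valence (bond orders plus the explicit
#' hydrogen count) is at most the maximum allowed valence for its element and
#' formal charge, remaining valence being filled with implicit hydrogens --
#' and 0 otherwise. The empty graph is invalid. Disconnected graphs are judged
#' whole (every fragment must pass).
#'
#' @param g A [molecular_graph()].
#' @return 0 or 1.
#' @export
validity_reward <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$n_heavy == 0L) return(0)
  ev <- explicit_valences(g)
  for (k in seq_len(g$n_heavy)) {
    if (!valence_ok(g$atoms$elem[k], g$atoms$charge[k], ev[k])) return(0)
  }
  1
}

# Atom/bond tables of the realized molecule: explicit hydrogens honored,
# remaining valence filled with implicit hydrogens (h_render = total H).
realized_tables <- function(g) {
  atoms <- g$atoms
  ev <- explicit_valences(g)
  atoms$h_render <- atoms$h + mapply(implicit_h_fill, atoms$elem, atoms$charge, ev)
  list(atoms = atoms, bonds = g$bonds)
}

#' Serialize a molecular graph to SMILES
#'
#' Every atom is written as a bracket atom carrying its total hydrogen count
#' (explicit plus implicit fill) and formal charge, so the string round-trips
#' exactly through standard toolkits. Fragments are joined with ".".
#'
#' @param g A non-empty [molecular_graph()].
#' @return A SMILES string.
#' @export
graph_to_smiles <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$n_heavy == 0L) abort_canonicalization("cannot serialize an empty graph")
  tb <- realized_tables(g)
  smiles_from_tables(tb$atoms, tb$bonds)
}

#' Canonical identity key of a valid molecular graph
#'
#' Canonical SMILES of the sanitized structure; invariant under node
#' permutation, used for deduplication and novelty.
#'
#' @param g A [molecular_graph()] with `validity_reward(g) == 1`.
#' @return A canonical SMILES string.
#' @export
canonical_key <- function(g) {
  if (validity_reward(g) != 1)
    abort_canonicalization("canonical_key requires a chemically valid graph")
  key <- canonicalize_smiles(graph_to_smiles(g))
  if (is.na(key)) abort_canonicalization("canonicalization failed")
  key
}

# Batch canonical keys for a list of graphs; NA for invalid/unserializable.
canonical_keys <- function(graphs) {
  n <- length(graphs)
  smi <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    g <- graphs[[k]]
    if (inherits(g, "molecular_graph") && validity_reward(g) == 1)
      smi[k] <- graph_to_smiles(g)
  }
  out <- rep(NA_character_, n)
  ok <- which(!is.na(smi))
  if (length(ok) > 0) out[ok] <- canonicalize_smiles(smi[ok])
  out
}

#' Molecular properties of a valid graph
#'
#' Molecular weight (g/mol) and Wildman-Crippen LogP of the realized molecule;
#' the conditioning vector y has dimension l = 2.
#'
#' @param g A [molecular_graph()] with `validity_reward(g) == 1`.
#' @return Named numeric vector `c(molwt = , logp = )`.
#' @export
compute_properties <- function(g) {
  if (validity_reward(g) != 1)
    abort_canonicalization("compute_properties requires a chemically valid graph")
  pr <- properties_from_smiles(graph_to_smiles(g))
  if (is.na(pr$molwt[1])) abort_canonicalization("property computation failed")
  c(molwt = pr$molwt[1], logp = pr$logp[1])
}
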