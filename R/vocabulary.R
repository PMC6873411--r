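#' Feature vocabulary for molecular graph tensors
#'
#' A vocabulary fixes the one-hot encoding of a molecular graph: the ordered
#' atom-type alphabet (with a reserved `"none"` entry used for padding nodes),
#' the allowed formal charges, the allowed explicit-hydrogen counts, the bond
#' types (single, double, triple, `"none"`), and the maximum node count `m` of
#' the padded graph. The node feature dimension is
#' `p = |atom_types| + |charges| + |h_counts|` and the edge dimension is
#' `q = |bond_types| = 4`.
#'
#' @param atom_types Character vector of element symbols; must contain `"none"`
#'   exactly once (conventionally last).
#' @param formal_charges Integer vector of allowed formal charges.
#' @param explicit_h_counts Integer vector of allowed explicit-hydrogen counts.
#' @param bond_types Character vector of bond types; must be a permutation of
#'   `c("single", "double", "triple", "none")`.
#' @param max_nodes Maximum number of nodes `m` of the padded graph.
#' @return An object of class `feature_vocab`.
#' @examples
#' v <- vocab_preset("qm9")
#' v$p  # 12
#' v$max_nodes  # 14
#' @export
feature_vocabulary <- function(atom_types, formal_charges, explicit_h_counts,
                               bond_types = c("single", "double", "triple", "none"),
                               max_nodes) {
  if (sum(atom_types == "none") != 1L)
    abort_vocabulary("atom_types must contain 'none' exactly once")
  if (sum(bond_types == "none") != 1L || !setequal(bond_types, c("single", "double", "triple", "none")))
    abort_vocabulary("bond_types must be a permutation of single/double/triple/none")
  if (anyDuplicated(atom_types) || anyDuplicated(formal_charges) ||
      anyDuplicated(explicit_h_counts))
    abort_vocabulary("vocabulary entries must be unique")
  if (any(explicit_h_counts < 0)) abort_vocabulary("explicit H counts must be non-negative")
  max_nodes <- as.integer(max_nodes)
  if (is.na(max_nodes) || max_nodes < 1L) abort_vocabulary("max_nodes must be a positive integer")
  n_a <- length(atom_types); n_c <- length(formal_charges); n_h <- length(explicit_h_counts)
  v <- list(
    atom_types = atom_types,
    formal_charges = as.integer(formal_charges),
    explicit_h_counts = as.integer(explicit_h_counts),
    bond_types = bond_types,
    max_nodes = max_nodes,
    p = n_a + n_c + n_h,
    q = length(bond_types),
    # column index ranges of the three one-hot blocks within a node row
    atom_cols = seq_len(n_a),
    charge_cols = n_a + seq_len(n_c),
    h_cols = n_a + n_c + seq_len(n_h),
    none_atom = match("none", atom_types),
    none_bond = match("none", bond_types),
    charge0 = match(0L, as.integer(formal_charges)),
    h0 = match(0L, as.integer(explicit_h_counts)),
    n_pairs = (max_nodes * (max_nodes - 1L)) %/% 2L
  )
  if (is.na(v$charge0)) abort_vocabulary("formal_charges must include 0 (padding convention)")
  if (is.na(v$h0)) abort_vocabulary("explicit_h_counts must include 0 (padding convention)")
  # max allowed valence per (atom type, formal charge); NA = disallowed combo
  mv <- matrix(NA_real_, n_a, n_c,
               dimnames = list(atom_types, as.character(v$formal_charges)))
  for (a in seq_len(n_a)) {
    if (atom_types[a] == "none") next
    for (c in seq_len(n_c)) {
      av <- allowed_valences(atom_types[a], v$formal_charges[c])
      if (!is.null(av)) mv[a, c] <- max(av)
    }
  }
  v$max_valence <- mv
  structure(v, class = "feature_vocab")
}

#' Vocabulary presets
#'
#' `"qm9"`: atom types C, N, O, F (plus `"none"`), charges -1..1, explicit-H
#' 0..3, `m = 14` (5 plus the 9-heavy-atom maximum of QM9), giving `p = 12`,
#' `q = 4`. `"zinc"`: the ten-type drug-like alphabet C, N, O, F, P, S, Cl,
#' Br, I (plus `"none"`), `m = 43`, giving `p = 17`, `q = 4`.
#'
#' @param name One of `"qm9"`, `"zinc"`.
#' @return A [feature_vocabulary()] object.
#' @export
vocab_preset <- function(name = c("qm9", "zinc")) {
  name <- match.arg(name)
  switch(name,
    qm9 = feature_vocabulary(
      atom_types = c("C", "N", "O", "F", "none"),
      formal_charges = c(-1L, 0L, 1L),
      explicit_h_counts = 0:3,
      max_nodes = 14L
    ),
    zinc = feature_vocabulary(
      atom_types = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "none"),
      formal_charges = c(-1L, 0L, 1L),
      explicit_h_counts = 0:3,
      max_nodes = 43L
    )
  )
}

#' @export
print.feature_vocab <- function(x, ...) {
  cat("<feature_vocab> m =", x$max_nodes, " p =", x$p, " q =", x$q, "\n")
  cat("  atom types:", paste(x$atom_types, collapse = " "), "\n")
  cat("  charges:", paste(x$formal_charges, collapse = " "),
      " explicit H:", paste(x$explicit_h_counts, collapse = " "), "\n")
  invisible(x)
}

# Unordered node-pair index table in the fixed project-wide order
# (1,2), (1,3), ..., (1,m), (2,3), ...; row k gives (i, j) with i < j.
pair_index <- function(m) {
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(a) (a + 1L):m), use.names = FALSE)
  cbind(i = i, j = j)
}

same_vocab <- function(a, b) {
  identical(a$atom_types, b$atom_types) &&
    identical(a$formal_charges, b$formal_charges) &&
    identical(a$explicit_h_counts, b$explicit_h_counts) &&
    identical(a$bond_types, b$bond_types) &&
    identical(a$max_nodes, b$max_nodes)
}
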