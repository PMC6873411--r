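# Dataset I/O and a synthetic small-molecule generator, so every training,
# generation and evaluation path is exercisable without downloading QM9/ZINC.
# The generator grows random bond trees (with occasional ring closures) over
# {C, N, O, F} with full valence bookkeeping, fills remaining valence with
# hydrogens, and keeps only unique canonical structures -- every emitted
# molecule is valid and featurizable under the QM9-style vocabulary by
# construction.

fixture_elements <- c("C", "N", "O", "F")
fixture_weights <- c(0.70, 0.12, 0.14, 0.04)

# Valence capacity used during growth (neutral, or the zwitterion pair).
fixture_capacity <- function(elem, charge) {
  if (charge == 1L && elem == "N") return(4L)
  if (charge == -1L && elem == "O") return(1L)
  switch(elem, C = 4L, N = 3L, O = 2L, F = 1L)
}

grow_fixture_molecule <- function(max_heavy, zwitterion_prob) {
  n <- sample(2:max_heavy, 1L, prob = (2:max_heavy)^1.5)
  elem <- sample(fixture_elements, n, replace = TRUE, prob = fixture_weights)
  charge <- rep(0L, n)
  # Occasional ammonium/alkoxide zwitterion pair to exercise the charge paths.
  if (stats::runif(1) < zwitterion_prob && any(elem == "N") && any(elem == "O")) {
    charge[which(elem == "N")[1]] <- 1L
    charge[which(elem == "O")[1]] <- -1L
  }
  cap <- mapply(fixture_capacity, elem, charge)
  free <- cap
  bonds <- matrix(0L, 0, 3)
  attach_order <- function(i, j) {
    omax <- min(3L, free[i], free[j])
    if (omax < 1L) return(0L)
    pr <- c(0.80, 0.15, 0.05)[seq_len(omax)]
    sample.int(omax, 1L, prob = pr)
  }
  placed <- 1L
  for (k in 2:n) {
    open <- which(free[seq_len(placed)] > 0L)
    if (length(open) == 0L) break
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    o <- attach_order(parent, k)
    if (o == 0L) break
    bonds <- rbind(bonds, c(parent, k, o))
    free[parent] <- free[parent] - o
    free[k] <- free[k] - o
    placed <- k
  }
  n <- placed
  # Up to two ring-closure attempts between non-adjacent open atoms.
  for (a in 1:2) {
    if (stats::runif(1) > 0.35) next
    open <- which(free[seq_len(n)] > 0L)
    if (length(open) < 2L) next
    pick <- sample(open, 2L)
    i <- min(pick); j <- max(pick)
    if (any(bonds[, 1] == i & bonds[, 2] == j)) next
    o <- attach_order(i, j)
    if (o == 0L) next
    bonds <- rbind(bonds, c(i, j, o))
    free[i] <- free[i] - o
    free[j] <- free[j] - o
  }
  h <- free[seq_len(n)]
  if (any(h > 3L)) return(NULL)  # outside the explicit-H vocabulary
  list(atoms = data.frame(elem = elem[seq_len(n)], charge = charge[seq_len(n)],
                          h = as.integer(h), stringsAsFactors = FALSE),
       bonds = data.frame(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3]))
}

#' Generate a synthetic fixture set of small molecules
#'
#' Emits `n` unique, chemically valid, kekulizable molecules over
#' {C, N, O, F} with at most `max_heavy` heavy atoms, formal charges in
#' {-1, 0, 1} (an occasional ammonium/alkoxide pair) and hydrogen counts in
#' {0, 1, 2, 3}; deterministic given the seed. All molecules featurize under
#' the QM9 preset.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param max_heavy Maximum heavy-atom count (default 9).
#' @param zwitterion_prob Probability of inserting a charged pair (default 0.05).
#' @return Character vector of `n` unique canonical SMILES.
#' @export
make_fixture_set <- function(n, seed = 1L, max_heavy = 9L, zwitterion_prob = 0.05) {
  if (n < 1L) abort_domain("n must be at least 1")
  set.seed(seed)
  vocab <- vocab_preset("qm9")
  seen <- character(0)
  out <- character(0)
  max_rounds <- 60L
  round <- 0L
  while (length(out) < n && round < max_rounds) {
    round <- round + 1L
    want <- n - length(out)
    batch_n <- max(32L, ceiling(want * 1.5))
    smi <- character(0)
    for (k in seq_len(batch_n)) {
      mol <- grow_fixture_molecule(max_heavy, zwitterion_prob)
      if (is.null(mol)) next
      g <- molecular_graph(mol$atoms, mol$bonds, vocab)
      if (validity_reward(g) != 1) next
      smi <- c(smi, graph_to_smiles(g))
    }
    if (length(smi) == 0L) next
    can <- canonicalize_smiles(smi)
    can <- can[!is.na(can)]
    fresh <- setdiff(unique(can), seen)
    take <- utils::head(fresh, want)
    out <- c(out, take)
    seen <- c(seen, take)
  }
  if (length(out) < n)
    abort_exhaustion(sprintf("could only generate %d of %d unique molecules",
                             length(out), n))
  out
}

#' Build a training dataset from a fixture set
#'
#' Convenience wrapper: generates SMILES with [make_fixture_set()], parses and
#' featurizes them, and computes MolWt/LogP.
#'
#' @inheritParams make_fixture_set
#' @param vocab Vocabulary (default QM9 preset).
#' @return A dataset list: `graphs`, `properties` (n x 2), `smiles`, `skipped`.
#' @export
fixture_dataset <- function(n, seed = 1L, max_heavy = 9L,
                            vocab = vocab_preset("qm9")) {
  smiles <- make_fixture_set(n, seed = seed, max_heavy = max_heavy)
  dataset_from_smiles(smiles, vocab)
}

dataset_from_smiles <- function(smiles, vocab, properties = NULL) {
  parsed <- suppressWarnings(parse_smiles(smiles))
  graphs <- vector("list", length(smiles))
  skipped <- c(parse = 0L, vocabulary = 0L, size = 0L, other = 0L)
  for (k in seq_along(parsed)) {
    if (is.null(parsed[[k]])) { skipped["parse"] <- skipped["parse"] + 1L; next }
    graphs[[k]] <- tryCatch(featurize(parsed[[k]], vocab),
      molgvae_vocabulary_error = function(e) { skipped["vocabulary"] <<- skipped["vocabulary"] + 1L; NULL },
      molgvae_size_error = function(e) { skipped["size"] <<- skipped["size"] + 1L; NULL },
      molgvae_error = function(e) { skipped["other"] <<- skipped["other"] + 1L; NULL })
  }
  kept <- !vapply(graphs, is.null, logical(1))
  if (is.null(properties)) {
    pr <- properties_from_smiles(smiles[kept])
    properties <- as.matrix(pr)
  } else {
    properties <- as.matrix(properties)[kept, , drop = FALSE]
  }
  bad <- !stats::complete.cases(properties)
  if (any(bad)) {
    skipped["other"] <- skipped["other"] + sum(bad)
    keep_idx <- which(kept)[!bad]
  } else keep_idx <- which(kept)
  if (sum(skipped) > 0)
    warning(sprintf("dataset: skipped %d records (parse %d, vocabulary %d, size %d, other %d)",
                    sum(skipped), skipped["parse"], skipped["vocabulary"],
                    skipped["size"], skipped["other"]), call. = FALSE)
  list(graphs = graphs[keep_idx],
       properties = properties[!bad, , drop = FALSE],
       smiles = smiles[keep_idx],
       skipped = skipped)
}

#' Load a molecule dataset from disk
#'
#' Accepts SMILES files (one molecule per line), CSV files with a header
#' containing at least a `smiles` column (optional `molwt`, `logp` columns are
#' used as-is; otherwise properties are computed), or SDF files. Records that
#' fail parsing, the vocabulary, or the size limit are skipped and counted.
#'
#' @param path File path.
#' @param vocab A [feature_vocabulary()].
#' @return A dataset list: `graphs`, `properties`, `smiles`, `skipped`.
#' @export
load_dataset <- function(path, vocab) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  properties <- NULL
  if (ext == "csv") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) abort_format("unreadable CSV file"))
    if (!"smiles" %in% names(df)) abort_format("CSV must have a 'smiles' column")
    smiles <- as.character(df$smiles)
    if (all(c("molwt", "logp") %in% names(df)))
      properties <- cbind(molwt = df$molwt, logp = df$logp)
  } else if (ext == "sdf") {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    smi_text <- tryCatch(ob_convert("SDF", "SMI", text), error = function(e) "")
    lines <- strsplit(smi_text, "\n", fixed = TRUE)[[1]]
    smiles <- vapply(strsplit(lines, "[ \t]"), `[`, character(1), 1)
    smiles <- smiles[nzchar(smiles)]
  } else {
    smiles <- readLines(path, warn = FALSE)
    smiles <- trimws(vapply(strsplit(smiles, "[ \t]"), `[`, character(1), 1))
    smiles <- smiles[nzchar(smiles) & !is.na(smiles)]
  }
  if (length(smiles) == 0L) {
    warning("empty dataset file", call. = FALSE)
    return(list(graphs = list(), properties = matrix(numeric(0), 0, 2),
                smiles = character(0),
                skipped = c(parse = 0L, vocabulary = 0L, size = 0L, other = 0L)))
  }
  dataset_from_smiles(smiles, vocab, properties)
}

#' Write molecules as SMILES lines
#'
#' @param x Character vector of SMILES, a list of [molecular_graph()], or a
#'   `generation_result` (valid graphs are written as canonical SMILES; the
#'   invalid count is reported via a warning).
#' @param path Output file.
#' @export
write_smiles <- function(x, path) {
  if (inherits(x, "generation_result")) x <- x$graphs
  if (is.list(x)) {
    keys <- canonical_keys(x)
    n_invalid <- sum(is.na(keys))
    if (n_invalid > 0)
      warning(sprintf("%d invalid graphs were not written", n_invalid), call. = FALSE)
    x <- keys[!is.na(keys)]
  }
  writeLines(x, path)
  invisible(path)
}
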