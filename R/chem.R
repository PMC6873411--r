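# Chemistry backend. SMILES parsing, kekulization, canonicalization and the
# MolWt / Wildman-Crippen LogP descriptors are delegated to Open Babel through
# ChemmineOB/ChemmineR. The valence model used by the validity reward is
# implemented here (Open Babel does not reject over-valent molecules): an atom
# is acceptable when its explicit valence (sum of bond orders plus the
# explicit-hydrogen count) does not exceed the maximum allowed valence for its
# element/formal-charge combination, remaining valence being filled with
# implicit hydrogens -- the same convention standard sanitization applies.

# Allowed valence sets per element and formal charge.
.VALENCE <- list(
  C  = list(`-1` = 3L, `0` = 4L, `1` = 3L),
  N  = list(`-1` = 2L, `0` = 3L, `1` = 4L),
  O  = list(`-1` = 1L, `0` = 2L, `1` = 3L),
  F  = list(`-1` = 0L, `0` = 1L, `1` = 2L),
  Cl = list(`-1` = 0L, `0` = 1L, `1` = 2L),
  Br = list(`-1` = 0L, `0` = 1L, `1` = 2L),
  I  = list(`-1` = 0L, `0` = 1L, `1` = 2L),
  P  = list(`-1` = 2L, `0` = c(3L, 5L), `1` = 4L),
  S  = list(`-1` = 1L, `0` = c(2L, 4L, 6L), `1` = c(3L, 5L))
)

allowed_valences <- function(elem, charge) {
  e <- .VALENCE[[elem]]
  if (is.null(e)) return(NULL)
  e[[as.character(as.integer(charge))]]
}

# TRUE when (element, charge, explicit valence) passes the sanitization rule.
valence_ok <- function(elem, charge, explicit_valence) {
  av <- allowed_valences(elem, charge)
  !is.null(av) && explicit_valence <= max(av)
}

# Number of implicit hydrogens filling up to the smallest allowed valence that
# accommodates the explicit valence (0 when already at or beyond the maximum).
implicit_h_fill <- function(elem, charge, explicit_valence) {
  av <- allowed_valences(elem, charge)
  if (is.null(av)) return(0L)
  av <- av[av >= explicit_valence]
  if (length(av) == 0L) return(0L)
  as.integer(min(av) - explicit_valence)
}

ob_convert <- function(from, to, text,
                       options = data.frame(names = character(0), args = character(0))) {
  # Open Babel writes progress chatter to stderr; keep the result only.
  suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat(from, to, source = text, options = options)
  ))
}

#' Parse SMILES strings into atom/bond tables
#'
#' Molecules are kekulized (aromatic bonds rewritten as alternating single and
#' double bonds) and hydrogens made explicit, so each heavy atom carries its
#' element symbol, formal charge, and total attached-hydrogen count. Strings
#' that cannot be parsed or kekulized yield `NULL` entries; the number of
#' failures is attached as attribute `"n_failed"` and reported via a warning.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list (one entry per input) of `parsed_mol` objects: each a list
#'   with `atoms` (data.frame: `elem`, `charge`, `h`) and `bonds` (data.frame:
#'   `i`, `j`, `order`), or `NULL` for failed records.
#' @export
parse_smiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  if (n == 0L) return(out)
  # Carry the input index through Open Babel as the molecule title.
  text <- paste(paste(smiles, seq_len(n)), collapse = "\n")
  sdf_text <- tryCatch(
    ob_convert("SMI", "SDF", text, options = data.frame(names = "h", args = "")),
    error = function(e) ""
  )
  if (nzchar(sdf_text)) {
    con <- textConnection(sdf_text)
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con))),
      error = function(e) NULL
    )
    close(con)
    if (!is.null(sdfset)) {
      for (k in seq_along(sdfset)) {
        sdf <- sdfset[[k]]
        title <- suppressWarnings(as.integer(ChemmineR::header(sdf)[["Molecule_Name"]]))
        if (is.na(title) || title < 1L || title > n) next
        out[[title]] <- tryCatch(mol_from_sdf(sdf), error = function(e) NULL)
      }
    }
  }
  # A malformed record can abort Open Babel's batch conversion; retry the
  # missing records one at a time so one bad SMILES cannot mask its neighbors.
  missing <- which(vapply(out, is.null, logical(1)))
  if (length(missing) > 0L && n > 1L) {
    for (k in missing) out[[k]] <- parse_one_smiles(smiles[k])
  }
  n_failed <- sum(vapply(out, is.null, logical(1)))
  if (n_failed > 0L)
    warning(sprintf("parse_smiles: %d of %d records could not be parsed/kekulized",
                    n_failed, n), call. = FALSE)
  attr(out, "n_failed") <- n_failed
  out
}

parse_one_smiles <- function(smi) {
  sdf_text <- tryCatch(
    ob_convert("SMI", "SDF", paste(smi, "1"),
               options = data.frame(names = "h", args = "")),
    error = function(e) "")
  if (!nzchar(sdf_text)) return(NULL)
  con <- textConnection(sdf_text)
  on.exit(close(con))
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con))),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) < 1L) return(NULL)
  tryCatch(mol_from_sdf(sdfset[[1]]), error = function(e) NULL)
}

# Convert one ChemmineR SDF (Open Babel output, explicit hydrogens) into
# heavy-atom/bond tables. Legacy charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3.
mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_[0-9]+$", "", rownames(ab))
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- integer(length(code))
  charge[code %in% 1:3] <- 4L - as.integer(code[code %in% 1:3])
  charge[code %in% 5:7] <- 4L - as.integer(code[code %in% 5:7])
  heavy <- which(sym != "H")
  remap <- integer(length(sym)); remap[heavy] <- seq_along(heavy)
  h_count <- integer(length(heavy))
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0) {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
    for (r in seq_along(bi)) {
      a <- bi[r]; b <- bj[r]
      ha <- sym[a] != "H"; hb <- sym[b] != "H"
      if (ha && hb) {
        if (!(bo[r] %in% 1:3)) abort_kekulization("non-kekulized bond order in structure")
        bonds <- rbind(bonds, c(remap[a], remap[b], bo[r]))
      } else if (ha && !hb) {
        h_count[remap[a]] <- h_count[remap[a]] + 1L
      } else if (!ha && hb) {
        h_count[remap[b]] <- h_count[remap[b]] + 1L
      }
    }
  }
  atoms <- data.frame(elem = sym[heavy], charge = charge[heavy], h = h_count,
                      stringsAsFactors = FALSE)
  bonds <- if (is.null(bonds)) {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    data.frame(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3])
  }
  structure(list(atoms = atoms, bonds = bonds), class = "parsed_mol")
}

#' Canonicalize SMILES strings
#'
#' Batch canonicalization through Open Babel; permutation-equivalent inputs map
#' to identical canonical strings. Failed records return `NA`.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (`NA` on failure).
#' @export
canonicalize_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  text <- paste(paste(smiles, seq_len(n)), collapse = "\n")
  res <- tryCatch(ob_convert("SMI", "CAN", text), error = function(e) "")
  out <- rep(NA_character_, n)
  if (nzchar(res)) {
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    for (ln in lines) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) >= 2) {
        idx <- suppressWarnings(as.integer(parts[length(parts)]))
        if (!is.na(idx) && idx >= 1L && idx <= n)
          out[idx] <- paste(parts[-length(parts)], collapse = "")
      }
    }
  }
  out
}

#' Molecular properties from SMILES
#'
#' Computes the two conditioning properties: molecular weight (g/mol) and the
#' Wildman-Crippen octanol-water partition coefficient, both as implemented in
#' Open Babel.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with columns `molwt` and `logp` (`NA` on failure).
#' @export
properties_from_smiles <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(molwt = rep(NA_real_, n), logp = rep(NA_real_, n))
  if (n == 0L) return(out)
  text <- paste(paste(smiles, seq_len(n)), collapse = "\n")
  props <- tryCatch({
    mols <- suppressWarnings(ChemmineOB::forEachMol("SMILES", text, identity))
    suppressWarnings(ChemmineOB::prop_OB(mols))
  }, error = function(e) NULL)
  if (!is.null(props) && nrow(props) > 0) {
    idx <- suppressWarnings(as.integer(props$title))
    ok <- !is.na(idx) & idx >= 1L & idx <= n
    out$molwt[idx[ok]] <- props$MW[ok]
    out$logp[idx[ok]] <- props$logP[ok]
  }
  out
}

# ---- SMILES emission for the package's own graph container -----------------

# Bracket-atom label, pinning element, total hydrogen count and charge exactly
# so Open Babel cannot re-interpret hydrogen counts on re-read.
atom_bracket <- function(elem, charge, h_total) {
  hs <- if (h_total <= 0L) "" else if (h_total == 1L) "H" else paste0("H", h_total)
  cs <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
    else if (charge > 1L) paste0("+", charge) else paste0("-", abs(charge))
  paste0("[", elem, hs, cs, "]")
}

bond_symbol <- c("", "=", "#")

ring_digit <- function(d) if (d < 10L) as.character(d) else paste0("%", sprintf("%02d", d))

# Serialize heavy-atom tables to SMILES by depth-first traversal with ring
# closures; disconnected components are joined with ".". Hydrogens beyond the
# explicit count are implied by the bracket label (implicit fill applied by the
# caller), so the string is an exact description of the realized molecule.
smiles_from_tables <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n == 0L) abort_canonicalization("cannot serialize an empty graph")
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      adj[[i]] <- rbind(adj[[i]], c(j, bonds$order[r], r))
      adj[[j]] <- rbind(adj[[j]], c(i, bonds$order[r], r))
    }
  }
  visited <- rep(FALSE, n)
  edge_used <- rep(FALSE, max(1L, nrow(bonds)))
  ring_tok <- vector("list", n)  # closure tokens appended after each atom label
  ring_no <- 0L
  children <- vector("list", n)  # tree children as (atom, order) rows

  walk <- function(root) {
    stack <- list(c(root, 0L))
    order_visit <- integer(0)
    visited[root] <<- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      u <- top[1]
      order_visit <- c(order_visit, u)
      nb <- adj[[u]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          v <- nb[r, 1]; o <- nb[r, 2]; e <- nb[r, 3]
          if (edge_used[e]) next
          if (visited[v]) {  # ring closure
            edge_used[e] <<- TRUE
            ring_no <<- ring_no + 1L
            tok <- paste0(bond_symbol[o], ring_digit(ring_no))
            ring_tok[[u]] <<- c(ring_tok[[u]], tok)
            ring_tok[[v]] <<- c(ring_tok[[v]], tok)
          } else {
            edge_used[e] <<- TRUE
            visited[v] <<- TRUE
            children[[u]] <<- rbind(children[[u]], c(v, o))
            stack[[length(stack) + 1L]] <- c(v, 0L)
          }
        }
      }
    }
    order_visit
  }

  emit <- function(u) {
    s <- paste0(atom_bracket(atoms$elem[u], atoms$charge[u], atoms$h_render[u]),
                paste(ring_tok[[u]], collapse = ""))
    ch <- children[[u]]
    if (!is.null(ch)) {
      k <- nrow(ch)
      for (r in seq_len(k)) {
        sub <- paste0(bond_symbol[ch[r, 2]], emit(ch[r, 1]))
        s <- paste0(s, if (r < k) paste0("(", sub, ")") else sub)
      }
    }
    s
  }

  frags <- character(0)
  for (root in seq_len(n)) {
    if (!visited[root]) {
      walk(root)
      frags <- c(frags, emit(root))
    }
  }
  paste(frags, collapse = ".")
}
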