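# Molecular graphs: parsing, featurization, SMILES file I/O.
#
# A mol_graph stores heavy atoms only (implicit hydrogens): the atom ratios
# the masking strategy reasons about are heavy-atom ratios. Undirected bonds
# are stored once and expanded to both orientations on featurization, as in
# message-passing conventions. SMILES parsing is delegated to OpenBabel via
# ChemmineOB/ChemmineR; atom order follows the parser's output order, which
# is fixed across runs for a given input string.

#' Construct a molecular graph
#'
#' Low-level constructor. Most users obtain `mol_graph` objects from
#' [parse_smiles()], [read_smiles_file()] or [generate_corpus()].
#'
#' @param symbols Character vector of element symbols, one per heavy atom.
#' @param bonds Data frame (or NULL for a bond-less molecule) with integer
#'   columns `u`, `v` (1-based atom indices, `u != v`), character `type`
#'   (one of single/double/triple/aromatic) and optional `dir` (one of
#'   none/end-up/end-down; defaults to "none").
#' @param chirality Character vector of chirality tags (default all
#'   "unspecified").
#' @param name Optional identifier string.
#' @param smiles Optional originating SMILES string.
#' @return An object of class `mol_graph` with fields `atoms` (data frame:
#'   `symbol`, `z`, `chirality`), `bonds`, `name`, `smiles`.
#' @export
mol_graph <- function(symbols, bonds = NULL, chirality = NULL,
                      name = NULL, smiles = NULL) {
  n <- length(symbols)
  if (n < 1L) stop("a molecule must have at least one atom")
  z <- atomic_number(symbols)
  if (is.null(chirality)) chirality <- rep("unspecified", n)
  stopifnot(length(chirality) == n, all(chirality %in% CHIRALITY_TAGS))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(u = integer(0), v = integer(0),
                        type = character(0), dir = character(0),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$dir)) bonds$dir <- "none"
    bonds <- bonds[, c("u", "v", "type", "dir")]
    bonds$u <- as.integer(bonds$u)
    bonds$v <- as.integer(bonds$v)
    if (any(bonds$u < 1L | bonds$u > n | bonds$v < 1L | bonds$v > n)) {
      stop("bond references an atom index outside 1..", n)
    }
    if (any(bonds$u == bonds$v)) stop("self-bonds are not allowed")
    if (!all(bonds$type %in% BOND_TYPES)) {
      stop("unknown bond type(s): ",
           paste(setdiff(bonds$type, BOND_TYPES), collapse = ", "))
    }
    if (!all(bonds$dir %in% BOND_DIRS)) stop("unknown bond direction tag")
    key <- paste(pmin(bonds$u, bonds$v), pmax(bonds$u, bonds$v))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }
  structure(
    list(
      atoms = data.frame(symbol = symbols, z = z, chirality = chirality,
                         stringsAsFactors = FALSE),
      bonds = bonds, name = name, smiles = smiles
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds%s\n",
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$name)) paste0(" (", x$name, ")") else ""))
  cat("  atoms:", paste(x$atoms$symbol, collapse = " "), "\n")
  if (!is.null(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# --- SMILES parsing via OpenBabel -------------------------------------------

# Convert a batch of SMILES to V2000 SDF entries, keeping track of which
# input line produced each entry (OpenBabel silently skips unparsable
# records; the molecule title carries the input index back). Entries are
# returned as character vectors of lines, one per successfully parsed input.
ob_smiles_to_sdf <- function(smiles) {
  input <- paste0(paste(smiles, seq_along(smiles), sep = "\t"),
                  collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "SDF", paste0(input, "\n"))
  if (!nzchar(out)) return(list(entries = list(), idx = integer(0)))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  entries <- mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
  idx <- suppressWarnings(as.integer(vapply(entries, `[`, "", 1L)))
  list(entries = entries, idx = idx)
}

# One mol_graph from one V2000 entry (character vector of lines).
# ChemmineR handles the general case; it rejects bond-less entries, for
# which the single atom block line is read directly.
sdf_to_mol_graph <- function(entry, name = NULL, smiles = NULL) {
  counts <- entry[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("malformed SDF entry")
  if (nb == 0L) {
    atom_lines <- entry[5:(4 + na)]
    symbols <- vapply(strsplit(trimws(atom_lines), "[ \t]+"), `[`, "", 4L)
    return(mol_graph(symbols, NULL, name = name, smiles = smiles))
  }
  sdf <- ChemmineR::read.SDFset(entry)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  symbols <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- NULL
  if (NROW(bb) > 0L) {
    bb <- matrix(as.numeric(bb), nrow = NROW(bb))
    type_code <- bb[, 3]
    type <- ifelse(type_code == 2, "double",
            ifelse(type_code == 3, "triple",
            ifelse(type_code == 4, "aromatic", "single")))
    stereo <- if (ncol(bb) >= 4) bb[, 4] else rep(0, nrow(bb))
    dir <- ifelse(stereo == 1, "end-up", ifelse(stereo == 6, "end-down", "none"))
    bonds <- data.frame(u = as.integer(bb[, 1]), v = as.integer(bb[, 2]),
                        type = type, dir = dir, stringsAsFactors = FALSE)
  }
  mol_graph(symbols, bonds, name = name, smiles = smiles)
}

#' Parse a SMILES string into a molecular graph
#'
#' Heavy-atom graph with implicit hydrogens. Atom order follows the
#' OpenBabel parse of the input string and is fixed across runs. Aromatic
#' rings are kekulized by the parser, so ring bonds come back as alternating
#' single/double bonds.
#'
#' @param smiles A single SMILES string.
#' @param name Optional molecule name stored on the result.
#' @return A [mol_graph()].
#' @export
#' @examples
#' m <- parse_smiles("CCO")
#' n_atoms(m)   # 3
parse_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  res <- ob_smiles_to_sdf(smiles)
  if (length(res$entries) == 0L || is.na(res$idx[1])) {
    stop("invalid SMILES: ", smiles)
  }
  sdf_to_mol_graph(res$entries[[1]], name = name, smiles = smiles)
}

# Vectorized parse; returns list with NULL at failed positions. OpenBabel
# aborts a batch at the first unparsable record, so conversion resumes just
# past each failing line until the whole input is covered.
parse_smiles_batch <- function(smiles, names = NULL) {
  n <- length(smiles)
  out <- vector("list", n)
  p <- 1L
  while (p <= n) {
    res <- ob_smiles_to_sdf(smiles[p:n])
    done <- p - 1L
    for (j in seq_along(res$idx)) {
      i <- res$idx[j] + p - 1L
      if (!is.na(res$idx[j]) && i >= p && i <= n) {
        out[[i]] <- sdf_to_mol_graph(res$entries[[j]],
                                     name = if (!is.null(names)) names[i],
                                     smiles = smiles[i])
        done <- max(done, i)
      }
    }
    p <- done + 2L  # skip the line the converter stopped on
  }
  out
}

#' Canonical SMILES of a molecule or SMILES string
#'
#' @param x A `mol_graph` or a character vector of SMILES.
#' @return Character vector of OpenBabel-canonical SMILES.
#' @export
canonical_smiles <- function(x) {
  smi <- if (inherits(x, "mol_graph")) {
    if (is.null(x$smiles)) stop("mol_graph carries no SMILES string")
    x$smiles
  } else as.character(x)
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(paste(smi, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  vapply(lines, function(l) strsplit(l, "[ \t]")[[1]][1], "", USE.NAMES = FALSE)
}

# --- Featurization ----------------------------------------------------------

#' Encode a molecular graph as integer feature tensors
#'
#' Node features are (atom-type index, chirality index); the atom-type index
#' is the atomic number, and one extra reserved index ([feature_vocab()]
#' `$mask_token`) exists for the mask token, never produced here. Edge
#' features are (bond-type index, bond-direction index). Every undirected
#' bond is expanded to both orientations; the end-up/end-down direction tags
#' swap when the orientation is reversed.
#'
#' @param mol A [mol_graph()].
#' @return An object of class `graph_tensors`: list with `node_features`
#'   (N x 2 integer matrix), `edge_index` (2 x 2B integer matrix of
#'   source/target rows, 1-based), `edge_features` (2B x 2 integer matrix)
#'   and `n_nodes`.
#' @export
#' @examples
#' gt <- featurize(parse_smiles("CCO"))
#' ncol(gt$edge_index)  # 4 directed edges from 2 bonds
featurize <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  vocab <- feature_vocab()
  z <- mol$atoms$z
  if (any(z > 118L)) stop("element outside supported periodic-table range")
  chir <- match(mol$atoms$chirality, CHIRALITY_TAGS)
  node_features <- cbind(atom_type = as.integer(z),
                         chirality = as.integer(chir))
  nb <- nrow(mol$bonds)
  if (nb > 0L) {
    bt <- match(mol$bonds$type, BOND_TYPES)
    bd <- match(mol$bonds$dir, BOND_DIRS)
    # reversed orientation swaps end-up (2) and end-down (3)
    bd_rev <- ifelse(bd == 2L, 3L, ifelse(bd == 3L, 2L, 1L))
    edge_index <- rbind(c(mol$bonds$u, mol$bonds$v),
                        c(mol$bonds$v, mol$bonds$u))
    edge_features <- cbind(bond_type = as.integer(c(bt, bt)),
                           bond_dir = as.integer(c(bd, bd_rev)))
  } else {
    edge_index <- matrix(integer(0), nrow = 2)
    edge_features <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("bond_type", "bond_dir")))
  }
  structure(
    list(node_features = node_features,
         edge_index = edge_index,
         edge_features = edge_features,
         n_nodes = nrow(node_features)),
    class = "graph_tensors"
  )
}

#' Relabel the atoms of a molecule
#'
#' `perm[i]` gives the new position of original atom `i`. Used to exercise
#' the permutation-equivariance contracts of [featurize()] and the encoder.
#'
#' @param mol A `mol_graph`.
#' @param perm Integer permutation of `1:n_atoms(mol)`.
#' @return The relabeled `mol_graph`.
#' @export
permute_mol <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)  # inv[new position] = old index
  bonds <- mol$bonds
  if (nrow(bonds) > 0L) {
    bonds$u <- perm[bonds$u]
    bonds$v <- perm[bonds$v]
  }
  mol_graph(mol$atoms$symbol[inv], bonds,
            chirality = mol$atoms$chirality[inv],
            name = mol$name, smiles = NULL)
}

# --- SMILES files -----------------------------------------------------------

#' Read a SMILES file
#'
#' One record per line: a SMILES string, optionally followed by
#' tab-separated label columns; empty fields are missing labels (`NA`). A
#' header line whose first field is "smiles" (case-insensitive) is detected
#' and skipped.
#'
#' @param path File path.
#' @param strict If TRUE, an unparsable line is an error; otherwise such
#'   lines are dropped with a warning naming the line numbers.
#' @return A list with one entry per parsed molecule: `list(mol, labels)`
#'   where `labels` is a numeric vector (possibly length 0) with `NA` for
#'   missing fields. Order is preserved.
#' @export
read_smiles_file <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- vapply(fields, `[`, "", 1L)
  lineno <- seq_along(lines)
  if (tolower(trimws(first[1])) == "smiles") {
    fields <- fields[-1]; first <- first[-1]; lineno <- lineno[-1]
  }
  if (length(fields) == 0L) return(list())
  mols <- parse_smiles_batch(trimws(first))
  bad <- which(vapply(mols, is.null, TRUE))
  if (length(bad) > 0L) {
    msg <- paste0("unparsable SMILES at line(s) ",
                  paste(lineno[bad], collapse = ", "), " of ", path)
    if (strict) stop(msg) else warning(msg)
  }
  keep <- setdiff(seq_along(mols), bad)
  lapply(keep, function(i) {
    lab <- fields[[i]][-1]
    # a trailing empty field is dropped by strsplit; restore via raw line
    nsep <- lengths(regmatches(lines[lineno[i]],
                               gregexpr("\t", lines[lineno[i]], fixed = TRUE)))
    if (nsep > length(lab)) lab <- c(lab, rep("", nsep - length(lab)))
    labels <- suppressWarnings(as.numeric(ifelse(nzchar(trimws(lab)), lab, NA)))
    list(mol = mols[[i]], labels = labels)
  })
}

#' Write molecules (and optional labels) to a SMILES file
#'
#' Inverse of [read_smiles_file()]: one tab-separated record per line,
#' missing labels written as empty fields.
#'
#' @param records Either a character vector of SMILES, a list of
#'   `mol_graph`s, or a list of `list(mol, labels)` records as returned by
#'   [read_smiles_file()].
#' @param path Output file path.
#' @param header Optional character vector of column names to write first.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(records, path, header = NULL) {
  fmt_one <- function(rec) {
    if (is.character(rec)) return(rec)
    if (inherits(rec, "mol_graph")) return(rec$smiles)
    smi <- if (inherits(rec$mol, "mol_graph")) rec$mol$smiles else as.character(rec$mol)
    if (is.null(rec$labels) || length(rec$labels) == 0L) return(smi)
    lab <- ifelse(is.na(rec$labels), "",
                  format(rec$labels, trim = TRUE, scientific = FALSE))
    paste(c(smi, lab), collapse = "\t")
  }
  out <- if (is.character(records)) records else vapply(records, fmt_one, "")
  if (any(is.na(out) | !nzchar(out))) stop("record without a SMILES string")
  if (!is.null(header)) out <- c(paste(header, collapse = "\t"), out)
  writeLines(out, path)
  invisible(path)
}
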