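#' Featurization vocabulary
#'
#' Fixed sizes of the categorical feature vocabularies used to build the
#' encoder's embedding tables.  Atom type is the atomic number (capped at
#' 119), with slot 120 reserved for the mask token used by the generative
#' channel.  Chirality and bond-direction slots exist so checkpoints have
#' a stable layout; the parser emits the "unspecified" index for both
#' (stereochemistry beyond the tag is out of scope).  Bond types are
#' single, double, triple, aromatic, plus a fifth slot used for the
#' self-loop edges added during message passing.
#'
#' @return A named list with vocabulary sizes and reserved indices.
#' @export
mol_vocab <- function() {
  list(
    n_atom_type = 120L,
    mask_atom_type = 120L,
    n_chirality = 3L,
    n_bond_type = 5L,     # 1 single, 2 double, 3 triple, 4 aromatic, 5 self-loop
    self_loop_bond = 5L,
    n_bond_dir = 3L
  )
}

# Symbol -> atomic number for the organic subset plus common heteroatoms.
.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, As = 33, Se = 34, Br = 35, Te = 52, I = 53,
  Li = 3, Na = 11, Mg = 12, Al = 13, K = 19, Ca = 20, Fe = 26, Zn = 30,
  Sn = 50
)

new_molecular_graph <- function(num_atoms, atom_features, bond_list,
                                bond_features, smiles) {
  g <- list(
    num_atoms = as.integer(num_atoms),
    atom_features = atom_features,   # num_atoms x 2: (atom type, chirality)
    bond_list = bond_list,           # n_bonds x 2, each undirected bond once
    bond_features = bond_features,   # n_bonds x 2: (bond type, direction)
    smiles = smiles
  )
  class(g) <- "molecular_graph"
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, ": ", x$num_atoms, " atoms, ",
      nrow(x$bond_list), " bonds\n", sep = "")
  invisible(x)
}

validate_graph <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  nb <- nrow(g$bond_list)
  stopifnot(nrow(g$atom_features) == g$num_atoms,
            nrow(g$bond_features) == nb)
  if (nb > 0) {
    stopifnot(all(g$bond_list >= 1L), all(g$bond_list <= g$num_atoms),
              all(g$bond_list[, 1] != g$bond_list[, 2]))
    key <- paste(pmin(g$bond_list[, 1], g$bond_list[, 2]),
                 pmax(g$bond_list[, 1], g$bond_list[, 2]))
    stopifnot(!anyDuplicated(key))
  }
  invisible(g)
}

# Convert one ChemmineR SDF record into a featurized graph.  OpenBabel
# kekulizes on conversion, so aromaticity is re-perceived from the ring
# systems reported by ChemmineR::rings() and written back onto ring
# bonds/atoms.
sdf_to_graph <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  if (n == 0L) stop("molecule has no atoms")
  elements <- sub("_.*$", "", rownames(ab))
  z <- .element_z[elements]
  if (anyNA(z)) {
    z[is.na(z)] <- 119L  # unknown element bucket
  }
  atom_type <- pmin(as.integer(z), 119L)
  atom_feat <- cbind(atom_type = atom_type,
                     chirality = rep(1L, n))

  bb <- ChemmineR::bondblock(sdf)
  nb <- 0L
  if (!is.null(bb) && length(bb) > 0) {
    bb <- as.matrix(bb)
    # bond-free molecules come back as a single dummy row of zeros
    if (ncol(bb) >= 3L) {
      bb <- bb[bb[, 1] >= 1 & bb[, 2] >= 1, , drop = FALSE]
      nb <- nrow(bb)
    }
  }

  aromatic_atom <- rep(FALSE, n)
  if (nb > 0L) {
    bl <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    btype <- as.integer(bb[, 3])
    btype[btype > 3L] <- 1L  # molblock "4" (aromatic) re-derived below

    rr <- tryCatch(
      ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    if (length(rr$RINGS) > 0) {
      idx_of <- function(nm) as.integer(sub("^.*_", "", nm))
      for (ri in seq_along(rr$RINGS)) {
        if (!isTRUE(rr$AROMATIC[[ri]])) next
        members <- idx_of(rr$RINGS[[ri]])
        aromatic_atom[members] <- TRUE
        inring <- bl[, 1] %in% members & bl[, 2] %in% members
        btype[inring] <- 4L
      }
    }
    bond_feat <- cbind(bond_type = btype, bond_dir = rep(1L, nb))
  } else {
    bl <- matrix(integer(0), 0L, 2L)
    bond_feat <- matrix(integer(0), 0L, 2L,
                        dimnames = list(NULL, c("bond_type", "bond_dir")))
  }

  g <- new_molecular_graph(n, atom_feat, bl, bond_feat, smiles)
  g$aromatic_atom <- aromatic_atom
  g$element <- elements
  validate_graph(g)
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Hydrogens are left implicit (heavy atoms only).  Each atom carries an
#' (atom type, chirality tag) integer pair and each bond a (bond type,
#' bond direction) pair; see [mol_vocab()] for the index layout.  Bonds
#' are stored once and expanded to both directions only inside message
#' passing.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A `molecular_graph` object.
#' @examples
#' \donttest{
#' g <- parse_smiles("c1ccccc1")   # benzene: 6 atoms, 6 aromatic bonds
#' }
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    cond <- structure(
      class = c("fragssl_parse_error", "error", "condition"),
      list(message = paste0("unparseable SMILES: ", smiles),
           call = sys.call(-1), smiles = smiles)
    )
    stop(cond)
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (is.null(dim(ab)) || ncol(ab) < 3L) {
    # ChemmineR cannot index molblocks without a bond block; recover the
    # atom symbols from the raw V2000 record for bond-free molecules
    return(parse_bondfree(smiles))
  }
  sdf_to_graph(sdf[[1]], smiles)
}

parse_bondfree <- function(smiles) {
  txt <- strsplit(ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
                  "\n", fixed = TRUE)[[1]]
  counts_at <- grep("V2000", txt, fixed = TRUE)[1]
  stopifnot(!is.na(counts_at))
  n <- as.integer(substr(txt[counts_at], 1L, 3L))
  stopifnot(n >= 1L)
  elements <- vapply(seq_len(n), function(i) {
    strsplit(trimws(txt[counts_at + i]), "\\s+")[[1]][4]
  }, character(1))
  z <- .element_z[elements]
  z[is.na(z)] <- 119L
  g <- new_molecular_graph(
    n, cbind(atom_type = pmin(as.integer(z), 119L),
             chirality = rep(1L, n)),
    matrix(integer(0), 0L, 2L),
    matrix(integer(0), 0L, 2L,
           dimnames = list(NULL, c("bond_type", "bond_dir"))),
    smiles)
  g$aromatic_atom <- rep(FALSE, n)
  g$element <- elements
  validate_graph(g)
}

# Parse a character vector of SMILES; failures become NULL entries.
parse_smiles_set <- function(smiles) {
  lapply(smiles, function(s) {
    tryCatch(parse_smiles(s), fragssl_parse_error = function(e) NULL,
             error = function(e) NULL)
  })
}

#' Parse an SDF file through the same featurization path
#'
#' @param path Path to an SDF file.
#' @return A list of `molecular_graph` objects.
#' @export
parse_sdf <- function(path) {
  stopifnot(file.exists(path))
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfs), function(i) {
    sdf_to_graph(sdfs[[i]], ChemmineR::sdfid(sdfs[i]))
  })
}

new_labeled_dataset <- function(graphs, labels, task_kind) {
  d <- list(graphs = graphs, labels = labels, task_kind = task_kind)
  class(d) <- "labeled_dataset"
  d
}

#' Read a labeled molecule dataset from CSV
#'
#' The file must have a header with a `smiles` column.  Rows whose SMILES
#' cannot be parsed are dropped with a warning carrying the count.
#' Missing label cells are kept as `NA` and excluded from losses and
#' metrics downstream (multi-task panels routinely have missing entries).
#'
#' @param path CSV file path.
#' @param task_columns Character vector of label column names.
#' @param task_kind `"classification"` (labels in \{0, 1, NA\}) or
#'   `"regression"`.
#' @return A `labeled_dataset`: list of graphs plus a molecules-by-tasks
#'   label matrix.
#' @export
read_dataset <- function(path, task_columns,
                         task_kind = c("classification", "regression")) {
  task_kind <- match.arg(task_kind)
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) {
    stop("dataset is missing the mandatory 'smiles' column: ", path)
  }
  missing_cols <- setdiff(task_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("label column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  graphs <- parse_smiles_set(df$smiles)
  ok <- !vapply(graphs, is.null, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " molecule(s) dropped: unparseable SMILES")
  }
  labels <- as.matrix(df[ok, task_columns, drop = FALSE])
  storage.mode(labels) <- "double"
  if (task_kind == "classification") {
    bad <- !(is.na(labels) | labels == 0 | labels == 1)
    if (any(bad)) stop("classification labels must be 0, 1 or missing")
  }
  new_labeled_dataset(graphs[ok], labels, task_kind)
}
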