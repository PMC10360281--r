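# Hand-built graphs, tiny models, and independent scalar oracles used to
# cross-check the vectorized implementations.

# A bare molecular graph without chemistry annotations (enough for the
# encoder and pooling layers, which only consume feature indices).
make_graph <- function(atom_type, bonds = NULL, bond_type = NULL,
                       smiles = "<synthetic>") {
  n <- length(atom_type)
  bl <- if (is.null(bonds)) matrix(integer(0), 0L, 2L) else bonds
  bf <- cbind(bond_type = if (is.null(bond_type)) rep(1L, nrow(bl)) else
                bond_type,
              bond_dir = rep(1L, nrow(bl)))
  if (nrow(bl) == 0L) bf <- matrix(integer(0), 0L, 2L)
  fragssl:::new_molecular_graph(
    n, cbind(atom_type = as.integer(atom_type), chirality = rep(1L, n)),
    bl, bf, smiles)
}

tiny_model <- function(D = 4L, layers = 1L, seed = 5L, norm = "batch") {
  init_model(encoder_config(num_layers = layers, hidden_dim = D,
                            norm = norm), seed = seed)
}

# --- independent scalar oracles -------------------------------------------

# InfoNCE by direct evaluation of the definition, one pair at a time.
oracle_infonce <- function(anchors, positives, tau) {
  cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  B <- nrow(anchors)
  total <- 0
  for (i in seq_len(B)) {
    num <- exp(cosine(anchors[i, ], positives[i, ]) / tau)
    den <- 0
    for (j in seq_len(B)) {
      den <- den + exp(cosine(anchors[i, ], positives[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / B
}

# Attention pooling by direct evaluation: per-fragment scaled dot-product
# logits, softmax within each molecule, weighted sum of value vectors.
oracle_attentive_pool <- function(Hf, mol_of_frag, Wq, Wk, Wv) {
  D <- ncol(Hf)
  nmol <- max(mol_of_frag)
  out <- matrix(0, nmol, D)
  w_all <- numeric(nrow(Hf))
  for (m in seq_len(nmol)) {
    rows <- which(mol_of_frag == m)
    logits <- vapply(rows, function(r) {
      q <- drop(Hf[r, ] %*% Wq)
      k <- drop(Hf[r, ] %*% Wk)
      sum(q * k) / sqrt(D)
    }, numeric(1))
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    w_all[rows] <- w
    for (ri in seq_along(rows)) {
      out[m, ] <- out[m, ] + w[ri] * drop(Hf[rows[ri], ] %*% Wv)
    }
  }
  list(pooled = out, weights = w_all)
}

# One GIN layer (norm = "none") by direct evaluation: for every node, sum
# incoming messages (neighbor state + bond-type + bond-dir embeddings,
# plus a self-loop message), then the two-layer perceptron.
oracle_gin_layer <- function(H, bonds, W1, b1, W2, b2, bond_type_emb,
                             bond_dir_emb, self_loop = 5L) {
  n <- nrow(H)
  agg <- matrix(0, n, ncol(H))
  add_msg <- function(to, from, bt, bd) {
    agg[to, ] <<- agg[to, ] + H[from, ] + bond_type_emb[bt, ] +
      bond_dir_emb[bd, ]
  }
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      add_msg(bonds[b, 1], bonds[b, 2], bonds[b, 3], bonds[b, 4])
      add_msg(bonds[b, 2], bonds[b, 1], bonds[b, 3], bonds[b, 4])
    }
  }
  for (v in seq_len(n)) add_msg(v, v, self_loop, 1L)
  Z <- matrix(0, n, ncol(W2))
  for (v in seq_len(n)) {
    hid <- pmax(drop(agg[v, ] %*% W1) + drop(b1), 0)
    Z[v, ] <- drop(hid %*% W2) + drop(b2)
  }
  Z
}

# Scaled cosine error by direct evaluation.
oracle_sce <- function(targets, recon, groups, gamma, n_mol = NULL) {
  if (is.null(n_mol)) n_mol <- length(unique(groups))
  total <- 0
  for (m in unique(groups)) {
    rows <- which(groups == m)
    s <- 0
    for (r in rows) {
      cs <- sum(targets[r, ] * recon[r, ]) /
        (sqrt(sum(targets[r, ]^2)) * sqrt(sum(recon[r, ]^2)))
      s <- s + (1 - cs)^gamma
    }
    total <- total + s / length(rows)
  }
  total / n_mol
}

# --- RDKit reference (independent toolkit, via the python interpreter) ----

rdkit_reference <- function(smiles, what = c("counts", "brics")) {
  what <- match.arg(what)
  inp <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".txt")
  writeLines(smiles, inp)
  script <- if (what == "counts") '
import sys
from rdkit import Chem
with open(sys.argv[1]) as f, open(sys.argv[2], "w") as o:
    for line in f:
        mol = Chem.MolFromSmiles(line.strip())
        o.write(f"{mol.GetNumAtoms()},{mol.GetNumBonds()}\\n")
' else '
import sys
from rdkit import Chem
from rdkit.Chem import BRICS
with open(sys.argv[1]) as f, open(sys.argv[2], "w") as o:
    for line in f:
        mol = Chem.MolFromSmiles(line.strip())
        cuts = sorted(tuple(sorted(b[0])) for b in BRICS.FindBRICSBonds(mol))
        o.write(";".join(f"{a}-{b}" for a, b in cuts) + "\\n")
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, inp, out), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  readLines(out)
}

# Format a cut-bond matrix (1-based) the way the reference does (0-based).
format_cuts <- function(cuts) {
  if (nrow(cuts) == 0L) return("")
  ord <- order(cuts[, 1L], cuts[, 2L])
  paste(cuts[ord, 1L] - 1L, cuts[ord, 2L] - 1L, sep = "-", collapse = ";")
}
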