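# Generative channel: fragment-level masked autoencoding.
#
# A random subset of atoms has its features replaced by a mask token; the
# encoder and a single-layer GIN decoder then run with message passing
# restricted to intra-fragment bonds, so a masked atom can only be
# reconstructed from its own fragment's context.  Before decoding, the
# hidden states at masked positions are re-masked with a learned token so
# the decoder must rely on neighbors rather than the encoder's output at
# the masked position itself.  The loss is the scaled cosine error
# (1 - cos)^gamma between the reconstruction and the clean embedded atom
# features, averaged over each molecule's masked set and then over the
# batch.

#' Generative-channel configuration
#'
#' @param mask_ratio Fraction of atoms to mask, in (0, 1); candidate
#'   values of interest span 0.1-0.6, default 0.3.
#' @param gamma Scaling exponent of the cosine error, >= 1 (default 2).
#' @param remask_before_decode Replace masked positions' hidden states
#'   with a learned token before decoding (default TRUE).
#' @return A `generative_config` list.
#' @export
generative_config <- function(mask_ratio = 0.3, gamma = 2,
                              remask_before_decode = TRUE) {
  stopifnot(mask_ratio > 0, mask_ratio < 1, gamma >= 1)
  structure(list(mask_ratio = mask_ratio, gamma = gamma,
                 remask_before_decode = isTRUE(remask_before_decode)),
            class = "generative_config")
}

#' Sample a node mask for one molecule
#'
#' Draws `max(1, floor(ratio * n))` atoms uniformly without replacement
#' (at least one whenever the molecule has two or more atoms, so every
#' such molecule yields a learning signal; a single-atom molecule is
#' never masked).  Deterministic given the R random seed.
#'
#' @param graph A `molecular_graph`.
#' @param ratio Mask ratio in (0, 1).
#' @return A `mask_spec`: list with `masked_atoms` (integer indices),
#'   `mask_ratio`, and `mask_token` (the reserved atom-type slot).
#' @export
sample_mask <- function(graph, ratio) {
  if (!(ratio > 0 && ratio < 1)) {
    stop("mask ratio must lie strictly between 0 and 1")
  }
  n <- graph$num_atoms
  k <- if (n >= 2L) max(1L, floor(ratio * n)) else 0L
  masked <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
  structure(list(masked_atoms = masked, mask_ratio = ratio,
                 mask_token = mol_vocab()$mask_atom_type),
            class = "mask_spec")
}

# Intra-fragment bond filter: TRUE for bonds whose endpoints share a
# fragment.
intra_fragment_bonds <- function(graph, assignment) {
  bl <- graph$bond_list
  if (nrow(bl) == 0L) return(logical(0))
  fa <- assignment$fragment_of_atom
  fa[bl[, 1L]] == fa[bl[, 2L]]
}

# Tape routine for the reconstruction pass over a (batched) graph.
# Returns tape id of reconstructed embeddings for all atoms plus the
# constant clean targets (embedded atom features, detached).
ag_reconstruct <- function(tp, P, batch, enc_config, gen_config, bn_state,
                           training, masked_global, keep_bonds,
                           vocab = mol_vocab()) {
  out <- gin_forward(tp, P, batch, enc_config, bn_state, training,
                     keep_bonds = keep_bonds, mask_atoms = masked_global,
                     vocab = vocab)
  h <- out$node
  if (gen_config$remask_before_decode && length(masked_global) > 0) {
    m <- matrix(0, batch$n_total, 1L)
    m[masked_global, 1L] <- 1
    h <- ag_add(tp, ag_cmul(tp, h, 1 - m),
                ag_matmul(tp, ag_const(tp, m), P$dec_mask))
  }
  z <- gin_decoder_forward(tp, P, h, batch, enc_config, bn_state, training,
                           keep_bonds = keep_bonds, vocab = vocab)
  z <- ag_add(tp, ag_matmul(tp, z, P$dec_out_W), P$dec_out_b)
  z
}

# Clean atom-feature embeddings (the reconstruction target) as numeric
# values; the tape-side equivalent is ag_clean_targets below.
clean_targets <- function(params, batch) {
  params$atom_type_emb[batch$atom_type, , drop = FALSE] +
    params$chirality_emb[batch$chirality, , drop = FALSE]
}

ag_clean_targets <- function(tp, P, batch) {
  ag_add(tp, ag_lookup(tp, P$atom_type_emb, batch$atom_type),
         ag_lookup(tp, P$chirality_emb, batch$chirality))
}

#' Reconstruct masked atom features for one molecule
#'
#' Runs the masked, fragment-restricted encoder and the single-layer GIN
#' decoder, and returns the reconstructed representation of each masked
#' atom alongside its clean target (the embedded atom features).
#'
#' @param model A `fragssl_model` or checkpoint model.
#' @param graph A `molecular_graph`.
#' @param mask A `mask_spec` for this graph.
#' @param assignment The graph's `fragment_assignment`.
#' @param gen_config A [generative_config()].
#' @param training Logical, normalization mode (see [encode()]).
#' @return List with `reconstruction` and `target`, each
#'   `length(masked_atoms)` x D.
#' @export
reconstruct <- function(model, graph, mask, assignment,
                        gen_config = generative_config(),
                        training = FALSE) {
  stopifnot(inherits(mask, "mask_spec"),
            inherits(assignment, "fragment_assignment"),
            length(assignment$fragment_of_atom) == graph$num_atoms)
  batch <- build_batch(graph)
  keep <- intra_fragment_bonds(graph, assignment)
  tp <- ag_tape()
  P <- push_params(tp, model$params)
  st <- if (training) model$bn_state else copy_bn_state(model$bn_state)
  z <- ag_reconstruct(tp, P, batch, model$config, gen_config, st, training,
                      masked_global = mask$masked_atoms, keep_bonds = keep,
                      vocab = model$vocab)
  targets <- clean_targets(model$params, batch)
  list(reconstruction = ag_val(tp, z)[mask$masked_atoms, , drop = FALSE],
       target = targets[mask$masked_atoms, , drop = FALSE])
}

# Tape version of the scaled cosine error.  `z` and `targets` are tape
# ids of reconstructions and clean targets for the masked atoms (rows
# aligned); `weights` carries 1 / (|B| * |V_i|) per row.  The targets
# stay on the tape: the loss is differentiated through both sides of the
# cosine, since the target embeddings are themselves learned.
ag_sce <- function(tp, z, targets, weights, gamma) {
  cosv <- ag_rowsums(tp, ag_mul(tp, ag_rownorm(tp, z),
                                ag_rownorm(tp, targets)))
  term <- ag_pow(tp, ag_cadd(tp, ag_cmul(tp, cosv, -1), 1), gamma)
  ag_sum(tp, ag_cmul(tp, term, matrix(weights, ncol = 1L)))
}

#' Scaled cosine error between targets and reconstructions
#'
#' Computes `mean_i (1/|V_i|) sum_v (1 - cos(x_v, z_v))^gamma`, where the
#' inner sum runs over molecule `i`'s masked atoms.  Each per-atom term
#' lies in `[0, 2^gamma]`; the loss is zero iff every reconstruction is
#' positively collinear with its target, and the error is invariant to
#' positive rescaling of either argument.
#'
#' @param targets Masked-atoms x D matrix of clean feature embeddings.
#' @param reconstructions Matching matrix of reconstructed vectors.
#' @param groups Integer vector mapping each row to its molecule; `NULL`
#'   treats all rows as one molecule.
#' @param gamma Scaling exponent, >= 1.
#' @param n_mol Number of molecules in the batch average (defaults to the
#'   number of distinct groups); molecules with no masked atoms
#'   contribute zero.
#' @return Scalar loss value; zero rows of input are an error.
#' @export
scaled_cosine_error <- function(targets, reconstructions, groups = NULL,
                                gamma = 2, n_mol = NULL) {
  stopifnot(is.matrix(targets), is.matrix(reconstructions),
            all(dim(targets) == dim(reconstructions)), gamma >= 1)
  if (nrow(targets) == 0L) return(0)
  if (any(rowSums(targets^2) == 0) || any(rowSums(reconstructions^2) == 0)) {
    stop("zero-norm vector in scaled cosine error")
  }
  if (is.null(groups)) groups <- rep(1L, nrow(targets))
  if (is.null(n_mol)) n_mol <- length(unique(groups))
  sizes <- table(groups)[as.character(groups)]
  weights <- 1 / (n_mol * as.numeric(sizes))
  tp <- ag_tape()
  z <- ag_node(tp, reconstructions)
  tg <- ag_node(tp, targets)
  as.numeric(ag_val(tp, ag_sce(tp, z, tg, weights, gamma)))
}
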