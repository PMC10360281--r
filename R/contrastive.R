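# Contrastive channel: fragment-attentive molecular view vs. plain
# atom-level view, aligned with an InfoNCE objective.
#
# For each molecule, node embeddings are mean-pooled within BRICS
# fragments; a self-attention network (query/key/value projections shared
# across the batch) scores each fragment with a scaled dot-product logit
# q.k/sqrt(D), the logits are softmaxed over the molecule's own
# fragments, and the fragment-view embedding is the weighted sum of the
# value vectors.  The atom view is the ordinary mean readout.  The critic
# is cosine similarity; the InfoNCE denominator runs over the whole batch
# including the positive itself.

#' Mean-pool node embeddings within fragments
#'
#' Row `m` of the result is the arithmetic mean of the node embeddings of
#' atoms assigned to fragment `m`.
#'
#' @param node_embeddings Atoms x D numeric matrix.
#' @param assignment A `fragment_assignment` covering all rows.
#' @return num_fragments x D matrix of fragment embeddings.
#' @export
fragment_mean_pool <- function(node_embeddings, assignment) {
  stopifnot(inherits(assignment, "fragment_assignment"),
            nrow(node_embeddings) == length(assignment$fragment_of_atom))
  fa <- assignment$fragment_of_atom
  sums <- rowsum(node_embeddings, group = fa)
  counts <- tabulate(fa, nbins = assignment$num_fragments)
  sums[order(as.integer(rownames(sums))), , drop = FALSE] / counts
}

# Tape version of attention pooling over fragments.  `hf` is the tape id
# of the stacked fragment embeddings, `mol_of_frag` maps each fragment to
# its molecule.  Returns tape ids of pooled embeddings and weights.
ag_attentive_pool <- function(tp, hf, mol_of_frag, n_mol, P,
                              logit_mode = "per_fragment") {
  D <- ncol(ag_val(tp, P$attn_Wq))
  q <- ag_matmul(tp, hf, P$attn_Wq)
  k <- ag_matmul(tp, hf, P$attn_Wk)
  v <- ag_matmul(tp, hf, P$attn_Wv)
  logits <- ag_cmul(tp, ag_rowsums(tp, ag_mul(tp, q, k)), 1 / sqrt(D))
  if (logit_mode == "batch_mean") {
    # literal batch-averaged logit: one shared value, uniform weights
    nf <- nrow(ag_val(tp, logits))
    mean_logit <- ag_cmul(tp, ag_sum(tp, logits), 1 / nf)
    logits <- ag_matmul(tp, ag_const(tp, matrix(1, nf, 1L)), mean_logit)
  }
  w <- ag_group_softmax(tp, logits, mol_of_frag, n_mol)
  pooled <- ag_scatter_sum(tp, ag_mul(tp, w, v), mol_of_frag, n_mol)
  list(pooled = pooled, weights = w)
}

#' Attention-weighted pooling of fragment embeddings
#'
#' Computes query/key/value projections of each fragment embedding,
#' scores fragments with scaled dot-product logits, softmaxes within each
#' molecule and returns the weighted sum of value vectors per molecule.
#' `logit_mode = "batch_mean"` replaces every logit by the batch average
#' (which makes the weights uniform); the default scores each fragment by
#' its own logit.
#'
#' @param fragment_embeddings Fragments x D matrix (all molecules in the
#'   batch stacked).
#' @param mol_of_frag Integer vector mapping each fragment row to its
#'   molecule (1-based, `n_mol` molecules).
#' @param params Named list with `attn_Wq`, `attn_Wk`, `attn_Wv` (D x D).
#' @param n_mol Number of molecules in the batch.
#' @param logit_mode `"per_fragment"` or `"batch_mean"`.
#' @return List: `pooled` (n_mol x D) and `weights` (one per fragment;
#'   nonnegative, summing to one within each molecule).
#' @export
attentive_pool <- function(fragment_embeddings, mol_of_frag, params,
                           n_mol = max(mol_of_frag),
                           logit_mode = c("per_fragment", "batch_mean")) {
  logit_mode <- match.arg(logit_mode)
  stopifnot(nrow(fragment_embeddings) == length(mol_of_frag),
            all(tabulate(mol_of_frag, n_mol) >= 1L))
  tp <- ag_tape()
  P <- list(attn_Wq = ag_node(tp, params$attn_Wq),
            attn_Wk = ag_node(tp, params$attn_Wk),
            attn_Wv = ag_node(tp, params$attn_Wv))
  hf <- ag_node(tp, fragment_embeddings)
  out <- ag_attentive_pool(tp, hf, mol_of_frag, n_mol, P, logit_mode)
  list(pooled = ag_val(tp, out$pooled),
       weights = as.numeric(ag_val(tp, out$weights)))
}

# Tape version of the InfoNCE loss with cosine critic; anchors are the
# fragment-view rows, positives the same-row atom-view embeddings.
ag_infonce <- function(tp, anchors, positives, tau) {
  B <- nrow(ag_val(tp, anchors))
  S <- ag_cmul(tp, ag_matmul(tp, ag_rownorm(tp, anchors),
                             ag_t(tp, ag_rownorm(tp, positives))), 1 / tau)
  Sv <- ag_val(tp, S)
  rowmax <- apply(Sv, 1L, max)
  E <- ag_exp(tp, ag_cadd(tp, S, matrix(-rowmax, ncol = 1L)))
  lse <- ag_cadd(tp, ag_log(tp, ag_rowsums(tp, E)), matrix(rowmax, ncol = 1L))
  pos <- ag_rowsums(tp, ag_cmul(tp, S, diag(B)))
  ag_cmul(tp, ag_sum(tp, ag_sub(tp, lse, pos)), 1 / B)
}

#' InfoNCE contrastive loss between two sets of molecule embeddings
#'
#' For each molecule `i` the fragment-view embedding is the anchor, the
#' same molecule's atom-view embedding is the positive, and every other
#' atom-view embedding in the batch is a negative.  The critic is cosine
#' similarity scaled by the temperature; the softmax denominator includes
#' the positive term, so the loss is bounded below by 0 and equals
#' `log(B)` when all embeddings collapse to a single direction.
#'
#' @param fragment_view Batch x D matrix of anchor embeddings.
#' @param atom_view Batch x D matrix of positive embeddings (same rows).
#' @param tau Positive temperature (default 0.1).
#' @return Scalar loss value.
#' @export
infonce_loss <- function(fragment_view, atom_view, tau = 0.1) {
  stopifnot(is.matrix(fragment_view), is.matrix(atom_view),
            nrow(fragment_view) == nrow(atom_view), tau > 0)
  if (nrow(fragment_view) < 2L) {
    stop("contrastive batch must contain at least 2 molecules")
  }
  if (any(rowSums(fragment_view^2) == 0) || any(rowSums(atom_view^2) == 0)) {
    stop("zero-norm embedding in contrastive batch")
  }
  tp <- ag_tape()
  a <- ag_node(tp, fragment_view)
  p <- ag_node(tp, atom_view)
  as.numeric(ag_val(tp, ag_infonce(tp, a, p, tau)))
}
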