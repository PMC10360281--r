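# GIN message-passing encoder.
#
# The backbone follows the common molecular-pretraining convention: atom
# features are embedded through per-field tables and summed; each layer
# adds self-loops carrying a dedicated bond-type slot, forms messages as
# neighbor state + embedded edge features, sum-aggregates them, and
# updates through a two-layer perceptron followed by batch normalization
# (ReLU between layers, none after the last).  The molecule embedding is
# the mean (or sum) of final-layer node embeddings.

#' Encoder configuration
#'
#' @param num_layers Number of message-passing layers (default 5).
#' @param hidden_dim Embedding width D (default 300).
#' @param dropout Dropout probability applied after each layer during
#'   training (0 for pretraining, 0.5 for downstream fine-tuning).
#' @param readout Graph readout, `"mean"` or `"sum"`.
#' @param norm `"batch"` for batch normalization after each layer's
#'   perceptron, `"none"` to disable (useful for exact hand-checks).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(num_layers = 5L, hidden_dim = 300L, dropout = 0,
                           readout = c("mean", "sum"),
                           norm = c("batch", "none")) {
  readout <- match.arg(readout)
  norm <- match.arg(norm)
  stopifnot(num_layers >= 1L, hidden_dim >= 1L, dropout >= 0, dropout < 1)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, readout = readout, norm = norm),
            class = "encoder_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

gin_layer_params <- function(D, vocab) {
  list(W1 = glorot(D, 2L * D), b1 = matrix(0, 1L, 2L * D),
       W2 = glorot(2L * D, D), b2 = matrix(0, 1L, D),
       gamma = matrix(1, 1L, D), beta = matrix(0, 1L, D),
       bond_type_emb = glorot(vocab$n_bond_type, D),
       bond_dir_emb = glorot(vocab$n_bond_dir, D))
}

flatten_layer <- function(lp, prefix) {
  stats::setNames(lp, paste0(prefix, "_", names(lp)))
}

# All trainable tensors for the full pretraining model (encoder, attention
# projections, decoder, mask tokens), as a flat named list of matrices.
init_model_params <- function(config, seed, vocab = mol_vocab()) {
  D <- config$hidden_dim
  with_seed(seed, {
    p <- list(atom_type_emb = glorot(vocab$n_atom_type, D),
              chirality_emb = glorot(vocab$n_chirality, D))
    for (k in seq_len(config$num_layers)) {
      p <- c(p, flatten_layer(gin_layer_params(D, vocab), paste0("enc", k)))
    }
    p <- c(p, list(attn_Wq = glorot(D, D), attn_Wk = glorot(D, D),
                   attn_Wv = glorot(D, D)))
    p <- c(p, flatten_layer(gin_layer_params(D, vocab), "dec"))
    p <- c(p, list(dec_mask = glorot(1L, D),
                   dec_out_W = glorot(D, D), dec_out_b = matrix(0, 1L, D)))
    p
  })
}

# Fresh running-statistics containers for every batch-norm layer.
init_bn_state <- function(config) {
  D <- config$hidden_dim
  mk <- function() {
    e <- new.env(parent = emptyenv())
    e$mean <- rep(0, D)
    e$var <- rep(1, D)
    e
  }
  st <- lapply(seq_len(config$num_layers), function(k) mk())
  names(st) <- paste0("enc", seq_len(config$num_layers))
  st$dec <- mk()
  st
}

bn_state_to_list <- function(st) {
  lapply(st, function(e) list(mean = e$mean, var = e$var))
}

bn_state_from_list <- function(lst) {
  out <- lapply(lst, function(x) {
    e <- new.env(parent = emptyenv())
    e$mean <- x$mean
    e$var <- x$var
    e
  })
  names(out) <- names(lst)
  out
}

copy_bn_state <- function(st) bn_state_from_list(bn_state_to_list(st))

#' Assemble a model object
#'
#' Bundles configuration, trainable parameters, normalization statistics
#' and the featurization vocabulary.  Freshly initialized models use
#' Glorot (uniform) initialization under the given seed.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `fragssl_model`.
#' @export
init_model <- function(config = encoder_config(), seed = 42L) {
  structure(list(config = config,
                 vocab = mol_vocab(),
                 params = init_model_params(config, seed),
                 bn_state = init_bn_state(config)),
            class = "fragssl_model")
}

# ---------------------------------------------------------------------------
# Batched graph representation: molecules are stacked block-diagonally.

build_batch <- function(graphs) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  n_each <- vapply(graphs, function(g) g$num_atoms, integer(1))
  offset <- c(0L, cumsum(n_each))
  atom_type <- unlist(lapply(graphs, function(g) g$atom_features[, 1L]))
  chirality <- unlist(lapply(graphs, function(g) g$atom_features[, 2L]))
  mol_idx <- rep(seq_along(graphs), n_each)
  bonds <- do.call(rbind, c(list(matrix(integer(0), 0L, 4L)),
    lapply(seq_along(graphs), function(i) {
      g <- graphs[[i]]
      if (nrow(g$bond_list) == 0L) return(matrix(integer(0), 0L, 4L))
      cbind(g$bond_list + offset[i], g$bond_features)
    })))
  bond_mol <- rep(seq_along(graphs),
                  vapply(graphs, function(g) nrow(g$bond_list), integer(1)))
  list(graphs = graphs, n_total = sum(n_each), n_mol = length(graphs),
       n_each = n_each, offset = offset,
       atom_type = as.integer(atom_type), chirality = as.integer(chirality),
       mol_idx = mol_idx, bonds = bonds, bond_mol = bond_mol)
}

# Forward pass on the tape.  `P` maps parameter names to tape node ids.
# `keep_bonds` is a logical over the batch's undirected bond rows;
# `mask_atoms` replaces those atoms' features with the mask token before
# embedding.  Returns tape ids for node and molecule embeddings.
gin_forward <- function(tp, P, batch, config, bn_state, training,
                        keep_bonds = NULL, mask_atoms = NULL,
                        vocab = mol_vocab()) {
  n <- batch$n_total
  at <- batch$atom_type
  ch <- batch$chirality
  if (!is.null(mask_atoms) && length(mask_atoms) > 0) {
    at[mask_atoms] <- vocab$mask_atom_type
    ch[mask_atoms] <- 1L
  }
  bonds <- batch$bonds
  if (!is.null(keep_bonds)) bonds <- bonds[keep_bonds, , drop = FALSE]
  # expand undirected bonds to both directions, then append self-loops
  src <- c(bonds[, 1L], bonds[, 2L], seq_len(n))
  dst <- c(bonds[, 2L], bonds[, 1L], seq_len(n))
  ebt <- c(bonds[, 3L], bonds[, 3L], rep(vocab$self_loop_bond, n))
  ebd <- c(bonds[, 4L], bonds[, 4L], rep(1L, n))

  h <- ag_add(tp, ag_lookup(tp, P$atom_type_emb, at),
              ag_lookup(tp, P$chirality_emb, ch))
  for (k in seq_len(config$num_layers)) {
    pre <- paste0("enc", k, "_")
    msg <- ag_add(tp, ag_lookup(tp, h, src),
                  ag_add(tp, ag_lookup(tp, P[[paste0(pre, "bond_type_emb")]], ebt),
                         ag_lookup(tp, P[[paste0(pre, "bond_dir_emb")]], ebd)))
    agg <- ag_scatter_sum(tp, msg, dst, n)
    z <- ag_add(tp, ag_matmul(tp, agg, P[[paste0(pre, "W1")]]),
                P[[paste0(pre, "b1")]])
    z <- ag_relu(tp, z)
    z <- ag_add(tp, ag_matmul(tp, z, P[[paste0(pre, "W2")]]),
                P[[paste0(pre, "b2")]])
    if (config$norm == "batch") {
      z <- ag_batchnorm(tp, z, P[[paste0(pre, "gamma")]],
                        P[[paste0(pre, "beta")]],
                        bn_state[[paste0("enc", k)]], training)
    }
    if (k < config$num_layers) z <- ag_relu(tp, z)
    z <- ag_dropout(tp, z, config$dropout, training)
    h <- z
  }
  pooled <- ag_scatter_sum(tp, h, batch$mol_idx, batch$n_mol)
  if (config$readout == "mean") {
    counts <- tabulate(batch$mol_idx, nbins = batch$n_mol)
    pooled <- ag_cmul(tp, pooled, matrix(1 / counts, ncol = 1L))
  }
  list(node = h, mol = pooled)
}

# Single-layer GIN decoder used by the generative channel.
gin_decoder_forward <- function(tp, P, h, batch, config, bn_state, training,
                                keep_bonds = NULL, vocab = mol_vocab()) {
  n <- batch$n_total
  bonds <- batch$bonds
  if (!is.null(keep_bonds)) bonds <- bonds[keep_bonds, , drop = FALSE]
  src <- c(bonds[, 1L], bonds[, 2L], seq_len(n))
  dst <- c(bonds[, 2L], bonds[, 1L], seq_len(n))
  ebt <- c(bonds[, 3L], bonds[, 3L], rep(vocab$self_loop_bond, n))
  ebd <- c(bonds[, 4L], bonds[, 4L], rep(1L, n))
  msg <- ag_add(tp, ag_lookup(tp, h, src),
                ag_add(tp, ag_lookup(tp, P$dec_bond_type_emb, ebt),
                       ag_lookup(tp, P$dec_bond_dir_emb, ebd)))
  agg <- ag_scatter_sum(tp, msg, dst, n)
  z <- ag_relu(tp, ag_add(tp, ag_matmul(tp, agg, P$dec_W1), P$dec_b1))
  z <- ag_add(tp, ag_matmul(tp, z, P$dec_W2), P$dec_b2)
  if (config$norm == "batch") {
    z <- ag_batchnorm(tp, z, P$dec_gamma, P$dec_beta, bn_state$dec, training)
  }
  z
}

# Push every parameter onto a tape; returns name -> node id.
push_params <- function(tp, params) {
  ids <- lapply(params, function(v) ag_node(tp, v))
  names(ids) <- names(params)
  ids
}

#' Encode molecules into node and molecule embeddings
#'
#' Runs the message-passing encoder and the readout.  With
#' `edge_subset`, message passing is restricted to the given bonds of
#' each molecule (used by the generative channel to confine information
#' flow to intra-fragment bonds); `NULL` uses all bonds.
#'
#' @param model A `fragssl_model` or loaded checkpoint model.
#' @param graphs A `molecular_graph` or list of them.
#' @param edge_subset Optional list (one element per molecule) of logical
#'   vectors over that molecule's bonds, `TRUE` to keep.
#' @param training Logical; `TRUE` uses batch statistics for
#'   normalization and applies dropout, `FALSE` (default) uses running
#'   statistics and no dropout.
#' @return List with `node_embeddings` (atoms x D, molecules stacked, with
#'   attribute `"mol_idx"`) and `molecule_embedding` (molecules x D).
#' @export
encode <- function(model, graphs, edge_subset = NULL, training = FALSE) {
  stopifnot(inherits(model, "fragssl_model") ||
              inherits(model, "fragssl_checkpoint"))
  batch <- build_batch(graphs)
  keep <- NULL
  if (!is.null(edge_subset)) {
    keep <- unlist(edge_subset)
    stopifnot(length(keep) == nrow(batch$bonds))
  }
  tp <- ag_tape()
  P <- push_params(tp, model$params)
  st <- if (training) model$bn_state else copy_bn_state(model$bn_state)
  out <- gin_forward(tp, P, batch, model$config, st, training,
                     keep_bonds = keep, vocab = model$vocab)
  node <- ag_val(tp, out$node)
  attr(node, "mol_idx") <- batch$mol_idx
  list(node_embeddings = node, molecule_embedding = ag_val(tp, out$mol))
}
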