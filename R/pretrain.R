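# Joint dual-channel pretraining: L = L_C + L_G, optimized with Adam.

#' Pretraining configuration
#'
#' Defaults mirror the common molecular-pretraining recipe: batch size
#' 256, learning rate 0.001, seed 42, a 5-layer 300-dimensional GIN with
#' zero dropout, temperature 0.1, mask ratio 0.3, gamma 2.
#'
#' @param batch_size Molecules per optimization step (>= 2; the
#'   contrastive loss needs at least one in-batch negative).
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the library.
#' @param seed Integer seed governing initialization, shuffling and mask
#'   sampling.
#' @param tau InfoNCE temperature (> 0).
#' @param mask_ratio,gamma,remask_before_decode Generative-channel knobs,
#'   see [generative_config()].
#' @param attention_logit_mode `"per_fragment"` (default) or
#'   `"batch_mean"`, see [attentive_pool()].
#' @param encoder An [encoder_config()].
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(batch_size = 256L, learning_rate = 0.001,
                            epochs = 100L, seed = 42L, tau = 0.1,
                            mask_ratio = 0.3, gamma = 2,
                            remask_before_decode = TRUE,
                            attention_logit_mode = c("per_fragment",
                                                     "batch_mean"),
                            encoder = encoder_config()) {
  attention_logit_mode <- match.arg(attention_logit_mode)
  stopifnot(batch_size >= 2L, learning_rate > 0, epochs >= 1L, tau > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 tau = tau,
                 generative = generative_config(mask_ratio, gamma,
                                                remask_before_decode),
                 attention_logit_mode = attention_logit_mode,
                 encoder = encoder),
            class = "pretrain_config")
}

# --- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

# --- joint loss on one batch ----------------------------------------------

# Builds the full dual-channel loss for a batch of graphs on a fresh
# tape.  `masks` is a list of mask_spec aligned with `graphs`.  BN state
# is copied unless update_bn = TRUE (the training loop passes TRUE so
# running statistics track the data).  Returns the loss values and, when
# want_grads, the gradient for every parameter.
pretrain_batch_loss <- function(params, graphs, assignments, masks, config,
                                bn_state, training = TRUE,
                                update_bn = FALSE, want_grads = TRUE,
                                vocab = mol_vocab()) {
  B <- length(graphs)
  stopifnot(B >= 2L, length(assignments) == B, length(masks) == B)
  batch <- build_batch(graphs)
  st <- if (update_bn) bn_state else copy_bn_state(bn_state)

  # global fragment indexing across the batch
  nf_each <- vapply(assignments, function(a) a$num_fragments, integer(1))
  frag_offset <- c(0L, cumsum(nf_each))
  frag_of_atom <- unlist(lapply(seq_len(B), function(i) {
    assignments[[i]]$fragment_of_atom + frag_offset[i]
  }))
  n_frag <- sum(nf_each)
  mol_of_frag <- rep(seq_len(B), nf_each)

  masked_global <- unlist(lapply(seq_len(B), function(i) {
    masks[[i]]$masked_atoms + batch$offset[i]
  }))
  mol_of_masked <- batch$mol_idx[masked_global]
  keep_bonds <- unlist(lapply(seq_len(B), function(i) {
    intra_fragment_bonds(graphs[[i]], assignments[[i]])
  }))

  tp <- ag_tape()
  P <- push_params(tp, params)

  # contrastive channel: full-graph pass
  full <- gin_forward(tp, P, batch, config$encoder, st, training,
                      vocab = vocab)
  frag_counts <- tabulate(frag_of_atom, nbins = n_frag)
  hf <- ag_cmul(tp, ag_scatter_sum(tp, full$node, frag_of_atom, n_frag),
                matrix(1 / frag_counts, ncol = 1L))
  att <- ag_attentive_pool(tp, hf, mol_of_frag, B, P,
                           config$attention_logit_mode)
  lc <- ag_infonce(tp, att$pooled, full$mol, config$tau)

  # generative channel: masked, fragment-restricted pass
  if (length(masked_global) > 0) {
    z <- ag_reconstruct(tp, P, batch, config$encoder, config$generative, st,
                        training, masked_global, keep_bonds, vocab = vocab)
    zm <- ag_lookup(tp, z, masked_global)
    targets <- ag_lookup(tp, ag_clean_targets(tp, P, batch), masked_global)
    sizes <- tabulate(mol_of_masked, nbins = B)[mol_of_masked]
    weights <- 1 / (B * sizes)
    lg <- ag_sce(tp, zm, targets, weights, config$generative$gamma)
  } else {
    lg <- ag_const(tp, matrix(0, 1L, 1L))
  }

  loss <- ag_add(tp, lc, lg)
  out <- list(loss = as.numeric(ag_val(tp, loss)),
              loss_contrastive = as.numeric(ag_val(tp, lc)),
              loss_generative = as.numeric(ag_val(tp, lg)))
  if (!is.finite(out$loss)) stop("non-finite pretraining loss")
  if (want_grads) {
    grads <- ag_backward(tp, loss)
    out$grads <- lapply(P, function(id) grads[[id]])
  }
  out
}

#' Pretrain the encoder on an unlabeled molecule library
#'
#' Runs joint optimization of the contrastive and generative losses
#' (their unweighted sum) over the library.  Molecules that fail to
#' parse are dropped with a warning carrying the count.  Incomplete
#' trailing batches of size < 2 are skipped.  All parameters are
#' Glorot-initialized under the configuration seed, which also governs
#' shuffling and mask sampling, so runs are exactly reproducible.
#'
#' @param library A list of `molecular_graph` objects or a character
#'   vector of SMILES.
#' @param config A [pretrain_config()].
#' @param verbose Print per-epoch losses.
#' @param log_file Optional path; per-epoch records are appended as JSON
#'   lines.
#' @return A `fragssl_checkpoint` (also usable as a `fragssl_model`):
#'   config, vocabulary, trained parameters, normalization statistics and
#'   the per-epoch loss log (`$log`, columns epoch/loss/
#'   loss_contrastive/loss_generative/n_steps).
#' @export
pretrain <- function(library, config = pretrain_config(), verbose = FALSE,
                     log_file = NULL) {
  if (is.character(library)) {
    graphs <- parse_smiles_set(library)
    if (any(bad <- vapply(graphs, is.null, logical(1)))) {
      warning(sum(bad), " molecule(s) dropped: unparseable SMILES")
      graphs <- graphs[!bad]
    }
  } else {
    graphs <- library
  }
  if (length(graphs) == 0L) stop("empty pretraining library")
  assignments <- lapply(graphs, brics_partition)

  n <- length(graphs)
  vocab <- mol_vocab()
  log_rows <- vector("list", config$epochs)

  with_seed(config$seed, {
    params <- init_model_params(config$encoder, seed = config$seed,
                                vocab = vocab)
    bn_state <- init_bn_state(config$encoder)
    opt <- adam_state(params)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tot <- c(loss = 0, lc = 0, lg = 0)
      steps <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        masks <- lapply(graphs[idx], sample_mask,
                        ratio = config$generative$mask_ratio)
        res <- pretrain_batch_loss(params, graphs[idx], assignments[idx],
                                   masks, config, bn_state,
                                   training = TRUE, update_bn = TRUE,
                                   want_grads = TRUE, vocab = vocab)
        params <- adam_update(params, res$grads, opt, config$learning_rate)
        tot <- tot + c(res$loss, res$loss_contrastive, res$loss_generative)
        steps <- steps + 1L
      }
      row <- data.frame(epoch = epoch, loss = tot[["loss"]] / steps,
                        loss_contrastive = tot[["lc"]] / steps,
                        loss_generative = tot[["lg"]] / steps,
                        n_steps = steps)
      log_rows[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  L=%.4f  (C=%.4f  G=%.4f)", epoch,
                        row$loss, row$loss_contrastive, row$loss_generative))
      }
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
            file = log_file, append = TRUE)
      }
    }
    structure(list(version = "1",
                   config = config$encoder,
                   pretrain_config = config,
                   vocab = vocab,
                   params = params,
                   bn_state = bn_state,
                   log = do.call(rbind, log_rows)),
              class = c("fragssl_checkpoint", "fragssl_model"))
  })
}

#' @export
print.fragssl_checkpoint <- function(x, ...) {
  lg <- x$log
  cat("<fragssl_checkpoint> ", x$config$num_layers, "-layer GIN, D=",
      x$config$hidden_dim, ", ", nrow(lg), " epoch(s); final loss ",
      signif(lg$loss[nrow(lg)], 5), "\n", sep = "")
  invisible(x)
}

#' Save / load a pretrained checkpoint
#'
#' Checkpoints are serialized with `saveRDS`, with normalization
#' statistics flattened to plain lists so the round trip reproduces
#' embeddings bit-for-bit.
#'
#' @param checkpoint A `fragssl_checkpoint`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  checkpoint$bn_state <- bn_state_to_list(checkpoint$bn_state)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$bn_state <- bn_state_from_list(ck$bn_state)
  ck
}
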