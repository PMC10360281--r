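# Downstream evaluation: Murcko scaffold splitting, fine-tuning with a
# task head, linear probing of frozen embeddings, ROC-AUC and RMSE.

# Murcko framework of a graph: ring systems plus the linkers between
# them, obtained by iteratively pruning non-ring atoms of degree <= 1.
# Returns the kept atom indices (possibly none for ring-free molecules).
murcko_atoms <- function(graph) {
  n <- graph$num_atoms
  bl <- graph$bond_list
  if (nrow(bl) == 0L) return(integer(0))
  ig <- igraph::make_graph(edges = as.vector(t(bl)), n = n, directed = FALSE)
  ring_bond <- rep(TRUE, nrow(bl))
  ring_bond[as.integer(igraph::bridges(ig))] <- FALSE
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    ring_atom[unique(as.vector(bl[ring_bond, , drop = FALSE]))] <- TRUE
  }
  if (!any(ring_atom)) return(integer(0))
  keep <- rep(TRUE, n)
  adj <- lapply(seq_len(n), function(a) integer(0))
  for (b in seq_len(nrow(bl))) {
    adj[[bl[b, 1L]]] <- c(adj[[bl[b, 1L]]], bl[b, 2L])
    adj[[bl[b, 2L]]] <- c(adj[[bl[b, 2L]]], bl[b, 1L])
  }
  repeat {
    deg <- vapply(seq_len(n), function(a) {
      if (!keep[a]) return(99L)
      sum(keep[adj[[a]]])
    }, integer(1))
    drop <- keep & !ring_atom & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep)
}

#' Murcko scaffold key of a molecule
#'
#' Computes the Murcko framework (rings plus linkers) and returns a
#' canonical string identifying it up to graph isomorphism, so molecules
#' sharing a scaffold map to the same key regardless of atom ordering.
#' Ring-free molecules share the empty scaffold `""`.  The
#' canonicalization colors atoms by element and aromaticity and encodes
#' bond orders through subdivision vertices, then applies a canonical
#' vertex ordering (BLISS, via igraph).
#'
#' @param graph A `molecular_graph`.
#' @return A scaffold key string.
#' @export
murcko_scaffold <- function(graph) {
  keep <- murcko_atoms(graph)
  if (length(keep) == 0L) return("")
  idx <- match(seq_len(graph$num_atoms), keep)  # old -> new (NA if dropped)
  bl <- graph$bond_list
  bkeep <- bl[, 1L] %in% keep & bl[, 2L] %in% keep
  bl <- bl[bkeep, , drop = FALSE]
  btype <- graph$bond_features[bkeep, 1L]
  na <- length(keep)
  nb <- nrow(bl)
  z <- .element_z[graph$element[keep]]
  z[is.na(z)] <- 119
  acolor <- as.integer(z * 2L + graph$aromatic_atom[keep])
  bcolor <- as.integer(1000L + btype)
  # bipartite encoding: bond b becomes vertex na + b joined to both ends
  edges <- integer(0)
  for (b in seq_len(nb)) {
    edges <- c(edges, idx[bl[b, 1L]], na + b, idx[bl[b, 2L]], na + b)
  }
  ig <- igraph::make_graph(edges = edges, n = na + nb, directed = FALSE)
  colors <- c(acolor, bcolor)
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  # serialize colors and edges under the canonical labeling
  ord_colors <- colors[order(perm)]
  canon_edges <- matrix(perm[edges], ncol = 2L, byrow = TRUE)
  canon_edges <- cbind(pmin(canon_edges[, 1L], canon_edges[, 2L]),
                       pmax(canon_edges[, 1L], canon_edges[, 2L]))
  ord <- order(canon_edges[, 1L], canon_edges[, 2L])
  paste0(paste(ord_colors, collapse = ","), "|",
         paste(canon_edges[ord, 1L], canon_edges[ord, 2L],
               sep = "-", collapse = ","))
}

#' Scaffold split of a dataset
#'
#' Groups molecules by Murcko scaffold key, orders the groups by
#' descending size (ties by first occurrence), and greedily assigns
#' whole groups: to the training set while it holds fewer than
#' `ratios[1]` of the molecules, then to validation while it holds fewer
#' than `ratios[2]`, and the remainder to test.  Whole-group assignment
#' guarantees no scaffold spans two subsets, constructing the
#' out-of-distribution evaluation scenario.
#'
#' @param x A `labeled_dataset` or list of `molecular_graph` objects.
#' @param ratios Length-3 train/valid/test fractions summing to 1.
#' @return A `scaffold_split`: list of disjoint index vectors `train`,
#'   `valid`, `test` covering all molecules.
#' @export
scaffold_split <- function(x, ratios = c(0.8, 0.1, 0.1)) {
  graphs <- if (inherits(x, "labeled_dataset")) x$graphs else x
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  n <- length(graphs)
  keys <- vapply(graphs, murcko_scaffold, character(1))
  groups <- split(seq_len(n), factor(keys, levels = unique(keys)))
  sizes <- lengths(groups)
  first <- vapply(groups, min, integer(1))
  ord <- order(-sizes, first)
  train <- integer(0); valid <- integer(0); test <- integer(0)
  for (g in ord) {
    if (length(train) < ratios[1] * n) {
      train <- c(train, groups[[g]])
    } else if (length(valid) < ratios[2] * n) {
      valid <- c(valid, groups[[g]])
    } else {
      test <- c(test, groups[[g]])
    }
  }
  if (length(valid) == 0L || length(test) == 0L) {
    warning("scaffold split produced an empty validation or test subset; ",
            "too few scaffold groups for the requested ratios")
  }
  structure(list(train = sort(train), valid = sort(valid),
                 test = sort(test)),
            class = "scaffold_split")
}

# --- metrics ---------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based AUC with ties contributing 1/2 (equivalent to trapezoidal
#' integration of the ROC curve, with the true-positive rate TP/(TP+FN)
#' on the vertical axis and the false-positive rate FP/(FP+TN) on the
#' horizontal).  Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param labels Binary 0/1 vector (both classes must be present).
#' @param scores Numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    cond <- structure(
      class = c("fragssl_metric_error", "error", "condition"),
      list(message = "ROC-AUC undefined: only one class present",
           call = sys.call(-1)))
    stop(cond)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root mean squared error
#'
#' @param labels Observed values.
#' @param predictions Predicted values (same length, n >= 1).
#' @return `sqrt(mean((labels - predictions)^2))`.
#' @export
rmse <- function(labels, predictions) {
  ok <- !is.na(labels) & !is.na(predictions)
  labels <- labels[ok]; predictions <- predictions[ok]
  if (length(labels) == 0L) stop("RMSE undefined on empty input")
  sqrt(mean((labels - predictions)^2))
}

# mean test metric across tasks, skipping undefined ones with a warning
multitask_metric <- function(labels, scores, task_kind) {
  vals <- vapply(seq_len(ncol(labels)), function(t) {
    if (task_kind == "classification") {
      tryCatch(roc_auc(labels[, t], scores[, t]),
               fragssl_metric_error = function(e) NA_real_)
    } else {
      rmse(labels[, t], scores[, t])
    }
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " task(s) skipped: single-class labels")
  }
  list(per_task = vals, mean = mean(vals, na.rm = TRUE))
}

# --- fine-tuning -----------------------------------------------------------

# Supervised loss on the tape: masked binary cross-entropy with logits,
# or masked squared error.
ag_supervised_loss <- function(tp, logits, y, task_kind) {
  mask <- !is.na(y)
  w <- matrix(0, nrow(y), ncol(y))
  w[mask] <- 1 / sum(mask)
  yc <- y
  yc[!mask] <- 0
  if (task_kind == "classification") {
    # stable BCE: max(z,0) - z*y + log(1 + exp(-|z|))
    t1 <- ag_relu(tp, logits)
    t2 <- ag_cmul(tp, logits, yc)
    t3 <- ag_log(tp, ag_cadd(tp, ag_exp(tp, ag_cmul(tp, ag_abs(tp, logits),
                                                    -1)), 1))
    ag_sum(tp, ag_cmul(tp, ag_add(tp, ag_sub(tp, t1, t2), t3), w))
  } else {
    ag_sum(tp, ag_cmul(tp, ag_pow(tp, ag_cadd(tp, logits, -yc), 2), w))
  }
}

#' Fine-tune a pretrained encoder on a labeled dataset
#'
#' Attaches a linear head to the molecule embedding and trains with Adam
#' (sigmoid cross-entropy per task for classification, ignoring missing
#' labels; squared error for regression).  By default encoder and head
#' are updated jointly with dropout 0.5 in the encoder; with
#' `freeze_encoder = TRUE` embeddings are computed once in evaluation
#' mode and only the head is fit.  The epoch with the best validation
#' metric is selected and the test metric of that epoch's model is
#' reported.
#'
#' @param checkpoint A `fragssl_checkpoint`.
#' @param dataset A `labeled_dataset` with compatible featurization.
#' @param split A `scaffold_split` (validation must be non-empty).
#' @param seed Seed for head initialization, shuffling and dropout.
#' @param epochs,learning_rate,batch_size,dropout Optimization knobs.
#' @param freeze_encoder Fit the head only, on frozen embeddings.
#' @param verbose Print per-epoch validation metric.
#' @return A `finetune_result`: fitted model, `best_epoch`,
#'   `valid_metric`, `test_metric`, per-task test values, and the metric
#'   name (`"roc_auc"` or `"rmse"`).
#' @export
finetune <- function(checkpoint, dataset, split, seed = 0L, epochs = 50L,
                     learning_rate = 0.001, batch_size = 32L, dropout = 0.5,
                     freeze_encoder = FALSE, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(split, "scaffold_split"))
  if (length(split$valid) == 0L) {
    stop("empty validation split; adjust the split ratios")
  }
  task_kind <- dataset$task_kind
  metric_name <- if (task_kind == "classification") "roc_auc" else "rmse"
  better <- if (task_kind == "classification") `>` else `<`
  Tn <- ncol(dataset$labels)
  D <- checkpoint$config$hidden_dim

  cfg <- checkpoint$config
  cfg$dropout <- dropout
  vocab <- checkpoint$vocab

  with_seed(seed, {
    params <- checkpoint$params
    params$head_W <- glorot(D, Tn)
    params$head_b <- matrix(0, 1L, Tn)
    bn_state <- copy_bn_state(checkpoint$bn_state)
    opt <- adam_state(params)

    frozen_emb <- NULL
    if (freeze_encoder) {
      model <- structure(list(config = checkpoint$config, vocab = vocab,
                              params = checkpoint$params,
                              bn_state = bn_state),
                         class = "fragssl_model")
      frozen_emb <- encode(model, dataset$graphs)$molecule_embedding
    }

    predict_logits <- function(p, st, idx) {
      if (freeze_encoder) {
        emb <- frozen_emb[idx, , drop = FALSE]
      } else {
        model <- structure(list(config = checkpoint$config, vocab = vocab,
                                params = p, bn_state = st),
                           class = "fragssl_model")
        emb <- encode(model, dataset$graphs[idx])$molecule_embedding
      }
      emb %*% p$head_W + matrix(p$head_b, nrow(emb), Tn, byrow = TRUE)
    }

    eval_metric <- function(p, st, idx) {
      multitask_metric(dataset$labels[idx, , drop = FALSE],
                       predict_logits(p, st, idx), task_kind)$mean
    }

    train_idx <- split$train
    best <- list(metric = if (task_kind == "classification") -Inf else Inf,
                 params = params, bn = bn_state_to_list(bn_state),
                 epoch = 0L)
    for (epoch in seq_len(epochs)) {
      perm <- sample(train_idx)
      for (s in seq(1L, length(perm), by = batch_size)) {
        idx <- perm[s:min(s + batch_size - 1L, length(perm))]
        y <- dataset$labels[idx, , drop = FALSE]
        if (all(is.na(y))) next
        tp <- ag_tape()
        if (freeze_encoder) {
          Pids <- list(head_W = ag_node(tp, params$head_W),
                       head_b = ag_node(tp, params$head_b))
          emb <- ag_const(tp, frozen_emb[idx, , drop = FALSE])
        } else {
          Pids <- push_params(tp, params)
          out <- gin_forward(tp, Pids, build_batch(dataset$graphs[idx]),
                             cfg, bn_state, training = TRUE, vocab = vocab)
          emb <- out$mol
        }
        logits <- ag_add(tp, ag_matmul(tp, emb, Pids$head_W), Pids$head_b)
        loss <- ag_supervised_loss(tp, logits, y, task_kind)
        grads <- ag_backward(tp, loss)
        g <- lapply(Pids, function(id) grads[[id]])
        params <- adam_update(params, g, opt, learning_rate)
      }
      vm <- suppressWarnings(eval_metric(params, bn_state, split$valid))
      if (verbose) message(sprintf("epoch %3d  valid %s = %.4f", epoch,
                                   metric_name, vm))
      if (is.finite(vm) && better(vm, best$metric)) {
        best <- list(metric = vm, params = params,
                     bn = bn_state_to_list(bn_state), epoch = epoch)
      }
    }

    bn_best <- bn_state_from_list(best$bn)
    test_scores <- predict_logits(best$params, bn_best, split$test)
    tm <- multitask_metric(dataset$labels[split$test, , drop = FALSE],
                           test_scores, task_kind)
    model <- structure(list(config = checkpoint$config, vocab = vocab,
                            params = best$params, bn_state = bn_best),
                       class = "fragssl_model")
    structure(list(model = model, best_epoch = best$epoch,
                   valid_metric = best$metric, test_metric = tm$mean,
                   per_task = tm$per_task, metric_name = metric_name),
              class = "finetune_result")
  })
}

#' Fine-tune across several seeds and summarize
#'
#' Repeats [finetune()] under each seed and reports the mean and
#' standard deviation of the test metric, the standard protocol for
#' scaffold-split molecular benchmarks.
#'
#' @inheritParams finetune
#' @param seeds Integer vector of seeds (default `c(0, 1, 2)`).
#' @param ... Passed to [finetune()].
#' @return A `metric_result`: metric name, per-seed values, `mean`, `sd`,
#'   and the per-task means.
#' @export
finetune_runs <- function(checkpoint, dataset, split, seeds = c(0L, 1L, 2L),
                          ...) {
  runs <- lapply(seeds, function(s) {
    finetune(checkpoint, dataset, split, seed = s, ...)
  })
  vals <- vapply(runs, function(r) r$test_metric, numeric(1))
  nt <- length(runs[[1]]$per_task)
  per_task <- rowMeans(matrix(vapply(runs, function(r) r$per_task,
                                     numeric(nt)), nrow = nt))
  structure(list(metric_name = runs[[1]]$metric_name, values = vals,
                 mean = mean(vals), sd = stats::sd(vals),
                 per_task = per_task, seeds = seeds),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat("<metric_result> ", x$metric_name, " = ", signif(x$mean, 4), " +/- ",
      signif(x$sd, 4), " over ", length(x$values), " seed(s)\n", sep = "")
  invisible(x)
}

#' Linear probe of frozen embeddings
#'
#' Encodes all molecules in evaluation mode, fits a ridge-regularized
#' linear model (logistic for classification) on the training subset of
#' the first task, and reports the test metric.  A fast, deterministic
#' readout of how linearly separable the downstream signal already is in
#' the pretrained embedding space.
#'
#' @param checkpoint A `fragssl_checkpoint` or `fragssl_model`.
#' @param dataset A `labeled_dataset` (first task column is used).
#' @param split A `scaffold_split`.
#' @param lambda Ridge penalty (default 0.01).
#' @return List with `metric_name`, `test_metric` and the test scores.
#' @export
linear_probe <- function(checkpoint, dataset, split, lambda = 0.01) {
  emb <- encode(checkpoint, dataset$graphs)$molecule_embedding
  y <- dataset$labels[, 1L]
  tr <- split$train[!is.na(y[split$train])]
  te <- split$test[!is.na(y[split$test])]
  task_kind <- dataset$task_kind
  fam <- if (task_kind == "classification") "binomial" else "gaussian"
  fit <- glmnet::glmnet(emb[tr, , drop = FALSE], y[tr], family = fam,
                        alpha = 0, lambda = lambda, standardize = TRUE)
  scores <- as.numeric(stats::predict(fit, emb[te, , drop = FALSE]))
  if (task_kind == "classification") {
    list(metric_name = "roc_auc", test_metric = roc_auc(y[te], scores),
         scores = scores)
  } else {
    list(metric_name = "rmse", test_metric = rmse(y[te], scores),
         scores = scores)
  }
}

#' Molecule embeddings from a trained model
#'
#' @param model A `fragssl_model` or checkpoint.
#' @param x A character vector of SMILES or list of `molecular_graph`s.
#' @return Molecules x D matrix (rownames are SMILES where available).
#' @export
embed_molecules <- function(model, x) {
  graphs <- if (is.character(x)) {
    gs <- parse_smiles_set(x)
    if (any(vapply(gs, is.null, logical(1)))) {
      stop("unparseable SMILES in input")
    }
    gs
  } else if (inherits(x, "molecular_graph")) list(x) else x
  emb <- encode(model, graphs)$molecule_embedding
  rownames(emb) <- vapply(graphs, function(g) g$smiles %||% "", character(1))
  emb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
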