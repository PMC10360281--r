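frag_assign <- function(fa) {
  structure(list(fragment_of_atom = as.integer(fa),
                 num_fragments = max(as.integer(fa))),
            class = "fragment_assignment")
}

test_that("fragment mean pooling computes within-fragment means", {
  H <- matrix(as.numeric(1:12), 4, 3)
  # one fragment per atom: identity
  expect_equal(fragment_mean_pool(H, frag_assign(1:4)), H,
               ignore_attr = TRUE)
  # all atoms one fragment: the global mean
  expect_equal(fragment_mean_pool(H, frag_assign(rep(1, 4)))[1, ],
               colMeans(H))
  # fragments {1,2} and {3,4}
  out <- fragment_mean_pool(H, frag_assign(c(1, 1, 2, 2)))
  expect_equal(out[1, ], colMeans(H[1:2, ]))
  expect_equal(out[2, ], colMeans(H[3:4, ]))
})

test_that("attention pooling follows the scaled dot-product definition", {
  I2 <- diag(2)
  params <- list(attn_Wq = I2, attn_Wk = I2, attn_Wv = I2)
  # single fragment: weight 1, output = value projection
  out <- attentive_pool(matrix(c(1, 0), 1, 2), 1L, params, n_mol = 1L)
  expect_equal(out$weights, 1)
  expect_equal(out$pooled[1, ], c(1, 0))

  # identical fragments: uniform weights
  Hf <- matrix(1, 3, 2)
  out <- attentive_pool(Hf, rep(1L, 3), params, n_mol = 1L)
  expect_equal(out$weights, rep(1 / 3, 3))

  # worked two-fragment example: logits 1/sqrt(2) and 4/sqrt(2)
  Hf <- rbind(c(1, 0), c(0, 2))
  out <- attentive_pool(Hf, c(1L, 1L), params, n_mol = 1L)
  w <- exp(c(1, 4) / sqrt(2))
  w <- w / sum(w)
  expect_equal(out$weights, w, tolerance = 1e-12)
  expect_equal(out$pooled[1, ], w[1] * c(1, 0) + w[2] * c(0, 2),
               tolerance = 1e-12)
})

test_that("attention weights form a probability distribution per molecule", {
  set.seed(8)
  Hf <- matrix(rnorm(24), 8, 3)
  mof <- c(1L, 1L, 1L, 2L, 3L, 3L, 3L, 3L)
  params <- list(attn_Wq = matrix(rnorm(9), 3, 3),
                 attn_Wk = matrix(rnorm(9), 3, 3),
                 attn_Wv = matrix(rnorm(9), 3, 3))
  out <- attentive_pool(Hf, mof, params, n_mol = 3L)
  expect_true(all(out$weights >= 0))
  expect_equal(as.numeric(tapply(out$weights, mof, sum)), rep(1, 3),
               tolerance = 1e-12)
  # oracle agreement
  orc <- oracle_attentive_pool(Hf, mof, params$attn_Wq, params$attn_Wk,
                               params$attn_Wv)
  expect_equal(out$pooled, orc$pooled, tolerance = 1e-10)
  expect_equal(out$weights, orc$weights, tolerance = 1e-10)
})

test_that("batch_mean logit mode yields uniform weights", {
  set.seed(9)
  Hf <- matrix(rnorm(12), 4, 3)
  params <- list(attn_Wq = matrix(rnorm(9), 3, 3),
                 attn_Wk = matrix(rnorm(9), 3, 3),
                 attn_Wv = diag(3))
  out <- attentive_pool(Hf, c(1L, 1L, 1L, 2L), params, n_mol = 2L,
                        logit_mode = "batch_mean")
  expect_equal(out$weights, c(1/3, 1/3, 1/3, 1), tolerance = 1e-12)
})

test_that("InfoNCE matches closed forms and the scalar oracle", {
  # total collapse: loss = log(batch size)
  for (B in c(2L, 5L)) {
    A <- matrix(1, B, 3)
    expect_equal(infonce_loss(A, A, tau = 0.37), log(B), tolerance = 1e-9)
  }

  # orthogonal two-molecule batch at tau = 1: each term log(1 + e^-1)
  A <- rbind(c(1, 0), c(0, 1))
  expect_equal(infonce_loss(A, A, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-9)

  # sharp temperature with separated similarities drives the loss to 0,
  # and the loss is monotone in tau in this regime
  taus <- c(0.5, 0.1, 0.01)
  losses <- vapply(taus, function(tau) infonce_loss(A, A, tau), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-10)

  # nonnegativity and oracle agreement on random batches
  set.seed(14)
  for (rep in 1:5) {
    anchors <- matrix(rnorm(12), 3, 4)
    positives <- matrix(rnorm(12), 3, 4)
    mine <- infonce_loss(anchors, positives, tau = 0.2)
    expect_gte(mine, 0)
    expect_equal(mine, oracle_infonce(anchors, positives, 0.2),
                 tolerance = 1e-10)
  }

  expect_error(infonce_loss(matrix(1, 1, 2), matrix(1, 1, 2)),
               "at least 2")
})

test_that("full contrastive pipeline matches a scalar recomputation", {
  set.seed(15)
  m <- tiny_model(D = 4, layers = 2)
  graphs <- lapply(c("CCOC(=O)c1ccccc1", "CC(=O)NCCC", "c1ccccc1OC"),
                   parse_smiles)
  asg <- lapply(graphs, brics_partition)
  enc <- encode(m, graphs)
  # fragment view, molecule by molecule, through exported functions
  Hf_list <- lapply(seq_along(graphs), function(i) {
    rows <- attr(enc$node_embeddings, "mol_idx") == i
    fragment_mean_pool(enc$node_embeddings[rows, , drop = FALSE], asg[[i]])
  })
  Hf <- do.call(rbind, Hf_list)
  mof <- rep(seq_along(graphs),
             vapply(asg, function(a) a$num_fragments, integer(1)))
  pooled <- attentive_pool(Hf, mof, m$params, n_mol = 3L)$pooled
  mine <- infonce_loss(pooled, enc$molecule_embedding, tau = 0.1)
  # scalar recomputation from the raw node embeddings
  orc_pool <- oracle_attentive_pool(Hf, mof, m$params$attn_Wq,
                                    m$params$attn_Wk, m$params$attn_Wv)
  orc <- oracle_infonce(orc_pool$pooled, enc$molecule_embedding, 0.1)
  expect_equal(mine, orc, tolerance = 1e-10)
})
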