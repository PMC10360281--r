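test_that("mask sampling respects the floor-with-minimum rule", {
  g10 <- make_graph(rep(6L, 10))
  set.seed(1)
  mk <- sample_mask(g10, 0.3)
  expect_length(mk$masked_atoms, 3L)            # floor(0.3 * 10)
  expect_true(all(mk$masked_atoms %in% 1:10))
  expect_equal(anyDuplicated(mk$masked_atoms), 0L)

  g2 <- make_graph(c(6L, 8L))
  set.seed(1)
  expect_length(sample_mask(g2, 0.05)$masked_atoms, 1L)  # minimum of one

  g1 <- make_graph(6L)
  expect_length(sample_mask(g1, 0.5)$masked_atoms, 0L)   # never mask n = 1

  expect_error(sample_mask(g10, 0), "between 0 and 1")
  expect_error(sample_mask(g10, 1.2), "between 0 and 1")

  set.seed(42); a <- sample_mask(g10, 0.4)
  set.seed(42); b <- sample_mask(g10, 0.4)
  expect_identical(a, b)
})

test_that("scaled cosine error matches its closed forms", {
  X <- matrix(rnorm(12), 3, 4)
  # equal vectors: zero loss for any gamma
  expect_equal(scaled_cosine_error(X, X, gamma = 1), 0, tolerance = 1e-12)
  expect_equal(scaled_cosine_error(X, X, gamma = 3), 0, tolerance = 1e-12)
  # orthogonal pairs: loss 1 for any gamma
  A <- rbind(c(1, 0), c(0, 2))
  B <- rbind(c(0, 3), c(5, 0))
  expect_equal(scaled_cosine_error(A, B, gamma = 1), 1)
  expect_equal(scaled_cosine_error(A, B, gamma = 7), 1)
  # antiparallel: per-pair term (1 - (-1))^gamma = 2^gamma
  expect_equal(scaled_cosine_error(X, -X, gamma = 2), 4)
  expect_equal(scaled_cosine_error(X, -X, gamma = 3), 8)
  # invariance to positive rescaling of either side
  set.seed(5)
  Z <- matrix(rnorm(12), 3, 4)
  expect_equal(scaled_cosine_error(X, Z), scaled_cosine_error(3.7 * X, Z),
               tolerance = 1e-12)
  expect_equal(scaled_cosine_error(X, Z), scaled_cosine_error(X, 0.2 * Z),
               tolerance = 1e-12)
  # per-node terms bounded by 2^gamma
  expect_lte(scaled_cosine_error(X, Z, gamma = 2), 4)
  # zero rows are rejected
  expect_error(scaled_cosine_error(rbind(c(0, 0)), rbind(c(1, 1))),
               "zero-norm")
  # empty masked set contributes zero by convention
  expect_equal(scaled_cosine_error(X[0, , drop = FALSE],
                                   Z[0, , drop = FALSE]), 0)
  # per-molecule averaging matches the scalar oracle
  grp <- c(1L, 1L, 2L)
  expect_equal(scaled_cosine_error(X, Z, groups = grp, gamma = 2),
               oracle_sce(X, Z, grp, 2), tolerance = 1e-12)
})

test_that("reconstruction matches a brute-force evaluation", {
  m <- tiny_model(D = 3, layers = 1, norm = "none")
  g <- make_graph(c(6L, 6L, 8L), rbind(c(1L, 2L), c(2L, 3L)))
  asg <- structure(list(fragment_of_atom = rep(1L, 3), num_fragments = 1L),
                   class = "fragment_assignment")
  mask <- structure(list(masked_atoms = 2L, mask_ratio = 0.3,
                         mask_token = mol_vocab()$mask_atom_type),
                    class = "mask_spec")
  out <- reconstruct(m, g, mask, asg)
  p <- m$params
  # oracle: masked input embedding, encoder layer, re-mask, decoder layer,
  # output projection
  vk <- mol_vocab()
  types <- c(6L, vk$mask_atom_type, 8L)
  H0 <- p$atom_type_emb[types, ] + p$chirality_emb[c(1, 1, 1), ]
  bonds <- cbind(g$bond_list, g$bond_features)
  H1 <- oracle_gin_layer(H0, bonds, p$enc1_W1, p$enc1_b1, p$enc1_W2,
                         p$enc1_b2, p$enc1_bond_type_emb,
                         p$enc1_bond_dir_emb)
  H1[2, ] <- p$dec_mask[1, ]
  H2 <- oracle_gin_layer(H1, bonds, p$dec_W1, p$dec_b1, p$dec_W2,
                         p$dec_b2, p$dec_bond_type_emb, p$dec_bond_dir_emb)
  Z <- H2 %*% p$dec_out_W + matrix(p$dec_out_b, 3, 3, byrow = TRUE)
  expect_equal(out$reconstruction, Z[2, , drop = FALSE], tolerance = 1e-12)
  expect_equal(out$target,
               (p$atom_type_emb[6, ] + p$chirality_emb[1, ]) |>
                 matrix(1, 3), tolerance = 1e-12)
})

test_that("an isolated masked fragment is reconstructed from the token alone", {
  m <- tiny_model(D = 4, layers = 2, norm = "none")
  # phenetole cleaves at both ether bonds: the oxygen is its own fragment
  g <- parse_smiles("c1ccccc1OCC")
  asg <- brics_partition(g)
  oxy <- which(asg$fragment_of_atom == asg$fragment_of_atom[7])
  expect_length(oxy, 1L)
  mask <- structure(list(masked_atoms = 7L, mask_ratio = 0.1,
                         mask_token = mol_vocab()$mask_atom_type),
                    class = "mask_spec")
  out <- reconstruct(m, g, mask, asg)
  # a masked lone atom in a different molecule reconstructs identically:
  # only the mask token and the self-loop feed the computation
  g2 <- parse_smiles("O")
  asg2 <- brics_partition(g2)
  mask2 <- structure(list(masked_atoms = 1L, mask_ratio = 0.5,
                          mask_token = mol_vocab()$mask_atom_type),
                     class = "mask_spec")
  out2 <- reconstruct(m, g2, mask2, asg2)
  expect_equal(out$reconstruction, out2$reconstruction, tolerance = 1e-12)
})

test_that("information cannot cross removed inter-fragment bonds", {
  m <- tiny_model(D = 4, layers = 2)
  g <- parse_smiles("c1ccccc1OC")
  asg <- brics_partition(g)
  ring <- which(asg$fragment_of_atom == asg$fragment_of_atom[1])
  expect_length(ring, 6L)
  mask <- structure(list(masked_atoms = 2L, mask_ratio = 0.1,
                         mask_token = mol_vocab()$mask_atom_type),
                    class = "mask_spec")
  base <- reconstruct(m, g, mask, asg)
  # perturb atom features in the *other* fragments (O -> S, C -> N)
  g2 <- g
  g2$atom_features[7, "atom_type"] <- 16L
  g2$atom_features[8, "atom_type"] <- 7L
  pert <- reconstruct(m, g2, mask, asg)
  expect_identical(base$reconstruction, pert$reconstruction)
  # sanity: perturbing inside the masked atom's own fragment does change it
  g3 <- g
  g3$atom_features[1, "atom_type"] <- 7L
  pert2 <- reconstruct(m, g3, mask, asg)
  expect_false(isTRUE(all.equal(base$reconstruction, pert2$reconstruction)))
})
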