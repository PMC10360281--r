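as_checkpoint <- function(model) {
  structure(model, class = c("fragssl_checkpoint", "fragssl_model"))
}

test_that("Murcko scaffolds group decorated molecules together", {
  benzene <- murcko_scaffold(parse_smiles("c1ccccc1"))
  expect_identical(murcko_scaffold(parse_smiles("Cc1ccccc1")), benzene)
  expect_identical(murcko_scaffold(parse_smiles("CCOc1ccccc1")), benzene)
  expect_false(identical(murcko_scaffold(parse_smiles("C1CCCCC1")),
                         benzene))
  # ring-free molecules share the empty scaffold
  expect_identical(murcko_scaffold(parse_smiles("CCO")), "")
  expect_identical(murcko_scaffold(parse_smiles("CC(C)CC")), "")
  # linkers between rings are part of the scaffold
  biphenyl <- murcko_scaffold(parse_smiles("c1ccc(-c2ccccc2)cc1"))
  bridged <- murcko_scaffold(parse_smiles("c1ccc(Cc2ccccc2)cc1"))
  expect_false(identical(biphenyl, bridged))
  # scaffold key is independent of atom ordering in the input
  expect_identical(murcko_scaffold(parse_smiles("CCc1ccncc1")),
                   murcko_scaffold(parse_smiles("c1cc(CC)ccn1")))
})

test_that("greedy scaffold split follows the quota rule", {
  # ten distinct scaffolds -> 8/1/1
  rings <- c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "c1ccccc1",
             "c1ccncc1", "C1CCOC1", "C1CCOCC1", "C1CCNC1", "C1CCNCC1")
  graphs <- lapply(rings, parse_smiles)
  sp <- scaffold_split(graphs)
  expect_length(sp$train, 8L)
  expect_length(sp$valid, 1L)
  expect_length(sp$test, 1L)
  expect_setequal(c(sp$train, sp$valid, sp$test), 1:10)

  # a single shared scaffold is atomic: everything lands in train
  dec <- lapply(paste0(c("C", "CC", "CCC", "CCCC"), "c1ccccc1"),
                parse_smiles)
  expect_warning(sp1 <- scaffold_split(dec), "empty")
  expect_length(sp1$train, 4L)
  expect_length(sp1$valid, 0L)

  # group sizes 6/3/1: train takes {6,3} (>= 80% only after both),
  # valid takes {1}, test stays empty
  sm <- c(paste0(c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C"),
                 "c1ccccc1"),
          paste0(c("C", "CC", "CCC"), "C1CCCCC1"),
          "c1ccncc1")
  expect_warning(sp2 <- scaffold_split(lapply(sm, parse_smiles)), "empty")
  expect_setequal(sp2$train, 1:9)
  expect_equal(sp2$valid, 10L)
  expect_length(sp2$test, 0L)
})

test_that("no scaffold spans two subsets on a generated library", {
  graphs <- lapply(generate_library(200, seed = 13)$smiles, parse_smiles)
  sp <- scaffold_split(graphs)
  keys <- vapply(graphs, murcko_scaffold, character(1))
  expect_length(intersect(keys[sp$train], keys[sp$valid]), 0L)
  expect_length(intersect(keys[sp$train], keys[sp$test]), 0L)
  expect_length(intersect(keys[sp$valid], keys[sp$test]), 0L)
  expect_setequal(c(sp$train, sp$valid, sp$test), seq_along(graphs))
})

test_that("ROC-AUC follows the rank definition", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  # worked example: 3 of 4 discordant-free pairs
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  # ties contribute one half
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5)), 0.5)
  # invariance under strictly monotone transforms
  set.seed(31)
  y <- rbinom(40, 1, 0.4)
  s <- rnorm(40)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 3 * s - 7), a)
  err <- tryCatch(roc_auc(c(1, 1), c(0.2, 0.3)),
                  fragssl_metric_error = function(e) e)
  expect_s3_class(err, "fragssl_metric_error")
})

test_that("RMSE follows its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5 + 2), 2)       # constant offset
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("a linear signal in frozen embeddings is recovered by the head", {
  smiles <- generate_library(40, seed = 17)$smiles
  graphs <- lapply(smiles, parse_smiles)
  ck <- as_checkpoint(tiny_model(D = 8, layers = 2, seed = 2))
  emb <- encode(ck, graphs)$molecule_embedding
  set.seed(18)
  w <- rnorm(8)
  y <- drop(scale(emb %*% w))
  ds <- fragssl:::new_labeled_dataset(graphs, matrix(y, ncol = 1),
                                      "regression")
  sp <- scaffold_split(ds)
  fit <- finetune(ck, ds, sp, seed = 0, epochs = 2000, learning_rate = 0.05,
                  batch_size = 4, freeze_encoder = TRUE, dropout = 0)
  expect_equal(fit$metric_name, "rmse")
  expect_lt(fit$test_metric, 0.05)
})

test_that("perfectly separable embeddings give test AUC 1", {
  smiles <- generate_library(40, seed = 23)$smiles
  graphs <- lapply(smiles, parse_smiles)
  ck <- as_checkpoint(tiny_model(D = 8, layers = 2, seed = 4))
  emb <- encode(ck, graphs)$molecule_embedding
  set.seed(24)
  w <- rnorm(8)
  y <- as.integer(drop(emb %*% w) > stats::median(emb %*% w))
  ds <- fragssl:::new_labeled_dataset(graphs, matrix(y, ncol = 1),
                                      "classification")
  sp <- scaffold_split(ds)
  pr <- linear_probe(ck, ds, sp, lambda = 1e-4)
  expect_equal(pr$test_metric, 1)
})

test_that("multi-seed fine-tuning reports mean and spread", {
  smiles <- generate_library(24, seed = 27, family_labels = TRUE)
  graphs <- lapply(smiles$smiles, parse_smiles)
  ds <- fragssl:::new_labeled_dataset(graphs,
                                      matrix(smiles$family, ncol = 1),
                                      "classification")
  # stratified manual split so every subset carries both classes
  pos <- which(smiles$family == 1L)
  neg <- which(smiles$family == 0L)
  sp <- structure(list(train = c(pos[-(1:4)], neg[-(1:4)]),
                       valid = c(pos[1:2], neg[1:2]),
                       test = c(pos[3:4], neg[3:4])),
                  class = "scaffold_split")
  ck <- as_checkpoint(tiny_model(D = 8, layers = 1, seed = 6))
  res <- finetune_runs(ck, ds, sp, seeds = c(0L, 1L, 2L), epochs = 3,
                       freeze_encoder = TRUE)
  expect_s3_class(res, "metric_result")
  expect_length(res$values, 3L)
  expect_equal(res$mean, mean(res$values))
  expect_equal(res$sd, stats::sd(res$values))
  expect_true(all(res$values >= 0 & res$values <= 1))
})

test_that("fine-tuning requires a non-empty validation split", {
  graphs <- lapply(c("CCO", "CCC"), parse_smiles)
  ds <- fragssl:::new_labeled_dataset(graphs, matrix(c(0, 1), ncol = 1),
                                      "classification")
  sp <- structure(list(train = 1:2, valid = integer(0), test = integer(0)),
                  class = "scaffold_split")
  ck <- as_checkpoint(tiny_model())
  expect_error(finetune(ck, ds, sp), "validation")
})
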