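# Deterministic toy molecule libraries.
#
# Small combinatorial products of building blocks joined through
# BRICS-cleavable linkages (amide, ester, ether), so the fragmenter
# always has work to do and every module is testable without downloads.
# Two structural families are available: aromatic cores (benzene /
# pyridine variants) and aliphatic cores (rings and branched chains),
# sharing the same linker and substituent pools.  Not intended to mimic
# drug-likeness or realistic property distributions.

.fix_aromatic_cores <- c(
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "Clc1ccccc1", "c1ccc(C)cc1",
  "Fc1ccccc1", "c1ccc2ccccc2c1", "Cc1ccncc1"
)
.fix_aliphatic_cores <- c(
  "C1CCCCC1", "C1CCCC1", "CC(C)C", "CCCC", "CC(C)CC",
  "C1CCCCC1C", "CCC(C)C", "CCCCC"
)
.fix_links <- c("C(=O)N", "C(=O)O", "O")
.fix_tails <- c("CC", "CCC", "CCCC", "CC(C)C", "C1CCCCC1", "CCOC",
                "CCN(C)C", "CCC(C)C", "CCO", "C")

#' Generate a deterministic toy molecule library
#'
#' Emits unique, parseable SMILES assembled as core-linker-tail products
#' (about 90% of molecules; the rest are bare cores, which typically stay
#' single BRICS fragments).  With `family_labels = TRUE` each molecule
#' carries `family` (1 = aromatic core, 0 = aliphatic core; balanced) and
#' a continuous `y` correlated with the molecule's BRICS fragment count
#' (fragment count plus Gaussian noise, sd 0.5).
#'
#' @param n_molecules Number of molecules (limited by the size of the
#'   combinatorial space, several hundred).
#' @param seed Integer seed; output is byte-identical across calls.
#' @param family_labels Attach the binary family label and continuous
#'   response.
#' @param path Optional CSV path to write the table to.
#' @return A data.frame with column `smiles` (plus `family`, `y`).
#' @export
generate_library <- function(n_molecules, seed = 7L, family_labels = FALSE,
                             path = NULL) {
  stopifnot(n_molecules >= 1L)
  combos <- function(cores) {
    grid <- expand.grid(core = cores, link = .fix_links, tail = .fix_tails,
                        stringsAsFactors = FALSE)
    paste0(grid$core, grid$link, grid$tail)
  }
  arom <- unique(c(combos(.fix_aromatic_cores), .fix_aromatic_cores))
  alip <- unique(c(combos(.fix_aliphatic_cores), .fix_aliphatic_cores))
  arom_is_single <- c(rep(FALSE, length(arom) - length(.fix_aromatic_cores)),
                      rep(TRUE, length(.fix_aromatic_cores)))
  alip_is_single <- c(rep(FALSE, length(alip) - length(.fix_aliphatic_cores)),
                      rep(TRUE, length(.fix_aliphatic_cores)))

  n_a <- ceiling(n_molecules / 2)
  n_b <- n_molecules - n_a
  if (n_a > length(arom) || n_b > length(alip)) {
    stop("requested library exceeds the combinatorial space (",
         length(arom) + length(alip), " molecules)")
  }
  with_seed(seed, {
    # keep bare cores to roughly 10% of each family's draw
    draw <- function(pool, singles, k) {
      k_single <- min(round(0.1 * k), sum(singles))
      keep <- c(sample(which(!singles), k - k_single),
                if (k_single > 0) sample(which(singles), k_single))
      pool[sort(keep)]
    }
    sm_a <- draw(arom, arom_is_single, n_a)
    sm_b <- draw(alip, alip_is_single, n_b)
    df <- data.frame(smiles = c(sm_a, sm_b),
                     family = rep(c(1L, 0L), c(n_a, n_b)),
                     stringsAsFactors = FALSE)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    if (family_labels) {
      nfrag <- vapply(df$smiles, function(s) {
        brics_partition(parse_smiles(s))$num_fragments
      }, integer(1), USE.NAMES = FALSE)
      df$y <- nfrag + stats::rnorm(nrow(df), sd = 0.5)
    } else {
      df$family <- NULL
    }
    if (!is.null(path)) {
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    df
  })
}
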