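# Minimal reverse-mode differentiation tape.
#
# Every value on the tape is a base-R numeric matrix (a scalar is 1x1).
# Operations append a node holding the forward value, the parent node ids,
# and a closure mapping the incoming gradient to per-parent gradients.
# ag_backward() walks the tape once in reverse, accumulating gradients.
# This is all the machinery the encoder and the two pretraining losses
# need; no graph optimization, no broadcasting beyond row/column vectors.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$backfns <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tp, value, parents = integer(0), backfn = NULL) {
  # force all arguments before claiming an id: evaluating them may push
  # further nodes onto the tape, and the backward pass requires every
  # parent id to be smaller than its child's
  force(value); force(parents); force(backfn)
  i <- tp$n + 1L
  stopifnot(all(parents < i))
  if (i > length(tp$vals)) {       # grow geometrically
    extra <- vector("list", length(tp$vals))
    tp$vals <- c(tp$vals, extra)
    tp$parents <- c(tp$parents, extra)
    tp$backfns <- c(tp$backfns, extra)
  }
  tp$n <- i
  tp$vals[[i]] <- value
  tp$parents[[i]] <- parents
  tp$backfns[[i]] <- backfn
  i
}

ag_const <- function(tp, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  ag_node(tp, value)
}

ag_val <- function(tp, id) {
  # force `id` before touching the list: nested op calls push nodes as a
  # side effect of evaluating their arguments
  force(id)
  tp$vals[[id]]
}

# Backward pass from a scalar node; returns gradients indexed by node id
# (NULL for nodes the output does not depend on).
ag_backward <- function(tp, id) {
  stopifnot(length(ag_val(tp, id)) == 1L)
  grads <- vector("list", tp$n)
  grads[[id]] <- matrix(1, 1L, 1L)
  for (i in seq(id, 1L)) {
    g <- grads[[i]]
    bf <- tp$backfns[[i]]
    if (is.null(g) || is.null(bf)) next
    pg <- bf(g)
    ps <- tp$parents[[i]]
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# --- broadcasting helpers (full / row-vector / column-vector) ------------

ag_expand <- function(M, n, m) {
  if (nrow(M) == n && ncol(M) == m) return(M)
  if (nrow(M) == 1L && ncol(M) == m) return(matrix(M, n, m, byrow = TRUE))
  if (ncol(M) == 1L && nrow(M) == n) return(matrix(M, n, m))
  if (length(M) == 1L) return(matrix(M[1L], n, m))
  stop("ag: shapes not broadcastable: ", nrow(M), "x", ncol(M),
       " to ", n, "x", m)
}

ag_reduce <- function(G, n, m) {
  if (nrow(G) == n && ncol(G) == m) return(G)
  if (n == 1L && m == ncol(G)) return(matrix(colSums(G), 1L, m))
  if (m == 1L && n == nrow(G)) return(matrix(rowSums(G), n, 1L))
  if (n == 1L && m == 1L) return(matrix(sum(G), 1L, 1L))
  stop("ag: cannot reduce gradient")
}

ag_outdim <- function(A, B) {
  c(max(nrow(A), nrow(B)), max(ncol(A), ncol(B)))
}

# --- elementwise arithmetic ----------------------------------------------

ag_add <- function(tp, a, b) {
  A <- ag_val(tp, a); B <- ag_val(tp, b)
  d <- ag_outdim(A, B)
  ag_node(tp, ag_expand(A, d[1], d[2]) + ag_expand(B, d[1], d[2]), c(a, b),
          function(G) list(ag_reduce(G, nrow(A), ncol(A)),
                           ag_reduce(G, nrow(B), ncol(B))))
}

ag_sub <- function(tp, a, b) {
  A <- ag_val(tp, a); B <- ag_val(tp, b)
  d <- ag_outdim(A, B)
  ag_node(tp, ag_expand(A, d[1], d[2]) - ag_expand(B, d[1], d[2]), c(a, b),
          function(G) list(ag_reduce(G, nrow(A), ncol(A)),
                           ag_reduce(-G, nrow(B), ncol(B))))
}

ag_mul <- function(tp, a, b) {
  A <- ag_val(tp, a); B <- ag_val(tp, b)
  d <- ag_outdim(A, B)
  Ae <- ag_expand(A, d[1], d[2]); Be <- ag_expand(B, d[1], d[2])
  ag_node(tp, Ae * Be, c(a, b),
          function(G) list(ag_reduce(G * Be, nrow(A), ncol(A)),
                           ag_reduce(G * Ae, nrow(B), ncol(B))))
}

ag_div <- function(tp, a, b) {
  A <- ag_val(tp, a); B <- ag_val(tp, b)
  d <- ag_outdim(A, B)
  Ae <- ag_expand(A, d[1], d[2]); Be <- ag_expand(B, d[1], d[2])
  ag_node(tp, Ae / Be, c(a, b),
          function(G) list(ag_reduce(G / Be, nrow(A), ncol(A)),
                           ag_reduce(-G * Ae / (Be * Be), nrow(B), ncol(B))))
}

# multiply / add with a non-differentiated constant
ag_cmul <- function(tp, a, K) {
  A <- ag_val(tp, a)
  if (!is.matrix(K)) K <- matrix(K, 1L)
  Ke <- ag_expand(K, nrow(A), ncol(A))
  ag_node(tp, A * Ke, a, function(G) list(G * Ke))
}

ag_cadd <- function(tp, a, K) {
  A <- ag_val(tp, a)
  if (!is.matrix(K)) K <- matrix(K, 1L)
  ag_node(tp, A + ag_expand(K, nrow(A), ncol(A)), a, function(G) list(G))
}

# --- elementwise nonlinearities ------------------------------------------

ag_exp <- function(tp, a) {
  V <- exp(ag_val(tp, a))
  ag_node(tp, V, a, function(G) list(G * V))
}

ag_log <- function(tp, a) {
  A <- ag_val(tp, a)
  ag_node(tp, log(A), a, function(G) list(G / A))
}

ag_sqrt <- function(tp, a) {
  V <- sqrt(ag_val(tp, a))
  ag_node(tp, V, a, function(G) list(G * 0.5 / V))
}

ag_pow <- function(tp, a, p) {
  A <- ag_val(tp, a)
  ag_node(tp, A^p, a, function(G) list(G * p * A^(p - 1)))
}

ag_relu <- function(tp, a) {
  A <- ag_val(tp, a)
  ag_node(tp, pmax(A, 0), a, function(G) list(G * (A > 0)))
}

ag_abs <- function(tp, a) {
  A <- ag_val(tp, a)
  ag_node(tp, abs(A), a, function(G) list(G * sign(A)))
}

# --- linear algebra -------------------------------------------------------

ag_matmul <- function(tp, a, b) {
  A <- ag_val(tp, a); B <- ag_val(tp, b)
  ag_node(tp, A %*% B, c(a, b),
          function(G) list(G %*% t(B), t(A) %*% G))
}

ag_t <- function(tp, a) {
  ag_node(tp, t(ag_val(tp, a)), a, function(G) list(t(G)))
}

ag_sum <- function(tp, a) {
  A <- ag_val(tp, a)
  ag_node(tp, matrix(sum(A), 1L, 1L), a,
          function(G) list(matrix(G[1L], nrow(A), ncol(A))))
}

ag_rowsums <- function(tp, a) {
  A <- ag_val(tp, a)
  ag_node(tp, matrix(rowSums(A), ncol = 1L), a,
          function(G) list(matrix(G, nrow(A), ncol(A))))
}

# --- gather / scatter (message passing, pooling, embeddings) --------------

ag_lookup <- function(tp, a, idx) {
  A <- ag_val(tp, a)
  idx <- as.integer(idx)
  ag_node(tp, A[idx, , drop = FALSE], a, function(G) {
    rs <- rowsum(G, group = idx)
    dA <- matrix(0, nrow(A), ncol(A))
    dA[as.integer(rownames(rs)), ] <- rs
    list(dA)
  })
}

ag_scatter_sum <- function(tp, a, idx, n_out) {
  A <- ag_val(tp, a)
  idx <- as.integer(idx)
  rs <- rowsum(A, group = idx)
  V <- matrix(0, n_out, ncol(A))
  V[as.integer(rownames(rs)), ] <- rs
  ag_node(tp, V, a, function(G) list(G[idx, , drop = FALSE]))
}

# --- regularization / normalization --------------------------------------

ag_dropout <- function(tp, a, p, training) {
  if (!training || p <= 0) return(a)
  A <- ag_val(tp, a)
  mask <- matrix((stats::runif(length(A)) >= p) / (1 - p), nrow(A), ncol(A))
  ag_node(tp, A * mask, a, function(G) list(G * mask))
}

# Batch normalization over rows (one feature per column).  `state` is an
# environment carrying running mean/var, updated in training mode only.
# Biased variance is used both for normalization and the running estimate.
ag_batchnorm <- function(tp, a, gamma, beta, state, training,
                         eps = 1e-5, momentum = 0.1) {
  A <- ag_val(tp, a)
  Gv <- ag_val(tp, gamma); Bv <- ag_val(tp, beta)
  n <- nrow(A); m <- ncol(A)
  if (training) {
    mu <- colMeans(A)
    xc <- A - matrix(mu, n, m, byrow = TRUE)
    va <- colMeans(xc * xc)
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * matrix(istd, n, m, byrow = TRUE)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
    V <- xhat * matrix(Gv, n, m, byrow = TRUE) + matrix(Bv, n, m, byrow = TRUE)
    ag_node(tp, V, c(a, gamma, beta), function(G) {
      dgamma <- matrix(colSums(G * xhat), 1L, m)
      dbeta <- matrix(colSums(G), 1L, m)
      dxhat <- G * matrix(Gv, n, m, byrow = TRUE)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dA <- (dxhat - matrix(s1 / n, n, m, byrow = TRUE) -
               xhat * matrix(s2 / n, n, m, byrow = TRUE)) *
        matrix(istd, n, m, byrow = TRUE)
      list(dA, dgamma, dbeta)
    })
  } else {
    istd <- 1 / sqrt(state$var + eps)
    xhat <- (A - matrix(state$mean, n, m, byrow = TRUE)) *
      matrix(istd, n, m, byrow = TRUE)
    V <- xhat * matrix(Gv, n, m, byrow = TRUE) + matrix(Bv, n, m, byrow = TRUE)
    ag_node(tp, V, c(a, gamma, beta), function(G) {
      list(G * matrix(Gv * istd, n, m, byrow = TRUE),
           matrix(colSums(G * xhat), 1L, m),
           matrix(colSums(G), 1L, m))
    })
  }
}

# --- composite helpers ----------------------------------------------------

# Softmax of a column of logits within groups (e.g. fragments of one
# molecule).  The per-group max is subtracted as a constant for stability;
# softmax is shift-invariant so the gradient is unaffected.
ag_group_softmax <- function(tp, logits, group, n_groups) {
  lv <- ag_val(tp, logits)
  mx <- tapply(lv[, 1L], factor(group, levels = seq_len(n_groups)), max)
  e <- ag_exp(tp, ag_cadd(tp, logits, matrix(-mx[group], ncol = 1L)))
  denom <- ag_scatter_sum(tp, e, group, n_groups)
  ag_div(tp, e, ag_lookup(tp, denom, group))
}

# L2-normalize rows; zero rows are a caller error.
ag_rownorm <- function(tp, a, eps = 0) {
  sq <- ag_rowsums(tp, ag_pow(tp, a, 2))
  nrm <- ag_sqrt(tp, if (eps > 0) ag_cadd(tp, sq, eps) else sq)
  ag_div(tp, a, nrm)
}
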