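# Minimal reverse-mode automatic differentiation on dense arrays.
#
# The pair-denoiser network is small (L^2 x C matrices with L ~ 50, C = 32),
# so a tape of R-level array operations with hand-written backward rules is
# fast enough for both training and sampling. Every op is checked against
# finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Start recording operations for backpropagation
#' @return The tape environment, invisibly.
#' @keywords internal
ad_begin_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 4096L)
  tape$n <- 0L
  .ad$tape <- tape
  invisible(tape)
}

#' Stop recording (frees the tape)
#' @keywords internal
ad_end_tape <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

.ad_record <- function(node) {
  tape <- .ad$tape
  if (is.null(tape)) return(invisible(node))
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  invisible(node)
}

.ad_node <- function(val, parents = list(), bw = NULL, record = TRUE) {
  if (is.null(.ad$tape) && !is.null(bw)) {
    # no tape active: value-only wrapper (no backward bookkeeping)
    return(structure(list(val = val), class = "ad_node"))
  }
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$bw <- bw
  e$grad <- NULL
  class(e) <- "ad_node"
  if (record && length(parents)) .ad_record(e)
  e
}

#' Wrap a constant (no gradient tracked)
#' @keywords internal
ad_const <- function(x) .ad_node(x, record = FALSE)

#' Wrap a parameter (gradient accumulated on backward)
#' @keywords internal
ad_param <- function(x) .ad_node(x, record = FALSE)

is_ad_node <- function(x) inherits(x, "ad_node")
.as_node <- function(x) if (is_ad_node(x)) x else ad_const(x)

.acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @keywords internal
ad_backward <- function(loss) {
  tape <- .ad$tape
  if (is.null(tape)) stop("no active tape")
  loss$grad <- 1
  for (k in rev(seq_len(tape$n))) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || is.null(node$bw)) next
    node$bw(node$grad, node)
  }
  invisible(NULL)
}

# ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ad_node(a$val + b$val, list(a, b), function(g, node) {
    .acc(node$parents[[1]], g); .acc(node$parents[[2]], g)
  })
}

ad_sub <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ad_node(a$val - b$val, list(a, b), function(g, node) {
    .acc(node$parents[[1]], g); .acc(node$parents[[2]], -g)
  })
}

ad_mul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ad_node(a$val * b$val, list(a, b), function(g, node) {
    .acc(node$parents[[1]], g * node$parents[[2]]$val)
    .acc(node$parents[[2]], g * node$parents[[1]]$val)
  })
}

ad_scale <- function(a, k) {
  a <- .as_node(a)
  .ad_node(a$val * k, list(a), function(g, node) .acc(node$parents[[1]], g * k))
}

ad_sigmoid <- function(a) {
  a <- .as_node(a)
  s <- if (is.matrix(a$val)) fd_sigmoid(a$val) else 1 / (1 + exp(-a$val))
  .ad_node(s, list(a), function(g, node) {
    s <- node$val
    .acc(node$parents[[1]], g * s * (1 - s))
  })
}

ad_relu <- function(a) {
  a <- .as_node(a)
  v <- if (is.matrix(a$val)) fd_relu(a$val) else pmax(a$val, 0)
  .ad_node(v, list(a), function(g, node) {
    .acc(node$parents[[1]], g * (node$parents[[1]]$val > 0))
  })
}

ad_pmin_const <- function(a, k) {
  a <- .as_node(a)
  .ad_node(pmin(a$val, k), list(a), function(g, node) {
    .acc(node$parents[[1]], g * (node$parents[[1]]$val < k))
  })
}

# ---- linear algebra -------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ad_node(a$val %*% b$val, list(a, b), function(g, node) {
    .acc(node$parents[[1]], g %*% t(node$parents[[2]]$val))
    .acc(node$parents[[2]], crossprod(node$parents[[1]]$val, g))
  })
}

# fast row-broadcasts (C++ kernels)
.bcast_add <- function(X, v) fd_bcast_add(X, v)
.bcast_mul <- function(X, v) fd_bcast_mul(X, v)

# X (N x C) + bias (length C), broadcast over rows
ad_addbias <- function(X, b) {
  X <- .as_node(X); b <- .as_node(b)
  .ad_node(.bcast_add(X$val, as.vector(b$val)), list(X, b),
           function(g, node) {
             .acc(node$parents[[1]], g)
             .acc(node$parents[[2]], colSums(g))
           })
}

ad_linear <- function(X, W, b = NULL) {
  if (is.null(b)) return(ad_matmul(X, W))
  X <- .as_node(X); W <- .as_node(W); b <- .as_node(b)
  .ad_node(.bcast_add(X$val %*% W$val, as.vector(b$val)), list(X, W, b),
           function(g, node) {
             .acc(node$parents[[1]], g %*% t(node$parents[[2]]$val))
             .acc(node$parents[[2]], crossprod(node$parents[[1]]$val, g))
             .acc(node$parents[[3]], colSums(g))
           })
}

# X (N x 3) minus a 1 x 3 node, broadcast over rows
ad_sub_rowvec <- function(X, v) {
  X <- .as_node(X); v <- .as_node(v)
  .ad_node(.bcast_add(X$val, -as.vector(v$val)), list(X, v),
           function(g, node) {
             .acc(node$parents[[1]], g)
             .acc(node$parents[[2]], matrix(-colSums(g), 1))
           })
}

# Row-wise layer normalization with per-channel affine parameters.
ad_layernorm <- function(X, gamma, beta, eps = 1e-5) {
  X <- .as_node(X); gamma <- .as_node(gamma); beta <- .as_node(beta)
  fw <- fd_layernorm_fwd(X$val, matrix(as.vector(gamma$val), 1),
                         matrix(as.vector(beta$val), 1), eps)
  node <- .ad_node(fw$val, list(X, gamma, beta), function(g, node) {
    bw <- fd_layernorm_bwd(g, node$cache$xhat, node$cache$inv,
                           matrix(as.vector(node$parents[[2]]$val), 1))
    .acc(node$parents[[1]], bw$dX)
    .acc(node$parents[[2]], as.vector(bw$dgamma))
    .acc(node$parents[[3]], as.vector(bw$dbeta))
  })
  node$cache <- list(xhat = fw$xhat, inv = fw$inv)
  node
}

ad_softmax_rows <- function(X) {
  X <- .as_node(X)
  m <- X$val[cbind(seq_len(nrow(X$val)), max.col(X$val, "first"))]
  e <- exp(X$val - m)
  s <- e / rowSums(e)
  .ad_node(s, list(X), function(g, node) {
    s <- node$val
    .acc(node$parents[[1]], s * (g - rowSums(g * s)))
  })
}

ad_mean_all <- function(a) {
  a <- .as_node(a)
  n <- length(a$val)
  .ad_node(mean(a$val), list(a), function(g, node) {
    .acc(node$parents[[1]], array(g / n, dim = dim(node$parents[[1]]$val) %||% n))
  })
}

ad_sum_all <- function(a) {
  a <- .as_node(a)
  .ad_node(sum(a$val), list(a), function(g, node) {
    p <- node$parents[[1]]
    .acc(p, array(g, dim = dim(p$val) %||% length(p$val)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise L2 norms of an N x 3 matrix -> length-N vector (eps-regularized).
ad_row_l2 <- function(X, eps = 1e-12) {
  X <- .as_node(X)
  n <- sqrt(rowSums(X$val^2) + eps)
  .ad_node(n, list(X), function(g, node) {
    .acc(node$parents[[1]],
         (as.vector(g) / node$val) * node$parents[[1]]$val)
  })
}

ad_l2normalize_vec <- function(v, eps = 1e-12) {
  v <- .as_node(v)
  x <- as.vector(v$val)
  n <- sqrt(sum(x^2) + eps)
  .ad_node(matrix(x / n, 1), list(v), function(g, node) {
    x <- as.vector(node$parents[[1]]$val)
    n <- sqrt(sum(x^2) + eps)
    g <- as.vector(g)
    .acc(node$parents[[1]], matrix(g / n - x * sum(g * x) / n^3, 1))
  })
}

ad_slice_rows <- function(X, idx) {
  X <- .as_node(X)
  .ad_node(X$val[idx, , drop = FALSE], list(X), function(g, node) {
    G <- array(0, dim(node$parents[[1]]$val))
    # accumulate (idx may repeat)
    for (k in seq_along(idx)) G[idx[k], ] <- G[idx[k], ] + g[k, ]
    .acc(node$parents[[1]], G)
  })
}

ad_slice_cols <- function(X, idx) {
  X <- .as_node(X)
  .ad_node(X$val[, idx, drop = FALSE], list(X), function(g, node) {
    G <- array(0, dim(node$parents[[1]]$val))
    G[, idx] <- g
    .acc(node$parents[[1]], G)
  })
}

# Mean-pool rows of X by groups (list of row-index vectors) -> G x C.
ad_pool_rows <- function(X, groups) {
  X <- .as_node(X)
  val <- do.call(rbind, lapply(groups, function(ix) {
    colMeans(X$val[ix, , drop = FALSE])
  }))
  .ad_node(val, list(X), function(g, node) {
    G <- array(0, dim(node$parents[[1]]$val))
    for (k in seq_along(groups)) {
      ix <- groups[[k]]
      G[ix, ] <- G[ix, ] + matrix(g[k, ] / length(ix), length(ix),
                                  ncol(g), byrow = TRUE)
    }
    .acc(node$parents[[1]], G)
  })
}

# ---- pair-representation (L x L flattened to L^2 x C) ops -----------------

# Row index of pair (i, j) in the column-major L^2 flattening.
pair_index <- function(i, j, L) i + (j - 1L) * L

# Transpose the pair dimension: out[(i,j), ] = X[(j,i), ].
ad_transpose_pair <- function(X, L) {
  X <- .as_node(X)
  perm <- as.vector(t(matrix(seq_len(L * L), L, L)))
  .ad_node(X$val[perm, , drop = FALSE], list(X), function(g, node) {
    .acc(node$parents[[1]], g[perm, , drop = FALSE])
  })
}

# Triangle multiplicative update core.
# A, B: L^2 x C. direction "outgoing": O_c = A_c %*% t(B_c);
# "incoming": O_c = t(A_c) %*% B_c  (A_c = matrix(A[, c], L, L)).
ad_tri_mult <- function(A, B, L, direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  A <- .as_node(A); B <- .as_node(B)
  outgoing <- direction == "outgoing"
  .ad_node(fd_tri_mult_fwd(A$val, B$val, L, outgoing), list(A, B),
           function(g, node) {
             bw <- fd_tri_mult_bwd(g, node$parents[[1]]$val,
                                   node$parents[[2]]$val, L, outgoing)
             .acc(node$parents[[1]], bw$dA)
             .acc(node$parents[[2]], bw$dB)
           })
}

# Triangle attention (starting-node flavor).
# Q, K, V: L^2 x (h * dh); Bias: L^2 x h (pair bias b[j, k] per head).
# out[(i,j), head] = sum_k softmax_k(q_ij . k_ik / sqrt(dh) + b_jk) v_ik.
# Ending-node attention is obtained by transposing the pair dimension of the
# inputs and the output (see the denoiser module).
# QKVB: packed projections, L^2 x (3*h*dh + h), columns [Q | K | V | Bias].
ad_tri_attention <- function(QKVB, L, h) {
  QKVB <- .as_node(QKVB)
  stopifnot((ncol(QKVB$val) - h) %% (3L * h) == 0L)
  fw <- fd_tri_attn_fwd(QKVB$val, L, h)
  node <- .ad_node(fw$val, list(QKVB), function(g, node) {
    .acc(node$parents[[1]],
         fd_tri_attn_bwd(g, node$parents[[1]]$val, node$cache$alpha, L, h))
  })
  node$cache <- list(alpha = fw$alpha)
  node
}

# Fused gated linear unit: sigmoid(X W1 + b1) * (X W2 + b2).
ad_glu <- function(X, p1, p2) {
  X <- .as_node(X)
  fw <- fd_glu_fwd(X$val, p1$W$val, as.vector(p1$b$val),
                   p2$W$val, as.vector(p2$b$val))
  node <- .ad_node(fw$val, list(X, p1$W, p1$b, p2$W, p2$b),
                   function(g, node) {
                     bw <- fd_glu_bwd(g, node$parents[[1]]$val,
                                      node$parents[[2]]$val,
                                      node$parents[[4]]$val,
                                      node$cache$s, node$cache$l2)
                     .acc(node$parents[[1]], bw$dX)
                     .acc(node$parents[[2]], bw$dW1)
                     .acc(node$parents[[3]], as.vector(bw$db1))
                     .acc(node$parents[[4]], bw$dW2)
                     .acc(node$parents[[5]], as.vector(bw$db2))
                   })
  node$cache <- list(s = fw$s, l2 = fw$l2)
  node
}

# ---- small geometric ops for the pose readout -----------------------------

# Apply per-row constant matrices: out[i, ] = frames[[i]] %*% D[i, ].
# Works for any square dimension (3x3 rotation frames, 4x4 quaternion
# left-multiplication matrices, ...).
ad_frames_apply <- function(D, frames) {
  D <- .as_node(D)
  k <- nrow(frames[[1]])
  val <- t(vapply(seq_along(frames), function(i) {
    as.vector(frames[[i]] %*% D$val[i, ])
  }, numeric(k)))
  .ad_node(val, list(D), function(g, node) {
    G <- t(vapply(seq_along(frames), function(i) {
      as.vector(crossprod(frames[[i]], g[i, ]))
    }, numeric(k)))
    .acc(node$parents[[1]], G)
  })
}

# Cross product of two 1 x 3 nodes.
ad_cross_vec <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  cross <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                            x[3] * y[1] - x[1] * y[3],
                            x[1] * y[2] - x[2] * y[1])
  .ad_node(matrix(cross(as.vector(a$val), as.vector(b$val)), 1),
           list(a, b), function(g, node) {
             av <- as.vector(node$parents[[1]]$val)
             bv <- as.vector(node$parents[[2]]$val)
             gv <- as.vector(g)
             .acc(node$parents[[1]], matrix(cross(bv, gv), 1))
             .acc(node$parents[[2]], matrix(cross(gv, av), 1))
           })
}

# Stack 1 x C row nodes into an n x C node.
ad_concat_rows <- function(...) {
  nodes <- lapply(list(...), .as_node)
  val <- do.call(rbind, lapply(nodes, function(n) n$val))
  .ad_node(val, nodes, function(g, node) {
    for (k in seq_along(node$parents)) {
      .acc(node$parents[[k]], g[k, , drop = FALSE])
    }
  })
}

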