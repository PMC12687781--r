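# Finite-difference verification of every backward rule in the autodiff
# engine, including the C++ kernels.

ad <- asNamespace("flowdock")

gradcheck <- function(make_loss, vals, eps = 1e-6, n_probe = 6L) {
  ps <- lapply(vals, ad$ad_param)
  ad$ad_begin_tape()
  loss <- make_loss(ps)
  ad$ad_backward(loss)
  ad$ad_end_tape()
  maxrel <- 0
  for (k in seq_along(ps)) {
    g <- ps[[k]]$grad
    v <- vals[[k]]
    for (j in seq_len(min(length(v), n_probe))) {
      vp <- v; vp[j] <- vp[j] + eps
      vm <- v; vm[j] <- vm[j] - eps
      psp <- ps; psp[[k]] <- ad$ad_const(vp)
      psm <- ps; psm[[k]] <- ad$ad_const(vm)
      num <- (make_loss(psp)$val - make_loss(psm)$val) / (2 * eps)
      an <- as.vector(g)[j]
      maxrel <- max(maxrel, abs(num - an) / max(1e-6, abs(num), abs(an)))
    }
  }
  maxrel
}

test_that("elementwise, linear and normalization ops backpropagate correctly", {
  set.seed(5)
  L <- 5L; C <- 4L
  Z <- matrix(stats::rnorm(L * L * C), L * L, C)
  W <- matrix(stats::rnorm(C * C), C, C) / 2
  b <- stats::rnorm(C)
  G <- matrix(stats::rnorm(L * L * C), L * L, C)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_sigmoid(ad$ad_linear(p[[1]], p[[2]], p[[3]])),
                             ad$ad_const(G)))
  }, list(Z, W, b)), 1e-5)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_layernorm(p[[1]], p[[2]], p[[3]]),
                             ad$ad_const(G)))
  }, list(Z, stats::rnorm(C), stats::rnorm(C))), 1e-5)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_relu(ad$ad_tanh(p[[1]])), ad$ad_const(G)))
  }, list(Z + 0.1)), 1e-5)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_softmax_rows(p[[1]]), ad$ad_const(G)))
  }, list(Z)), 1e-5)
})

test_that("triangle ops backpropagate correctly", {
  set.seed(6)
  L <- 5L; C <- 4L; h <- 2L
  Z <- matrix(stats::rnorm(L * L * C), L * L, C)
  G <- matrix(stats::rnorm(L * L * C), L * L, C)
  Bi <- matrix(stats::rnorm(L * L * h), L * L, h)

  for (dir in c("outgoing", "incoming")) {
    expect_lt(gradcheck(function(p) {
      ad$ad_mean_all(ad$ad_mul(ad$ad_tri_mult(p[[1]], p[[2]], L, dir),
                               ad$ad_const(G)))
    }, list(Z, Z * 0.5 + 1)), 1e-5)
  }

  QKVB <- cbind(Z, Z * 0.3 - 0.2, Z * 0.7, Bi)
  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_tri_attention(p[[1]], L, h),
                             ad$ad_const(G)))
  }, list(QKVB), n_probe = 10L), 1e-5)

  W1 <- matrix(stats::rnorm(C * C) / 2, C, C)
  W2 <- matrix(stats::rnorm(C * C) / 2, C, C)
  expect_lt(gradcheck(function(p) {
    p1 <- list(W = p[[2]], b = p[[3]])
    p2 <- list(W = p[[4]], b = p[[5]])
    ad$ad_mean_all(ad$ad_mul(ad$ad_glu(p[[1]], p1, p2), ad$ad_const(G)))
  }, list(Z, W1, stats::rnorm(C), W2, stats::rnorm(C))), 1e-5)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_transpose_pair(p[[1]], L), ad$ad_const(G)))
  }, list(Z)), 1e-6)
})

test_that("geometric readout ops backpropagate correctly", {
  set.seed(7)
  D <- matrix(stats::rnorm(12), 4, 3)
  G4 <- matrix(stats::rnorm(12), 4, 3)
  Fl <- lapply(1:4, function(i) sample_uniform_rotation())
  G3 <- matrix(stats::rnorm(9), 3, 3)

  expect_lt(gradcheck(function(p) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_frames_apply(p[[1]], Fl), ad$ad_const(G4)))
  }, list(D)), 1e-5)

  expect_lt(gradcheck(function(p) {
    q <- ad$ad_l2normalize_vec(p[[1]])
    ad$ad_mean_all(ad$ad_mul(q, ad$ad_const(matrix(1:4 / 4, 1))))
  }, list(matrix(c(1, 0.3, -0.2, 0.5), 1))), 1e-5)

  expect_lt(gradcheck(function(p) {
    cr <- ad$ad_cross_vec(p[[1]], p[[2]])
    stacked <- ad$ad_concat_rows(p[[1]], p[[2]], cr)
    ad$ad_mean_all(ad$ad_mul(stacked, ad$ad_const(G3)))
  }, list(matrix(c(0.4, -1, 0.2), 1), matrix(c(1.1, 0.5, -0.3), 1))), 1e-5)

  expect_lt(gradcheck(function(p) {
    d <- ad$ad_pmin_const(ad$ad_row_l2(p[[1]]), 2.0)
    ad$ad_sum_all(d)
  }, list(D)), 1e-5)

  expect_lt(gradcheck(function(p) {
    x <- ad$ad_pool_rows(p[[1]], list(1:2, 3:4))
    y <- ad$ad_slice_rows(ad$ad_slice_cols(x, 1:2), c(1L, 2L, 2L))
    ad$ad_mean_all(ad$ad_mul(y, ad$ad_const(matrix(1:6 / 6, 3, 2))))
  }, list(D)), 1e-5)

  expect_lt(gradcheck(function(p) {
    x <- ad$ad_sub_rowvec(ad$ad_const(D), p[[1]])
    y <- ad$ad_addbias(ad$ad_const(D), p[[2]])
    ad$ad_mean_all(ad$ad_mul(ad$ad_concat_cols(x, y),
                             ad$ad_const(cbind(G4, G4))))
  }, list(matrix(stats::rnorm(3), 1), stats::rnorm(3))), 1e-5)
})

test_that("gradients accumulate across shared-parameter uses", {
  set.seed(8)
  W <- matrix(stats::rnorm(9), 3, 3)
  X <- matrix(stats::rnorm(12), 4, 3)
  expect_lt(gradcheck(function(p) {
    # W used twice: gradient must be the sum of both paths
    a <- ad$ad_matmul(ad$ad_const(X), p[[1]])
    b <- ad$ad_matmul(a, p[[1]])
    ad$ad_mean_all(ad$ad_mul(b, b))
  }, list(W)), 1e-5)
})

test_that("no-tape forward gives identical values to taped forward", {
  set.seed(9)
  L <- 4L; C <- 4L
  Z <- matrix(stats::rnorm(L * L * C), L * L, C)
  run <- function() {
    z <- ad$ad_tri_mult(ad$ad_const(Z), ad$ad_const(Z * 0.5), L, "outgoing")
    z <- ad$ad_sigmoid(z)
    ad$ad_mean_all(z)$val
  }
  plain <- run()
  ad$ad_begin_tape()
  taped <- run()
  ad$ad_end_tape()
  expect_identical(plain, taped)
})
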