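make_states <- function(seed = 3) {
  cx <- fixture_complex(seed)
  prior <- prior_spec(15, NULL)
  x1s <- decompose(cx, cx, t = 1)
  set.seed(seed + 100)
  x0 <- sample_prior(cx, prior)
  list(cx = cx, prior = prior, x0 = x0, x1 = x1s)
}

test_that("decompose/recompose is the identity in the anchored frame", {
  cx <- fixture_complex(3)
  st <- decompose(cx, cx)
  back <- recompose(st)
  for (ci in 1:2) {
    expect_lt(max(abs(back$chains[[ci]]$coords - cx$chains[[ci]]$coords)), 1e-6)
  }
  expect_equal(st$c, colMeans(chain_ca(ligand_chain(cx))))
  expect_lt(max(abs(st$R - diag(3))), 1e-9)

  # a rigidly moved ligand shows up purely in R and c; internal unchanged
  Q <- random_rotation(8); v <- c(5, -3, 2)
  moved <- move_ligand(cx, Q, v)
  stm <- decompose(moved, cx)
  expect_lt(max(abs(stm$R - Q)), 1e-8)
  expect_lt(max(abs(stm$internal[[2]]$coords - st$internal[[2]]$coords)), 1e-6)
  back2 <- recompose(stm)
  expect_lt(max(abs(chain_ca(ligand_chain(back2)) -
                      chain_ca(ligand_chain(moved)))), 1e-6)

  # whole-complex rigid motion is absorbed by the receptor anchoring
  glob <- transform_complex(cx, random_rotation(12), c(-4, 9, 1))
  stg <- decompose(glob, cx)
  expect_lt(max(abs(stg$c - st$c)), 1e-6)
  expect_lt(max(abs(stg$R - st$R)), 1e-8)

  bad <- cx; bad$ligand_index <- 1L; bad$receptor_index <- 2L
  expect_error(decompose(bad, cx), "mismatch")
})

test_that("prior sampling matches its specification", {
  cx <- fixture_complex(4)
  prior <- prior_spec(12, NULL)
  set.seed(1)
  draws <- t(replicate(3000, sample_prior(cx, prior)$c))
  ctr <- colMeans(chain_ca(receptor_chain(cx)))
  sds <- apply(draws, 2, stats::sd)
  expect_true(all(abs(sds - 12) / 12 < 0.05))
  expect_true(all(abs(colMeans(draws) - ctr) < 3 * 12 / sqrt(3000)))
  # holo-only probabilities return the holo conformer exactly
  rec <- make_toy_records(1, seed = 77)[[1]]
  prior2 <- prior_spec(15, rec$flex, c(holo = 1, apo_like = 0, predicted_like = 0))
  set.seed(2)
  x0 <- sample_prior(rec$x1, prior2)
  expect_identical(attr(x0, "flex_provenance"), c("holo", "holo"))
  expect_lt(max(abs(chain_ca(x0$internal[[1]]) -
                      chain_ca(receptor_chain(rec$x1)))), 1e-6)
  # seeded determinism
  set.seed(9); a <- sample_prior(rec$x1, prior2)
  set.seed(9); b <- sample_prior(rec$x1, prior2)
  expect_equal(a$c, b$c)
  expect_equal(a$R, b$R)
  # empty library falls back to holo with a warning
  prior3 <- prior_spec(15, list(R = list(), L = list()),
                       c(holo = 0.2, apo_like = 0.4, predicted_like = 0.4))
  expect_warning(sample_prior(rec$x1, prior3), "empty flex library")
})

test_that("interpolation endpoints and the OT velocity algebra hold", {
  s <- make_states(3)
  i0 <- interpolate_state(s$x0, s$x1, 0)
  i1 <- interpolate_state(s$x0, s$x1, 1)
  expect_lt(max(abs(i0$c - s$x0$c)), 1e-9)
  expect_lt(max(abs(i1$c - s$x1$c)), 1e-9)
  expect_lt(max(abs(i0$R - s$x0$R)), 1e-9)
  expect_lt(max(abs(i1$R - s$x1$R)), 1e-9)
  expect_lt(max(abs(i1$internal[[2]]$coords - s$x1$internal[[2]]$coords)), 1e-9)

  # translation midpoint is linear
  mid <- interpolate_state(s$x0, s$x1, 0.5)
  expect_equal(mid$c, (s$x0$c + s$x1$c) / 2)

  # velocity along the path is t-independent for translation (OT property)
  for (t in c(0.1, 0.45, 0.8)) {
    xt <- interpolate_state(s$x0, s$x1, t)
    v <- conditional_velocity(xt, s$x1, t)
    expect_lt(max(abs(v$c - (s$x1$c - s$x0$c))), 1e-8)
  }

  # finite differences of the path match the velocity field
  t <- 0.35; h <- 1e-6
  xt <- interpolate_state(s$x0, s$x1, t)
  xh <- interpolate_state(s$x0, s$x1, t + h)
  v <- conditional_velocity(xt, s$x1, t)
  fd_c <- (xh$c - xt$c) / h
  expect_lt(max(abs(fd_c - v$c)), 1e-4)
  fd_int <- (xh$internal[[2]]$coords - xt$internal[[2]]$coords) / h
  expect_lt(max(abs(fd_int - v$internal[[2]])), 1e-4)

  # zero velocity at the target; 1/(1-t) growth of the magnitude
  expect_lt(max(abs(conditional_velocity(s$x1, s$x1, 0.5)$c)), 1e-9)
  v1 <- conditional_velocity(xt, s$x1, t)
  xt2 <- xt
  v2 <- denoiser_to_velocity(s$x1, xt2, t)
  expect_equal(v1$c, v2$c)
  expect_error(conditional_velocity(xt, s$x1, 1), "singular")
})

test_that("Euler step with the reparametrized velocity equals re-interpolation", {
  s <- make_states(5)
  for (t in c(0, 0.3, 0.7)) {
    xt <- interpolate_state(s$x0, s$x1, t); xt$t <- t
    h <- 0.1
    vel <- denoiser_to_velocity(s$x1, xt, t)
    xe <- euler_step(xt, vel, h)
    xr <- interpolate_state(xt, s$x1, h / (1 - t))
    expect_lt(max(abs(xe$c - xr$c)), 1e-9)
    expect_lt(max(abs(xe$R - xr$R)), 1e-9)
    expect_lt(max(abs(xe$internal[[2]]$coords - xr$internal[[2]]$coords)), 1e-9)
  }
})

test_that("cfm_loss obeys its closed-form weighting and invariances", {
  cx <- fixture_complex(6)
  expect_equal(cfm_loss(cx, cx, 0.5, "weighted_mse"), 0)
  expect_equal(cfm_loss(cx, cx, 0.5, "fape_like"), 0)
  # unit per-coordinate error at t = 0.5 -> 4.0
  shifted <- cx
  for (ci in 1:2) {
    shifted$chains[[ci]] <- flowdock:::map_chain_coords(shifted$chains[[ci]],
                                                        function(p) p + 1)
  }
  # unit per-coordinate error -> mse 1; weight 1/(1-t)^2 = 4
  expect_equal(cfm_loss(shifted, cx, 0.5, "weighted_mse"), 4, tolerance = 1e-9)
  expect_error(cfm_loss(cx, cx, 0.999999, "weighted_mse"), "singular")

  # fape_like is invariant to a global rigid transform of both inputs
  Q <- random_rotation(3); v <- c(2, 2, -1)
  pred <- move_ligand(cx, random_rotation(4), c(1, 0, 0))
  base <- fape_like_loss(pred, cx)
  both_t <- fape_like_loss(transform_complex(pred, Q, v),
                           transform_complex(cx, Q, v))
  expect_equal(base, both_t, tolerance = 1e-9)
  expect_gt(base, 0)
})

test_that("time grids are uniform, end before 1, and K=1 is single-shot", {
  g <- make_time_grid(10)
  expect_equal(as.numeric(g), seq(0, 0.9, by = 0.1))
  expect_identical(as.numeric(make_time_grid(1)), 0)
  expect_true(all(diff(g) > 0) && max(g) < 1)
  expect_error(make_time_grid(0), ">= 1")
})

test_that("integration is exact under the oracle denoiser and fixed under identity", {
  s <- make_states(7)
  oracle <- function(state, t) s$x1
  for (K in c(1, 3, 10)) {
    set.seed(41 + K)
    res <- integrate_flow(oracle, s$cx, s$prior, make_time_grid(K))
    rmsd <- sqrt(mean(rowSums((chain_ca(ligand_chain(res$final)) -
                                 chain_ca(ligand_chain(s$cx)))^2)))
    expect_lt(rmsd, 1e-6)
    expect_length(res$trajectory, K + 1L)
  }
  # identity denoiser: the prior sample is a fixed point
  identity_den <- function(state, t) state
  set.seed(4)
  res <- integrate_flow(identity_den, s$cx, s$prior, make_time_grid(5))
  set.seed(4)
  x0 <- sample_prior(s$cx, s$prior)
  expect_lt(max(abs(res$trajectory[[6]]$c - x0$c)), 1e-9)
  expect_lt(max(abs(res$trajectory[[6]]$R - x0$R)), 1e-9)
  # NaN from the denoiser aborts with the step index
  nan_den <- function(state, t) { state$c <- c(NaN, 0, 0); state }
  set.seed(4)
  expect_error(integrate_flow(nan_den, s$cx, s$prior, make_time_grid(5)),
               "non-finite state at step 1")
})

test_that("oracle-denoised finals collapse to x1 over many prior seeds", {
  s <- make_states(9)
  oracle <- function(state, t) s$x1
  worst <- 0
  for (seed in 1:50) {
    set.seed(seed)
    res <- integrate_flow(oracle, s$cx, s$prior, make_time_grid(10))
    rmsd <- sqrt(mean(rowSums((chain_ca(ligand_chain(res$final)) -
                                 chain_ca(ligand_chain(s$cx)))^2)))
    worst <- max(worst, rmsd)
  }
  expect_lt(worst, 1e-6)
})
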