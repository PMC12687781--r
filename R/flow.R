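# Conditional flow matching over the receptor-anchored state decomposition:
# ligand center c in R^3, ligand orientation R in SO(3), and per-chain
# internal coordinates after individual superposition. Translation and
# internal coordinates follow the straight conditional optimal-transport
# path; rotation follows the SO(3) geodesic. The learned denoiser predicts
# the fully denoised sample, and the sampler re-interpolates toward it, which
# is algebraically identical to an Euler step on the reparametrized velocity.

#' Prior specification for the flow
#'
#' @param sigma_tr Std (Angstrom) of the isotropic Gaussian translation prior,
#'   centered on the receptor CA centroid in the anchored frame.
#' @param flex_library Per-chain list (names = chain ids) of lists of
#'   conformers keyed by provenance (`holo`, `apo_like`, `predicted_like`);
#'   each entry a `ChainStructure` or list of them.
#' @param flex_sampling_probs Probabilities over
#'   `c(holo, apo_like, predicted_like)`; must sum to 1.
#' @return A `PriorSpec` list.
#' @export
prior_spec <- function(sigma_tr = 15, flex_library = NULL,
                       flex_sampling_probs = c(holo = 1, apo_like = 0,
                                               predicted_like = 0)) {
  stopifnot(sigma_tr > 0, abs(sum(flex_sampling_probs) - 1) < 1e-9)
  if (is.null(names(flex_sampling_probs))) {
    names(flex_sampling_probs) <- c("holo", "apo_like", "predicted_like")
  }
  structure(list(sigma_tr = sigma_tr, flex_library = flex_library,
                 flex_sampling_probs = flex_sampling_probs),
            class = "PriorSpec")
}

#' Receptor-anchored decomposition of a conformation
#'
#' The conformation is superposed onto `reference` on receptor CA atoms
#' (global RMSD alignment anchored on the receptor), then split into the
#' ligand CA centroid `c`, the ligand orientation `R` relative to the
#' reference ligand conformation, and per-chain internal coordinates after
#' individual CA superposition onto the reference chains.
#'
#' @param x,reference `ComplexConformation`s with identical chain topology
#'   and roles.
#' @param t Path time attached to the state (default `NA`).
#' @return A `DecomposedState`: list with `c` (3-vector), `R` (3x3 rotation),
#'   `internal` (list of `ChainStructure`s), `t`.
#' @export
decompose <- function(x, reference, t = NA_real_) {
  if (length(x$chains) != length(reference$chains) ||
      x$receptor_index != reference$receptor_index ||
      x$ligand_index != reference$ligand_index) {
    stop("chain topology / role mismatch between x and reference")
  }
  tf <- kabsch_align(chain_ca(receptor_chain(x)),
                     chain_ca(receptor_chain(reference)))
  anchored <- x
  anchored$chains <- lapply(x$chains, function(ch) {
    map_chain_coords(ch, function(p) apply_transform(p, tf))
  })
  lig <- ligand_chain(anchored)
  cvec <- colMeans(chain_ca(lig))
  tf_lig <- kabsch_align(chain_ca(lig), chain_ca(ligand_chain(reference)))
  R <- t(tf_lig$rotation)
  internal <- anchored$chains
  internal[[x$ligand_index]] <- map_chain_coords(lig, function(p) {
    apply_transform(p, tf_lig)
  })
  structure(list(c = cvec, R = R, internal = internal, t = t,
                 receptor_index = x$receptor_index,
                 ligand_index = x$ligand_index),
            class = "DecomposedState")
}

#' Recompose a DecomposedState into a conformation
#'
#' Inverse of [decompose()] in the receptor-anchored frame: the receptor is
#' taken from the internal coordinates as-is; the ligand internal coordinates
#' are centered on their CA centroid, rotated by `R` and moved to `c`.
#'
#' @param state A `DecomposedState`.
#' @param provenance Provenance tag for the result.
#' @return A `ComplexConformation`.
#' @export
recompose <- function(state, provenance = "sampled") {
  chains <- state$internal
  lig <- chains[[state$ligand_index]]
  cen <- colMeans(chain_ca(lig))
  R <- state$R; cv <- state$c
  chains[[state$ligand_index]] <- map_chain_coords(lig, function(p) {
    t(R %*% t(sweep(p, 2, cen))) + matrix(cv, nrow(p), 3, byrow = TRUE)
  })
  complex_conformation(chains, state$receptor_index, state$ligand_index,
                       provenance)
}

# Draw one conformer for a chain from the flex library by provenance probs.
.draw_conformer <- function(lib_entry, probs, chain_fallback) {
  avail <- names(lib_entry)[vapply(lib_entry, length, 1L) > 0]
  if (!length(avail)) {
    warning("empty flex library for a chain; falling back to holo input")
    return(list(chain = chain_fallback, provenance = "holo"))
  }
  p <- probs[avail]
  if (sum(p) <= 0) p <- stats::setNames(rep(1, length(avail)), avail)
  prov <- sample(avail, 1L, prob = p / sum(p))
  entry <- lib_entry[[prov]]
  if (is.list(entry) && !inherits(entry, "ChainStructure")) {
    entry <- entry[[sample.int(length(entry), 1L)]]
  }
  list(chain = entry, provenance = prov)
}

#' Sample a prior state at t = 0
#'
#' Translation is Gaussian with per-coordinate std `sigma_tr` centered on the
#' receptor CA centroid; orientation is Haar-uniform on SO(3); internal
#' coordinates are drawn from the unbound-conformer library by the provenance
#' sampling probabilities and individually aligned onto the chains of `x1`.
#'
#' @param x1 Reference `ComplexConformation` (defines the anchored frame and
#'   chain topology).
#' @param prior A [prior_spec()].
#' @return A `DecomposedState` at `t = 0` with attribute `flex_provenance`
#'   (per-chain provenance draws).
#' @export
sample_prior <- function(x1, prior) {
  ref_state <- decompose(x1, x1, t = 1)
  rec_cen <- colMeans(chain_ca(receptor_chain(x1)))
  c0 <- rec_cen + stats::rnorm(3, 0, prior$sigma_tr)
  R0 <- sample_uniform_rotation()
  internal <- ref_state$internal
  prov <- character(length(internal))
  for (ci in seq_along(internal)) {
    target <- internal[[ci]]
    cid <- target$chain_id
    lib_entry <- prior$flex_library[[cid]]
    if (is.null(lib_entry)) {
      drawn <- list(chain = target, provenance = "holo")
    } else {
      drawn <- .draw_conformer(lib_entry, prior$flex_sampling_probs, target)
    }
    prov[ci] <- drawn$provenance
    conf <- drawn$chain
    if (chain_length(conf) != chain_length(target)) {
      stop(sprintf("conformer length mismatch for chain %s", cid))
    }
    tf <- kabsch_align(chain_ca(conf), chain_ca(target))
    internal[[ci]] <- map_chain_coords(conf, function(p) apply_transform(p, tf))
  }
  st <- structure(list(c = c0, R = R0, internal = internal, t = 0,
                       receptor_index = x1$receptor_index,
                       ligand_index = x1$ligand_index),
                  class = "DecomposedState")
  attr(st, "flex_provenance") <- prov
  st
}

# Linear interpolation of the present-atom coordinates of two chains.
.lerp_chain <- function(a, b, t) {
  out <- a
  out$coords <- (1 - t) * a$coords + t * b$coords
  out
}

#' Interpolate two decomposed states along the conditional path
#'
#' Translation and internal coordinates interpolate linearly; orientation
#' follows the SO(3) geodesic. `t = 0` returns `x0`, `t = 1` returns `x1`.
#'
#' @param x0,x1 `DecomposedState`s sharing chain topology.
#' @param t Scalar in `[0, 1]`.
#' @return A `DecomposedState` at time `t` (absolute time is
#'   `(1 - t) * x0$t + t * x1$t` when both endpoints carry times).
#' @export
interpolate_state <- function(x0, x1, t) {
  stopifnot(t >= 0, t <= 1)
  internal <- Map(function(a, b) .lerp_chain(a, b, t), x0$internal, x1$internal)
  tt <- if (!is.na(x0$t) && !is.na(x1$t)) (1 - t) * x0$t + t * x1$t else NA_real_
  structure(list(c = (1 - t) * x0$c + t * x1$c,
                 R = geodesic_rotation(x0$R, x1$R, t),
                 internal = internal, t = tt,
                 receptor_index = x0$receptor_index,
                 ligand_index = x0$ligand_index),
            class = "DecomposedState")
}

#' Conditional velocity field of the optimal-transport path
#'
#' `u_t(x_t | x_1) = (x_1 - x_t) / (1 - t)` for the translation and internal
#' components; the rotation component is the geodesic tangent
#' `log(R_t^T R_1) / (1 - t)` (body-frame axis-angle).
#'
#' @param xt,x1 `DecomposedState`s.
#' @param t Scalar time, `t < 1 - 1e-6`.
#' @return List with `c` (3-vector per unit time), `rotation` (axis-angle
#'   3-vector), `internal` (list of coordinate arrays).
#' @export
conditional_velocity <- function(xt, x1, t) {
  if (t >= 1 - 1e-6) stop("velocity is singular at t >= 1")
  inv <- 1 / (1 - t)
  internal <- Map(function(a, b) (b$coords - a$coords) * inv,
                  xt$internal, x1$internal)
  list(c = (x1$c - xt$c) * inv,
       rotation = so3_log(crossprod(xt$R, x1$R)) * inv,
       internal = internal)
}

#' Velocity implied by a denoiser prediction
#'
#' Identical to [conditional_velocity()] with the network prediction
#' `x1_hat` in place of the data point: the reparametrization
#' `v_t = (xhat_1 - x_t) / (1 - t)`.
#' @param x1_hat,xt `DecomposedState`s.
#' @param t Scalar time, `t < 1 - 1e-6`.
#' @export
denoiser_to_velocity <- function(x1_hat, xt, t) {
  conditional_velocity(xt, x1_hat, t)
}

#' Euler step using a state-tangent velocity
#'
#' Advances translation and internal coordinates by `h * v` and the rotation
#' by `R exp(h * omega)`. Exposed so that the equivalence with
#' re-interpolation toward the prediction is testable.
#'
#' @param xt A `DecomposedState` at time `t`.
#' @param vel Velocity as returned by [conditional_velocity()].
#' @param h Time increment.
#' @export
euler_step <- function(xt, vel, h) {
  internal <- Map(function(ch, v) { ch$coords <- ch$coords + h * v; ch },
                  xt$internal, vel$internal)
  structure(list(c = xt$c + h * vel$c,
                 R = xt$R %*% so3_exp(h * vel$rotation),
                 internal = internal,
                 t = if (is.na(xt$t)) NA_real_ else xt$t + h,
                 receptor_index = xt$receptor_index,
                 ligand_index = xt$ligand_index),
            class = "DecomposedState")
}

#' Conditional flow-matching loss
#'
#' `weighted_mse`: mean squared coordinate error times `1 / (1 - t)^2`.
#' `fape_like`: mean over valid residue frames of the clamped (10 A)
#' frame-aligned error of the other chain's CA atoms, unweighted by `t`.
#'
#' @param x1_hat,x1 `ComplexConformation`s with matching topology.
#' @param t Path time, `t < 1 - 1e-6`.
#' @param mode `"weighted_mse"` or `"fape_like"`.
#' @return Non-negative scalar.
#' @export
cfm_loss <- function(x1_hat, x1, t, mode = c("weighted_mse", "fape_like")) {
  mode <- match.arg(mode)
  if (t >= 1 - 1e-6) stop("loss weight is singular at t >= 1")
  if (mode == "weighted_mse") {
    se <- 0; n <- 0
    for (ci in seq_along(x1$chains)) {
      a <- chain_atoms_flat(x1_hat$chains[[ci]])$coords
      b <- chain_atoms_flat(x1$chains[[ci]])$coords
      se <- se + sum((a - b)^2); n <- n + length(a)
    }
    return((se / n) / (1 - t)^2)
  }
  fape_like_loss(x1_hat, x1)
}

#' Cross-chain clamped frame-aligned point error
#'
#' For every valid backbone frame of one chain, the CA atoms of the other
#' chain are expressed in that local frame for both structures; the error is
#' the mean clamped (10 A) distance between the two local point clouds.
#' Invariant to global rigid transforms of either structure.
#'
#' @param model,native `ComplexConformation`s.
#' @param clamp Clamp distance (Angstrom).
#' @return Scalar.
#' @export
fape_like_loss <- function(model, native, clamp = 10) {
  ri <- model$receptor_index; li <- model$ligand_index
  total <- 0; nterm <- 0
  for (pair in list(c(ri, li), c(li, ri))) {
    fr_m <- backbone_frames(model$chains[[pair[1]]])
    fr_n <- backbone_frames(native$chains[[pair[1]]])
    ca_m <- chain_ca(model$chains[[pair[2]]])
    ca_n <- chain_ca(native$chains[[pair[2]]])
    for (i in which(fr_m$valid & fr_n$valid)) {
      loc_m <- sweep(ca_m, 2, fr_m$origins[i, ]) %*% fr_m$rotations[[i]]
      loc_n <- sweep(ca_n, 2, fr_n$origins[i, ]) %*% fr_n$rotations[[i]]
      d <- pmin(sqrt(rowSums((loc_m - loc_n)^2)), clamp)
      total <- total + sum(d); nterm <- nterm + length(d)
    }
  }
  total / nterm
}

#' Uniform time grid for sampling
#'
#' `K` grid points `t_k = k / K`, `k = 0 .. K-1`; `t = 1` is never fed to the
#' network — the final update jumps directly to the last prediction.
#'
#' @param K Number of integration steps (>= 1).
#' @return Numeric vector of times (class `TimeGrid`).
#' @export
make_time_grid <- function(K) {
  if (K < 1) stop("K must be >= 1")
  structure(seq(0, (K - 1) / K, length.out = K), class = "TimeGrid")
}

#' Integrate the learned flow from a prior draw to a predicted complex
#'
#' Starting from a prior sample, each step queries the denoiser for the fully
#' denoised prediction and re-interpolates toward it with the effective ratio
#' `(t_{k+1} - t_k) / (1 - t_k)`; the final update jumps to the last
#' prediction. With a denoiser that always returns the true bound state the
#' trajectory ends exactly at the bound pose for any step count.
#'
#' @param denoiser `function(state, t) -> DecomposedState` predicting the
#'   denoised state.
#' @param reference `ComplexConformation` defining topology and the anchored
#'   frame (its chains supply the holo fallback of the prior).
#' @param prior A [prior_spec()].
#' @param grid A [make_time_grid()] result (or numeric vector of times).
#' @return List with `final` (`ComplexConformation`) and `trajectory`
#'   (list of `DecomposedState`s, one per grid point plus the final
#'   prediction).
#' @export
integrate_flow <- function(denoiser, reference, prior, grid = make_time_grid(10)) {
  K <- length(grid)
  xt <- sample_prior(reference, prior)
  trajectory <- vector("list", K + 1L)
  trajectory[[1L]] <- xt
  for (k in seq_len(K)) {
    tk <- grid[k]
    x1_hat <- denoiser(xt, tk)
    if (any(!is.finite(x1_hat$c)) || any(!is.finite(x1_hat$R))) {
      stop(sprintf("denoiser returned non-finite state at step %d", k))
    }
    if (k < K) {
      s <- (grid[k + 1L] - tk) / (1 - tk)
      xt <- interpolate_state(xt, x1_hat, s)
      xt$t <- grid[k + 1L]
      trajectory[[k + 1L]] <- xt
    } else {
      x1_hat$t <- 1
      trajectory[[K + 1L]] <- x1_hat
      xt <- x1_hat
    }
  }
  list(final = recompose(xt), trajectory = trajectory)
}
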