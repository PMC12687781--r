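# The docking network at toy scale: structure / conditioning embedders
# (linear embedding + pair-stack blocks), an AdaLN-conditioned pair denoiser
# (triangle multiplicative updates, triangle attention, pair transition), and
# pose / confidence readouts closing the loop to coordinates.
#
# All sublayer output projections and the readout head are zero-initialized,
# so an untrained model is exactly the identity map on the state.

#' Denoiser configuration
#'
#' @param channels Pair-representation channel width C.
#' @param n_blocks Number of pair-denoiser blocks (default 4).
#' @param n_heads Attention heads (C must be divisible by it).
#' @param embedder_blocks Pair-stack blocks in each embedder (default 2).
#' @param readout One of `"rigid"` (internal coordinates copied from the
#'   input) or `"rigid_deform"` (adds a bounded per-residue deformation).
#' @param confidence Whether the confidence readout head is present.
#' @param use_seq_embed Whether residue-identity channels are used (the
#'   sequence-features ablation toggle).
#' @return A `DenoiserConfig` list.
#' @export
denoiser_config <- function(channels = 16L, n_blocks = 4L, n_heads = 2L,
                            embedder_blocks = 2L,
                            readout = c("rigid", "rigid_deform"),
                            confidence = TRUE, use_seq_embed = TRUE) {
  readout <- match.arg(readout)
  stopifnot(n_blocks >= 1L, channels %% n_heads == 0L)
  structure(list(channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 embedder_blocks = as.integer(embedder_blocks),
                 readout = readout, confidence = confidence,
                 use_seq_embed = use_seq_embed),
            class = "DenoiserConfig")
}

# ---- parameter construction ----------------------------------------------

.p_linear <- function(fan_in, fan_out, init = c("normal", "zero"),
                      bias = TRUE, bias_init = 0) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, fan_in, fan_out) else
    matrix(stats::rnorm(fan_in * fan_out, 0, 1 / sqrt(fan_in)), fan_in, fan_out)
  out <- list(W = ad_param(W))
  if (bias) out$b <- ad_param(rep(bias_init, fan_out))
  out
}

.p_layernorm <- function(C) {
  list(gamma = ad_param(rep(1, C)), beta = ad_param(rep(0, C)))
}

.p_tri_mult <- function(C) {
  list(ln = .p_layernorm(C),
       ap = .p_linear(C, C), ag = .p_linear(C, C),
       bp = .p_linear(C, C), bg = .p_linear(C, C),
       ln_out = .p_layernorm(C),
       g = .p_linear(C, C), o = .p_linear(C, C, init = "zero"))
}

.p_attn <- function(C, h) {
  # packed query/key/value/pair-bias projection (no bias terms)
  list(qkvb = .p_linear(C, 3L * C + h, bias = FALSE),
       g = .p_linear(C, C), o = .p_linear(C, C, init = "zero"))
}

.p_transition <- function(C, expand = 4L) {
  list(l1 = .p_linear(C, C * expand), l2 = .p_linear(C * expand, C, init = "zero"))
}

.p_adaln <- function(C) {
  # scale and gate start at 1, shift at 0: AdaLN is a plain layer norm at init
  list(s = .p_linear(C, C, init = "zero", bias_init = 1),
       sh = .p_linear(C, C, init = "zero", bias_init = 0),
       g = .p_linear(C, C, init = "zero", bias_init = 1))
}

.p_plain_block <- function(C, h) {
  list(tm_out = .p_tri_mult(C), tm_in = .p_tri_mult(C),
       ln_as = .p_layernorm(C), attn_s = .p_attn(C, h),
       ln_ae = .p_layernorm(C), attn_e = .p_attn(C, h),
       ln_tr = .p_layernorm(C), trans = .p_transition(C))
}

.p_denoiser_block <- function(C, h) {
  list(tm_out = .p_tri_mult(C), tm_in = .p_tri_mult(C),
       ada_as = .p_adaln(C), attn_s = .p_attn(C, h),
       ada_ae = .p_adaln(C), attn_e = .p_attn(C, h),
       ada_tr = .p_adaln(C), trans = .p_transition(C))
}

#' Initialize a denoiser model
#'
#' @param cfg A [denoiser_config()].
#' @param seed Integer seed for weight initialization.
#' @return A model list with `cfg` and nested parameter groups `embed`,
#'   `cond`, `denoise`, `readout`, `conf`.
#' @export
init_denoiser <- function(cfg = denoiser_config(), seed = 1L) {
  set.seed(seed)
  C <- cfg$channels; h <- cfg$n_heads
  n_in <- n_pair_feature_channels()
  n_cond <- n_in + 2L * TIME_FOURIER_K
  params <- list(
    embed = list(lin_in = .p_linear(n_in, C),
                 blocks = lapply(seq_len(cfg$embedder_blocks),
                                 function(i) .p_plain_block(C, h))),
    cond = list(lin_in = .p_linear(n_cond, C)),
    denoise = list(blocks = lapply(seq_len(cfg$n_blocks),
                                   function(i) .p_denoiser_block(C, h))),
    readout = list(l1 = .p_linear(C, C),
                   l2 = .p_linear(C, 10L, init = "zero"),
                   gc = ad_param(matrix(0, 1, 1)),
                   gr = ad_param(matrix(0, 1, 1))),
    deform = if (cfg$readout == "rigid_deform") {
      list(l1 = .p_linear(C, C), l2 = .p_linear(C, 3L, init = "zero"))
    },
    conf = if (cfg$confidence) {
      # per-pair scorer on inter-chain entries (raw positional features
      # concatenated with the embedded pair row), pooled afterwards
      list(l1 = .p_linear(n_in + C, C), l2 = .p_linear(C, 1L))
    }
  )
  structure(list(cfg = cfg, params = params), class = "flowdock_model")
}

#' Collect parameter nodes of a model, tagged by top-level group
#' @return Named list of `ad_param` nodes (names encode the group path).
#' @keywords internal
collect_params <- function(model) {
  out <- list()
  walk <- function(x, path) {
    if (is_ad_node(x)) {
      out[[path]] <<- x
    } else if (is.list(x)) {
      keys <- names(x)
      if (is.null(keys)) keys <- as.character(seq_along(x))
      for (k in seq_along(x)) {
        key <- if (is.null(names(x)) || names(x)[k] == "") {
          as.character(k)
        } else {
          names(x)[k]
        }
        if (!is.null(x[[k]])) walk(x[[k]], paste(path, key, sep = "/"))
      }
    }
  }
  walk(model$params, "")
  names(out) <- sub("^/", "", names(out))
  out
}

# ---- forward building blocks ---------------------------------------------

.f_linear <- function(p, X) ad_linear(X, p$W, p$b)

.f_ln <- function(p, X) ad_layernorm(X, p$gamma, p$beta)

# Layer norm without learned affine (AdaLN modulation supplies it).
.f_ln_plain <- function(X) {
  C <- ncol(X$val)
  ad_layernorm(X, ad_const(rep(1, C)), ad_const(rep(0, C)))
}

# triangle multiplicative update; Zin is the (already normalized) input,
# returns the residual delta
.f_tri_mult_core <- function(p, Zin, L, direction) {
  a <- ad_glu(Zin, p$ag, p$ap)
  b <- ad_glu(Zin, p$bg, p$bp)
  o <- ad_tri_mult(a, b, L, direction)
  g <- ad_sigmoid(.f_linear(p$g, Zin))
  ad_mul(g, .f_linear(p$o, .f_ln(p$ln_out, o)))
}

.f_tri_mult_block <- function(p, Z, L, direction) {
  ad_add(Z, .f_tri_mult_core(p, .f_ln(p$ln, Z), L, direction))
}

# triangle attention core on a normalized input (starting-node flavor)
.f_attn_core <- function(p, Zin, L, h) {
  O <- ad_tri_attention(ad_matmul(Zin, p$qkvb$W), L, h)
  G <- ad_sigmoid(.f_linear(p$g, Zin))
  .f_linear(p$o, ad_mul(G, O))
}

# AdaLN-conditioned residual sublayer: Z + gate(cond) * core(LN(Z) * s + sh)
.f_adaln_sublayer <- function(pa, Z, cond_rep, core) {
  s <- .f_linear(pa$s, cond_rep)
  sh <- .f_linear(pa$sh, cond_rep)
  g <- .f_linear(pa$g, cond_rep)
  zin <- ad_add(ad_mul(.f_ln_plain(Z), s), sh)
  ad_add(Z, ad_mul(g, core(zin)))
}

.f_transition_core <- function(p, Zin) {
  .f_linear(p$l2, ad_relu(.f_linear(p$l1, Zin)))
}

# Unconditioned pair-stack block (embedders).
.f_plain_block <- function(p, Z, L, h) {
  Z <- .f_tri_mult_block(p$tm_out, Z, L, "outgoing")
  Z <- .f_tri_mult_block(p$tm_in, Z, L, "incoming")
  Z <- ad_add(Z, .f_attn_core(p$attn_s, .f_ln(p$ln_as, Z), L, h))
  Zt <- ad_transpose_pair(Z, L)
  delta_t <- .f_attn_core(p$attn_e, .f_ln(p$ln_ae, Zt), L, h)
  Z <- ad_add(Z, ad_transpose_pair(delta_t, L))
  ad_add(Z, .f_transition_core(p$trans, .f_ln(p$ln_tr, Z)))
}

# AdaLN-conditioned denoiser block.
.f_denoiser_block <- function(p, Z, cond_rep, L, h) {
  Z <- .f_tri_mult_block(p$tm_out, Z, L, "outgoing")
  Z <- .f_tri_mult_block(p$tm_in, Z, L, "incoming")
  Z <- .f_adaln_sublayer(p$ada_as, Z, cond_rep,
                         function(zin) .f_attn_core(p$attn_s, zin, L, h))
  # ending-node attention: transpose the pair dimension, reuse the machinery
  Zt <- ad_transpose_pair(Z, L)
  condt <- ad_transpose_pair(cond_rep, L)
  Zt <- .f_adaln_sublayer(p$ada_ae, Zt, condt,
                          function(zin) .f_attn_core(p$attn_e, zin, L, h))
  Z <- ad_transpose_pair(Zt, L)
  .f_adaln_sublayer(p$ada_tr, Z, cond_rep,
                    function(zin) .f_transition_core(p$trans, zin))
}

#' Structure embedder: features -> noisy pair representation
#' @param model A model from [init_denoiser()].
#' @param feat Feature list from [assemble_features()].
#' @return An autodiff node (`L^2 x C`).
#' @export
structure_embedder <- function(model, feat) {
  p <- model$params$embed
  Z <- .f_linear(p$lin_in, ad_const(feat$noisy))
  for (blk in p$blocks) Z <- .f_plain_block(blk, Z, feat$L, model$cfg$n_heads)
  if (any(!is.finite(Z$val))) stop("non-finite values in structure embedder")
  Z
}

#' Conditioning embedder: features + time -> pair conditioning
#'
#' The pair conditioning is a linear embedding of the same positional
#' features as the noisy pair representation plus the time embedding; it
#' modulates the denoiser blocks through AdaLN.
#' @inheritParams structure_embedder
#' @export
conditioning_embedder <- function(model, feat) {
  p <- model$params$cond
  Z <- .f_linear(p$lin_in, ad_const(feat$cond))
  if (any(!is.finite(Z$val))) stop("non-finite values in conditioning embedder")
  Z
}

#' Pair denoiser: conditioned denoising of the pair representation
#' @param model Model list.
#' @param noisy,cond_rep Autodiff nodes (`L^2 x C`).
#' @param L Residue count.
#' @return Denoised pair representation node.
#' @export
pair_denoiser <- function(model, noisy, cond_rep, L) {
  Z <- noisy
  for (bi in seq_along(model$params$denoise$blocks)) {
    Z <- .f_denoiser_block(model$params$denoise$blocks[[bi]], Z, cond_rep, L,
                           model$cfg$n_heads)
    if (any(!is.finite(Z$val))) {
      stop(sprintf("non-finite values after denoiser block %d", bi))
    }
  }
  Z
}

#' Adaptive layer normalization (standalone)
#'
#' Layer-normalizes `pair` and modulates it with element-wise scale and shift
#' predicted from `cond`; a separately predicted gate rescales the residual
#' delta. Exposed for direct testing; the denoiser blocks use the same
#' machinery internally.
#'
#' @param pa AdaLN parameter group (as in `.p_adaln`).
#' @param pair,cond Autodiff nodes of matching shape.
#' @param core Function mapping the modulated input node to a delta node.
#' @return Node: `pair + gate * core(LN(pair) * scale + shift)`.
#' @export
adaln <- function(pa, pair, cond, core = identity) {
  .f_adaln_sublayer(pa, pair, cond, core)
}

# ---- readouts -------------------------------------------------------------

# Indices and frames needed by the pose readout, from a decomposed state.
.readout_geometry <- function(state, feat) {
  L <- feat$L
  lens <- feat$chain_lengths
  ri <- state$receptor_index; li <- state$ligand_index
  offs <- c(0L, cumsum(lens))
  rec_idx <- offs[ri] + seq_len(lens[ri])
  lig_idx <- offs[li] + seq_len(lens[li])
  fr <- backbone_frames(state$internal[[ri]])
  valid <- which(fr$valid)
  groups <- lapply(valid, function(i) pair_index(rec_idx[i], lig_idx, L))
  list(rec_idx = rec_idx, lig_idx = lig_idx, valid_rec = valid,
       frames = fr$rotations[valid], L = L)
}

#' Pose readout: pair representation + current state -> predicted x1
#'
#' Anchor-voting readout. Three body anchors of the ligand (its internal CA
#' centroid and two points offset along its principal axes) have
#' receptor-determined images under the bound pose. Every receptor residue
#' votes for each image as `CA_i + F_i d_ik` (local-frame offsets, pooled
#' from the receptor-to-ligand block of the pair representation), the votes
#' are combined under softmax attention weights, and two learned scalar
#' gates mix the absolute estimates with the anchors' current images: the
#' centroid gate gives the denoised center, and differentiable Gram-Schmidt
#' over the gated anchor displacements gives the denoised orientation. At
#' zero-initialized weights the gates are closed and the prediction is
#' exactly the input state; on bound toy complexes the open-gate branch
#' reads the pose off the receptor geometry alone.
#'
#' @param model Model list.
#' @param pair Pair-representation node.
#' @param state Current `DecomposedState` (x_t).
#' @param feat Feature list (for chain indexing).
#' @return List with nodes `c_hat` (1 x 3), `R_hat` (3 x 3), the per-anchor
#'   vote matrices and absolute estimates (`votes`, `zhat`), the anchor
#'   geometry, and `deform` (per-residue displacement node, or NULL in
#'   rigid mode).
#' @export
pose_readout <- function(model, pair, state, feat) {
  p <- model$params$readout
  geo <- .readout_geometry(state, feat)
  P <- ad_pool_rows(pair, lapply(geo$valid_rec, function(k) {
    pair_index(geo$rec_idx[k], geo$lig_idx, geo$L)
  }))
  Hdn <- ad_relu(.f_linear(p$l1, P))
  out <- .f_linear(p$l2, Hdn)          # R x 10: [logit, d1(3), d2(3), d3(3)]
  s <- ad_slice_cols(out, 1L)
  a <- ad_softmax_rows(ad_transpose_vec(s))   # 1 x R
  ca_rec <- chain_ca(state$internal[[state$receptor_index]])
  ca_valid <- ca_rec[geo$valid_rec, , drop = FALSE]

  # Ligand body anchors in internal coordinates: the CA centroid plus two
  # points offset along the principal axes of the internal conformer (signs
  # fixed deterministically). Their images under the bound pose are
  # receptor-determined physical points that every receptor residue votes
  # for as CA_i + F_i d_ik (output scaling x4 lets the zero-initialized head
  # reach tens of Angstroms with small weights).
  anch <- .ligand_anchors(state)
  zt <- t(state$R %*% t(sweep(anch$y, 2, anch$cen))) +
    matrix(state$c, 3, 3, byrow = TRUE)      # anchor images under x_t
  votes <- vector("list", 3L)
  zhat <- vector("list", 3L)
  zg <- vector("list", 3L)
  for (k in 1:3) {
    Dk <- ad_scale(ad_slice_cols(out, (2L + 3L * (k - 1L)):(4L + 3L * (k - 1L))), 4)
    votes[[k]] <- ad_add(ad_const(ca_valid), ad_frames_apply(Dk, geo$frames))
    zhat[[k]] <- ad_matmul(a, votes[[k]])    # 1 x 3 absolute estimate
    gate <- if (k == 1L) p$gc else p$gr
    zg[[k]] <- ad_add(ad_const(matrix(zt[k, ], 1)),
                      ad_matmul(gate, ad_sub(zhat[[k]],
                                             ad_const(matrix(zt[k, ], 1)))))
  }
  c_hat <- zg[[1L]]

  # orientation by Gram-Schmidt over the gated anchor displacements; at zero
  # gates this reproduces R_t exactly (the anchors are then the x_t images)
  u1 <- ad_sub(zg[[2L]], zg[[1L]])
  u2 <- ad_sub(zg[[3L]], zg[[1L]])
  g1 <- ad_l2normalize_vec(u1)
  proj <- ad_matmul(u2, ad_transpose_vec(g1))            # 1 x 1
  g2 <- ad_l2normalize_vec(ad_sub(u2, ad_matmul(proj, g1)))
  g3 <- ad_cross_vec(g1, g2)
  B <- ad_concat_rows(g1, g2, g3)                        # rows: images of e1..e3
  E <- rbind(anch$axes[, 1], anch$axes[, 2],
             c(anch$axes[2, 1] * anch$axes[3, 2] - anch$axes[3, 1] * anch$axes[2, 2],
               anch$axes[3, 1] * anch$axes[1, 2] - anch$axes[1, 1] * anch$axes[3, 2],
               anch$axes[1, 1] * anch$axes[2, 2] - anch$axes[2, 1] * anch$axes[1, 2]))
  R_hat <- ad_matmul(ad_transpose_vec(B), ad_const(E))   # G %*% E
  deform <- NULL
  if (model$cfg$readout == "rigid_deform") {
    pd <- model$params$deform
    # per-residue deformation in the residue's own frame, bounded per axis
    all_groups <- lapply(seq_len(feat$L), function(i) {
      pair_index(i, seq_len(feat$L), feat$L)
    })
    Pd <- ad_pool_rows(pair, all_groups)
    raw <- .f_linear(pd$l2, ad_relu(.f_linear(pd$l1, Pd)))
    deform <- ad_scale(ad_tanh(raw), 1.7)   # |shift| <= ~3 A per residue
  }
  list(c_hat = c_hat, R_hat = R_hat, c_abs = zhat[[1L]],
       votes = votes, zhat = zhat, anchors = anch,
       deform = deform, geo = geo)
}

# Ligand body anchors in internal coordinates: the CA centroid and two points
# offset along the principal axes of the conformer. Axis signs are fixed by
# intrinsic chain geometry (N-to-C direction; first-residue direction), so
# the anchors are independent of the conformer's ambient placement.
.ligand_anchors <- function(state, lever = 8) {
  ca <- chain_ca(state$internal[[state$ligand_index]])
  cen <- colMeans(ca)
  cc <- sweep(ca, 2, cen)
  sv <- svd(cc)
  axes <- sv$v[, 1:2, drop = FALSE]
  L <- nrow(ca)
  ref1 <- ca[L, ] - ca[1, ]
  ref2 <- ca[1, ] - cen
  for (k in 1:2) {
    ref <- if (k == 1L) ref1 else ref2
    d <- sum(axes[, k] * ref)
    if (abs(d) < 1e-8) d <- sum(axes[, k] * (ca[2, ] - ca[1, ]))
    if (d < 0) axes[, k] <- -axes[, k]
  }
  y <- rbind(cen, cen + lever * axes[, 1], cen + lever * axes[, 2])
  list(y = y, cen = cen, axes = axes, lever = lever)
}

#' Native anchor-image targets for the absolute pose branch
#'
#' Images of the state's ligand body anchors under the native pose
#' `(c1, R1)`: `z_k = R1 (y_k - cen) + c1`.
#' @keywords internal
.pose_targets <- function(native_state, anchors) {
  t(native_state$R %*% t(sweep(anchors$y, 2, anchors$cen))) +
    matrix(native_state$c, 3, 3, byrow = TRUE)
}

# transpose a column node (R x 1) into (1 x R)
ad_transpose_vec <- function(x) {
  x <- .as_node(x)
  .ad_node(t(x$val), list(x), function(g, node) {
    .acc(node$parents[[1]], t(g))
  })
}

ad_concat_cols <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  na <- ncol(a$val)
  .ad_node(cbind(a$val, b$val), list(a, b), function(g, node) {
    .acc(node$parents[[1]], g[, seq_len(na), drop = FALSE])
    .acc(node$parents[[2]], g[, -seq_len(na), drop = FALSE])
  })
}

ad_tanh <- function(a) {
  a <- .as_node(a)
  .ad_node(tanh(a$val), list(a), function(g, node) {
    .acc(node$parents[[1]], g * (1 - node$val^2))
  })
}

#' Confidence readout: pair representation -> scalar in [0, 1]
#'
#' Scores every inter-chain entry — the structure's raw positional pair
#' features concatenated with the corresponding embedded pair-representation
#' row — with a small per-pair MLP, averages the per-pair scores over both
#' inter-chain blocks and squashes through a sigmoid. Scoring before pooling
#' lets the head express contact-counting statistics (for example "biased
#' residue pair in contact") that mean-pooled channels cannot. Regresses the
#' docking quality (DockQ) of the model's own prediction; used to rank
#' samples (the ipTM surrogate of sample-and-rank inference). See
#' [predict_confidence()] for the scoring entry point.
#'
#' @param model Model list.
#' @param pair Pair-representation node of the scored structure.
#' @param feat Feature list of the structure being scored
#'   (from [assemble_features()]).
#' @param state Object carrying `receptor_index` / `ligand_index`
#'   (a `DecomposedState` or `ComplexConformation`).
#' @return Scalar autodiff node in (0, 1).
#' @export
confidence_readout <- function(model, pair, feat, state) {
  if (is.null(model$params$conf)) stop("model has no confidence head")
  p <- model$params$conf
  lens <- feat$chain_lengths
  offs <- c(0L, cumsum(lens))
  ri <- state$receptor_index; li <- state$ligand_index
  rec_idx <- offs[ri] + seq_len(lens[ri])
  lig_idx <- offs[li] + seq_len(lens[li])
  rl <- as.vector(outer(rec_idx, (lig_idx - 1L) * feat$L, "+"))
  lr <- as.vector(outer(lig_idx, (rec_idx - 1L) * feat$L, "+"))
  rows <- c(rl, lr)
  Zi <- ad_concat_cols(ad_const(feat$noisy[rows, , drop = FALSE]),
                       ad_slice_rows(pair, rows))
  per_pair <- .f_linear(p$l2, ad_relu(.f_linear(p$l1, Zi)))
  ad_sigmoid(ad_mean_all(per_pair))
}

# ---- full forward ---------------------------------------------------------

#' Run the full docking network on a state
#'
#' Featurizes the (noisy) state, embeds it, denoises the pair representation
#' under the time conditioning and reads out the predicted denoised state.
#'
#' @param model Model list.
#' @param state A `DecomposedState` at time `t`.
#' @param t Path time in `[0, 1)`.
#' @return List with `x1_hat` (a `DecomposedState` whose `c`/`R` carry the
#'   numeric prediction), node-level outputs (`c_hat`, `R_hat`, `votes`,
#'   `zhat`, `deform`, `pair`), and `feat`.
#' @export
model_forward <- function(model, state, t) {
  feat <- assemble_features(state, t, use_seq_embed = model$cfg$use_seq_embed)
  noisy <- structure_embedder(model, feat)
  cond_rep <- conditioning_embedder(model, feat)
  pair <- pair_denoiser(model, noisy, cond_rep, feat$L)
  ro <- pose_readout(model, pair, state, feat)
  internal <- state$internal
  if (!is.null(ro$deform)) {
    offs <- c(0L, cumsum(feat$chain_lengths))
    for (ci in seq_along(internal)) {
      idx <- offs[ci] + seq_len(feat$chain_lengths[ci])
      shift <- ro$deform$val[idx, , drop = FALSE]
      internal[[ci]] <- map_chain_coords_phantom(internal[[ci]], shift)
    }
  }
  x1_hat <- structure(list(c = as.vector(ro$c_hat$val), R = ro$R_hat$val,
                           internal = internal, t = 1,
                           receptor_index = state$receptor_index,
                           ligand_index = state$ligand_index),
                      class = "DecomposedState")
  list(x1_hat = x1_hat, c_hat = ro$c_hat, R_hat = ro$R_hat,
       c_abs = ro$c_abs, votes = ro$votes, zhat = ro$zhat,
       anchors = ro$anchors,
       deform = ro$deform, pair = pair, feat = feat, geo = ro$geo)
}

#' Score a predicted complex with the trained confidence head
#'
#' Featurizes the predicted structure, embeds it with the structure embedder
#' and applies the confidence readout to the embedded pair representation
#' (with the raw features alongside). This is the ranking score of
#' sample-and-rank inference: a learned structure-quality readout of the
#' model's own prediction.
#'
#' @param model Model with a confidence head.
#' @param prediction A `ComplexConformation`.
#' @return Scalar in (0, 1).
#' @export
predict_confidence <- function(model, prediction) {
  if (is.null(model$params$conf)) stop("model has no confidence head")
  feat <- assemble_features(prediction, t = 1,
                            use_seq_embed = model$cfg$use_seq_embed)
  pair <- structure_embedder(model, feat)
  as.numeric(confidence_readout(model, pair, feat, prediction)$val)
}

# shift every atom of residue i by shift[i, ]
map_chain_coords_phantom <- function(chain, shift) {
  L <- chain_length(chain)
  for (ai in seq_len(5L)) {
    chain$coords[, ai, ] <- chain$coords[, ai, ] + shift
  }
  chain
}

#' Wrap a model as a denoiser callable for [integrate_flow()]
#' @param model Model list.
#' @return `function(state, t) -> DecomposedState`.
#' @export
as_denoiser <- function(model) {
  function(state, t) model_forward(model, state, t)$x1_hat
}
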