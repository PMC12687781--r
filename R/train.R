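# CFM training: per-step path sampling (t ~ U[0, 1-eps), prior draw with
# staged monomer-provenance probabilities, interpolation, denoiser forward,
# structure loss, Adam update on the stage's trainable scope), plus the
# three-stage schedule and sample-and-rank docking inference.

#' Training configuration
#'
#' Three stages by default: stages 1 and 2 train the docking module
#' (embedders, pair denoiser, pose readout) and differ only in monomer
#' sampling — stage 1 holo-only, stage 2 mixed 20/40/40
#' holo/apo-like/predicted-like; stage 3 trains all parameters including the
#' confidence head under the same mixed sampling.
#'
#' @param stages List of stages; each a list with `steps`, `scope` (character
#'   vector of parameter groups among `embed`, `cond`, `denoise`, `readout`,
#'   `deform`, `conf`) and `probs` (holo/apo/predicted sampling
#'   probabilities).
#' @param lr Adam learning rate (initial).
#' @param lr_final Learning rate at the last step of the whole schedule;
#'   decayed linearly across stages (default: equal to `lr`, no decay).
#' @param sigma_tr Translation prior std (Angstrom).
#' @param loss_mode Structure objective: `"mse"` (default; coordinate MSE of
#'   the denoised prediction, unweighted in t), `"weighted_mse"` (the
#'   `1/(1-t)^2`-weighted CFM objective) or `"fape_like"` (clamped
#'   cross-chain frame-aligned error). The unweighted default is a stability
#'   choice: the CFM weight concentrates gradient mass on `t -> 1` samples,
#'   where the best prediction is the input itself, which measurably stalls
#'   pose learning at this data scale.
#' @param conf_loss_weight Weight of the confidence regression loss (applied
#'   when `conf` is in scope).
#' @param seed Master seed; every step derives its own substream.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(stages = NULL, lr = 5e-3, lr_final = 1e-3,
                         sigma_tr = 15,
                         loss_mode = c("mse", "weighted_mse", "fape_like"),
                         conf_loss_weight = 1.0, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (is.null(stages)) {
    mixed <- c(holo = 0.2, apo_like = 0.4, predicted_like = 0.4)
    stages <- list(
      list(steps = 1700L,
           scope = c("embed", "cond", "denoise", "readout"),
           probs = c(holo = 1, apo_like = 0, predicted_like = 0)),
      list(steps = 400L,
           scope = c("embed", "cond", "denoise", "readout", "conf"),
           probs = mixed),
      list(steps = 400L,
           scope = c("embed", "cond", "denoise", "readout", "deform", "conf"),
           probs = mixed)
    )
  }
  for (st in stages) {
    stopifnot(st$steps > 0, abs(sum(st$probs) - 1) < 1e-9)
  }
  structure(list(stages = stages, lr = lr, lr_final = lr_final,
                 sigma_tr = sigma_tr,
                 loss_mode = loss_mode, conf_loss_weight = conf_loss_weight,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# Evaluate an expression with the autodiff tape suspended (no recording).
.without_tape <- function(expr) {
  saved <- .ad$tape
  .ad$tape <- NULL
  on.exit(.ad$tape <- saved)
  force(expr)
}

# ---- Adam -----------------------------------------------------------------

.adam_step <- function(params, lr, t_step, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, scope_names = NULL) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!is.null(scope_names) && !nm %in% scope_names) next
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t_step)
    vhat <- p$v / (1 - beta2^t_step)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

.zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Parameter names belonging to the given top-level scope groups.
.scope_names <- function(params, groups) {
  nms <- names(params)
  top <- vapply(strsplit(nms, "/"), `[[`, "", 1L)
  nms[top %in% groups]
}

# ---- records --------------------------------------------------------------

#' Generate toy training records in memory
#'
#' Each record holds the bound complex plus a per-chain conformer library
#' (holo = chain extracted from the bound complex; apo-like and
#' predicted-like = perturbed conformers).
#'
#' @param n Number of complexes.
#' @param seed Master seed.
#' @param length_range Chain length range.
#' @param ... Passed to [toy_complex_spec()] fields.
#' @return List of records: `x1` (`ComplexConformation`), `flex` (library for
#'   [prior_spec()]), `id`.
#' @export
make_toy_records <- function(n, seed = 1L, length_range = c(16L, 24L),
                             interface_patch_size = 6L, contact_target = 6L,
                             clash_floor = 2.5) {
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- NULL
    cseed <- NA_integer_
    for (try in seq_len(20L)) {
      cseed <- derive_seed(seed, "complex", i, "try", try)
      set.seed(cseed)
      lens <- sample(length_range[1]:length_range[2], 2L, replace = TRUE)
      spec <- toy_complex_spec(lens[1], lens[2], interface_patch_size,
                               contact_target, clash_floor, seed = cseed)
      cx <- tryCatch(generate_bound_complex(spec), error = function(e) NULL)
      if (!is.null(cx)) break
    }
    if (is.null(cx)) stop(sprintf("complex %d failed after bounded retries", i))
    flex <- list()
    for (ci in seq_along(cx$chains)) {
      ch <- cx$chains[[ci]]
      flex[[ch$chain_id]] <- list(
        holo = ch,
        apo_like = perturb_unbound(
          ch, flex_perturb_spec("apo_like", seed = derive_seed(cseed, "apo", ci))),
        predicted_like = perturb_unbound(
          ch, flex_perturb_spec("predicted_like",
                                seed = derive_seed(cseed, "pred", ci)))
      )
    }
    records[[i]] <- list(x1 = cx, flex = flex, id = sprintf("cx%04d", i))
  }
  records
}

#' Load training records from a dataset manifest
#'
#' @param manifest_path Path to a `manifest.jsonl` written by
#'   [build_dataset()].
#' @return List of records as in [make_toy_records()].
#' @export
load_records <- function(manifest_path) {
  lines <- readLines(manifest_path)
  base <- dirname(manifest_path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    x1 <- read_pdb(file.path(base, rec$bound))
    flex <- list()
    for (cid in names(rec$monomers)) {
      entry <- rec$monomers[[cid]]
      flex[[cid]] <- lapply(entry, function(p) {
        read_monomer_pdb(file.path(base, p))
      })
    }
    list(x1 = x1, flex = flex, id = rec$id)
  })
}

# ---- node-level losses ----------------------------------------------------

ad_transpose <- function(x) ad_transpose_vec(x)

# Predicted ligand CA coordinates as a node: rotate the (constant) internal
# conformer about its CA centroid by R_hat and translate to c_hat.
.pred_ligand_ca_node <- function(fwd, xt) {
  lig <- xt$internal[[xt$ligand_index]]
  ca <- chain_ca(lig)
  cen <- colMeans(ca)
  ad_addbias(ad_matmul(ad_const(sweep(ca, 2, cen)), ad_transpose(fwd$R_hat)),
             ad_transpose(fwd$c_hat))
}

# Clamped cross-chain FAPE between the node-level prediction and the native
# complex; mirrors fape_like_loss() (tested for agreement).
.loss_fape_node <- function(fwd, xt, x1, clamp = 10) {
  ri <- xt$receptor_index; li <- xt$ligand_index
  rec_pred <- xt$internal[[ri]]
  fr_pred <- backbone_frames(rec_pred)
  fr_nat_rec <- backbone_frames(receptor_chain(x1))
  lig_bar <- xt$internal[[li]]
  fr_bar <- backbone_frames(lig_bar)
  fr_nat_lig <- backbone_frames(ligand_chain(x1))

  PL <- .pred_ligand_ca_node(fwd, xt)          # n_lig x 3 node
  RC <- chain_ca(rec_pred)                     # constant receptor CAs
  NR <- chain_ca(receptor_chain(x1))
  NL <- chain_ca(ligand_chain(x1))

  terms <- list(); nterm <- 0L
  # receptor frames (constant) observing the predicted ligand CAs
  for (i in which(fr_pred$valid & fr_nat_rec$valid)) {
    loc_pred <- ad_matmul(ad_addbias(PL, ad_const(-fr_pred$origins[i, ])),
                          ad_const(fr_pred$rotations[[i]]))
    tgt <- sweep(NL, 2, fr_nat_rec$origins[i, ]) %*% fr_nat_rec$rotations[[i]]
    d <- ad_pmin_const(ad_row_l2(ad_sub(loc_pred, ad_const(tgt))), clamp)
    terms[[length(terms) + 1L]] <- ad_sum_all(d)
    nterm <- nterm + nrow(NL)
  }
  # predicted ligand frames observing the (constant) receptor CAs
  cen <- colMeans(chain_ca(lig_bar))
  for (i in which(fr_bar$valid & fr_nat_lig$valid)) {
    Fi <- ad_matmul(fwd$R_hat, ad_const(fr_bar$rotations[[i]]))
    oi <- ad_slice_rows(PL, i)                  # 1 x 3 (CA of residue i)
    loc_pred <- ad_matmul(ad_sub_rowvec(ad_const(RC), oi), Fi)
    tgt <- sweep(NR, 2, fr_nat_lig$origins[i, ]) %*% fr_nat_lig$rotations[[i]]
    d <- ad_pmin_const(ad_row_l2(ad_sub(loc_pred, ad_const(tgt))), clamp)
    terms[[length(terms) + 1L]] <- ad_sum_all(d)
    nterm <- nterm + nrow(NR)
  }
  total <- terms[[1L]]
  for (k in seq_along(terms)[-1L]) total <- ad_add(total, terms[[k]])
  ad_scale(total, 1 / nterm)
}

# (1-t)^-2 weighted mean squared CA error of the prediction (ligand CAs carry
# the gradient; receptor internal coordinates are the constant input).
.loss_wmse_node <- function(fwd, xt, x1, t) {
  PL <- .pred_ligand_ca_node(fwd, xt)
  NL <- chain_ca(ligand_chain(x1))
  diff <- ad_sub(PL, ad_const(NL))
  se_lig <- ad_sum_all(ad_mul(diff, diff))
  rec_se <- sum((chain_ca(xt$internal[[xt$receptor_index]]) -
                   chain_ca(receptor_chain(x1)))^2)
  n <- length(NL) + length(chain_ca(receptor_chain(x1)))
  ad_scale(ad_add(se_lig, ad_const(rec_se)), 1 / (n * (1 - t)^2))
}

# ---- training step --------------------------------------------------------

#' One CFM training step
#'
#' Samples `t ~ U[0, 0.99)`, draws a prior state (monomer provenance by the
#' stage probabilities), interpolates to `x_t`, runs the model, computes the
#' structure loss (plus the confidence regression when in scope) and applies
#' one Adam update to the stage's trainable parameters.
#'
#' @param model Model from [init_denoiser()] (updated in place: parameters
#'   are environments).
#' @param record A training record (`x1`, `flex`).
#' @param cfg A [train_config()].
#' @param stage Stage index.
#' @param step_seed Integer seed for this step.
#' @param opt_state Environment carrying the Adam step counter `t`.
#' @param params Cached [collect_params()] result.
#' @return List: `loss`, `conf_loss`, `provenance` (per-chain draws), `t`.
#' @export
training_step <- function(model, record, cfg, stage, step_seed, opt_state,
                          params = collect_params(model), lr = cfg$lr) {
  set.seed(step_seed)
  st <- cfg$stages[[stage]]
  x1 <- record$x1
  t <- stats::runif(1, 0, 0.99)
  prior <- prior_spec(cfg$sigma_tr, record$flex, st$probs)
  x1s <- decompose(x1, x1, t = 1)
  x0 <- sample_prior(x1, prior)
  prov <- attr(x0, "flex_provenance")
  xt <- interpolate_state(x0, x1s, t)
  xt$t <- t

  ad_begin_tape()
  fwd <- model_forward(model, xt, t)
  loss_node <- switch(cfg$loss_mode,
    fape_like = .loss_fape_node(fwd, xt, x1),
    weighted_mse = .loss_wmse_node(fwd, xt, x1, t),
    mse = ad_scale(.loss_wmse_node(fwd, xt, x1, t), (1 - t)^2)
  )
  # dense deep supervision of the anchor-voting branch: every receptor
  # residue's vote for every ligand body anchor regresses onto that anchor's
  # image under the native pose. Dense per-residue targets give direct
  # credit assignment regardless of the attention weights and gate state.
  tgt <- .pose_targets(x1s, fwd$anchors)
  aux <- NULL
  for (k in 1:3) {
    nres <- nrow(fwd$votes[[k]]$val)
    vdiff <- ad_sub(fwd$votes[[k]],
                    ad_const(matrix(tgt[k, ], nres, 3, byrow = TRUE)))
    term <- ad_mean_all(ad_mul(vdiff, vdiff))
    aux <- if (is.null(aux)) term else ad_add(aux, term)
  }
  loss_node <- ad_add(loss_node, ad_scale(aux, 0.3))
  conf_loss <- NA_real_
  train_conf <- "conf" %in% st$scope && !is.null(model$params$conf)
  if (train_conf) {
    # the confidence head scores the model's own prediction: featurize and
    # six structures per step span the quality range: the model's
    # prediction, the noisy state itself (near-random at small t to
    # near-native at large t), and four rigid jitters of the bound pose
    # covering the high- and mid-quality bands where ranking matters
    jitter_pose <- function(s_tr, s_rot) {
      j <- x1s
      j$c <- j$c + stats::rnorm(3, 0, s_tr)
      j$R <- so3_exp(stats::rnorm(3, 0, s_rot)) %*% j$R
      recompose(j)
    }
    examples <- list(recompose(fwd$x1_hat), recompose(xt),
                     jitter_pose(1, 0.08), jitter_pose(2, 0.15),
                     jitter_pose(5, 0.5), jitter_pose(8, 0.8))
    closs <- NULL
    for (cx_ex in examples) {
      # stop-gradient on the trunk: the head reads the embedded pair rows
      # but trains only its own parameters
      emb <- .without_tape({
        pfeat <- assemble_features(cx_ex, t = 1,
                                   use_seq_embed = model$cfg$use_seq_embed)
        list(feat = pfeat, pair = structure_embedder(model, pfeat)$val)
      })
      conf_node <- confidence_readout(model, ad_const(emb$pair), emb$feat,
                                      cx_ex)
      target <- dockq(cx_ex, x1)$dockq
      cdiff <- ad_sub(conf_node, ad_const(target))
      term <- ad_mul(cdiff, cdiff)
      closs <- if (is.null(closs)) term else ad_add(closs, term)
    }
    closs <- ad_scale(closs, 1 / length(examples))
    conf_loss <- as.numeric(closs$val)
    loss_node <- ad_add(loss_node, ad_scale(closs, cfg$conf_loss_weight))
  }
  loss <- as.numeric(loss_node$val)
  if (!is.finite(loss)) {
    ad_end_tape()
    stop(sprintf("non-finite loss at record %s (seed %d)", record$id, step_seed))
  }
  ad_backward(loss_node)
  ad_end_tape()
  opt_state$t <- opt_state$t + 1L
  scope_nms <- .scope_names(params, st$scope)
  conf_nms <- grep("^conf/", scope_nms, value = TRUE)
  .adam_step(params, lr, opt_state$t,
             scope_names = setdiff(scope_nms, conf_nms))
  if (length(conf_nms)) {
    # the head keeps its own constant rate: it starts training mid-schedule,
    # after the trunk rate has decayed
    .adam_step(params, cfg$lr, opt_state$t, scope_names = conf_nms)
  }
  .zero_grads(params)
  list(loss = loss, conf_loss = conf_loss, provenance = prov, t = t)
}

#' Run the staged training schedule
#'
#' @param records Training records ([make_toy_records()] / [load_records()])
#'   or a manifest path.
#' @param cfg A [train_config()].
#' @param model Optional pre-initialized model (default: a fresh
#'   [init_denoiser()] seeded from `cfg$seed`).
#' @param dcfg Denoiser config for a fresh model.
#' @param verbose Print a progress line every 50 steps.
#' @return List: `model`, `history` (data.frame with stage, step, loss,
#'   conf_loss, t, and the receptor/ligand provenance draws), `checkpoints`
#'   (per-stage deep copies of the parameter values).
#' @export
run_stages <- function(records, cfg = train_config(), model = NULL,
                       dcfg = denoiser_config(), verbose = interactive()) {
  if (is.character(records)) records <- load_records(records)
  if (is.null(model)) model <- init_denoiser(dcfg, seed = cfg$seed)
  params <- collect_params(model)
  opt_state <- new.env(); opt_state$t <- 0L
  hist <- list()
  checkpoints <- vector("list", length(cfg$stages))
  total_steps <- sum(vapply(cfg$stages, function(s) s$steps, 1L))
  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[[si]]
    for (k in seq_len(st$steps)) {
      sseed <- derive_seed(cfg$seed, "stage", si, "step", k)
      set.seed(sseed)
      rec <- records[[sample.int(length(records), 1L)]]
      frac <- opt_state$t / max(1L, total_steps - 1L)
      lr_k <- cfg$lr + (cfg$lr_final - cfg$lr) * frac
      res <- training_step(model, rec, cfg, si, derive_seed(sseed, "inner"),
                           opt_state, params, lr = lr_k)
      hist[[length(hist) + 1L]] <- data.frame(
        stage = si, step = k, loss = res$loss, conf_loss = res$conf_loss,
        t = res$t, prov_receptor = res$provenance[1],
        prov_ligand = res$provenance[2])
      if (verbose && k %% 50L == 0L) {
        recent <- vapply(utils::tail(hist, 50L), function(h) h$loss, 0)
        message(sprintf("stage %d step %d  loss %.4f", si, k, mean(recent)))
      }
    }
    checkpoints[[si]] <- lapply(params, function(p) p$val)
  }
  list(model = model, history = do.call(rbind, hist),
       checkpoints = checkpoints)
}

#' Restore parameter values from a checkpoint
#' @param model Model list.
#' @param checkpoint Named list of parameter values (as stored by
#'   [run_stages()]).
#' @export
load_checkpoint <- function(model, checkpoint) {
  params <- collect_params(model)
  for (nm in names(checkpoint)) params[[nm]]$val <- checkpoint[[nm]]
  invisible(model)
}

# ---- inference ------------------------------------------------------------

#' Sample-and-rank docking of one target
#'
#' Draws `n_samples` independent prior states, integrates each over the time
#' grid, scores the final predictions with the confidence readout and ranks
#' them (ties broken by sample index).
#'
#' @param model Trained model.
#' @param reference `ComplexConformation` supplying topology and the anchored
#'   frame; its chains are also the holo fallback for the prior.
#' @param prior A [prior_spec()]; defaults to holo-only sampling from
#'   `reference` with `sigma_tr = 15`.
#' @param n_samples Number of samples (default 20).
#' @param steps Integration steps (default 10).
#' @param seed Integer seed.
#' @return List with `predictions` (list of `ComplexConformation`),
#'   `confidence` (sorted descending), `sample_index`.
#' @export
dock_complex <- function(model, reference, prior = NULL, n_samples = 20L,
                         steps = 10L, seed = 1L) {
  if (is.null(prior)) prior <- prior_spec(15, NULL)
  grid <- make_time_grid(steps)
  preds <- vector("list", n_samples)
  confs <- numeric(n_samples)
  den <- as_denoiser(model)
  for (s in seq_len(n_samples)) {
    set.seed(derive_seed(seed, "sample", s))
    res <- integrate_flow(den, reference, prior, grid)
    preds[[s]] <- res$final
    confs[s] <- if (!is.null(model$params$conf)) {
      predict_confidence(model, res$final)
    } else 0
  }
  ord <- order(-confs, seq_len(n_samples))
  list(predictions = preds[ord], confidence = confs[ord], sample_index = ord)
}
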