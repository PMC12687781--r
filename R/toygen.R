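# Synthetic toy complexes: self-avoiding chains with a composition-biased
# interface patch, rigidly docked into clash-free bound poses, plus perturbed
# unbound conformers emulating the holo / apo / predicted input distinction.

# Interface patches are drawn from a distinct residue set so that a small
# network can learn to recognize binding sites from sequence + geometry.
INTERFACE_RESIDUES <- c("W", "Y", "F", "M")
BACKGROUND_RESIDUES <- setdiff(AA1, INTERFACE_RESIDUES)

#' Specification of a toy complex
#'
#' @param receptor_length,ligand_length Residue counts (>= 8).
#' @param interface_patch_size Contiguous interface window length (residues);
#'   must not exceed either chain length.
#' @param contact_target Minimum number of inter-chain CB-CB contacts (< 8 A)
#'   required in the bound pose.
#' @param clash_floor Minimum allowed inter-chain atom distance (Angstrom).
#' @param seed Integer seed; the complex is a pure function of it.
#' @return A `ToyComplexSpec` list.
#' @export
toy_complex_spec <- function(receptor_length = 20L, ligand_length = 18L,
                             interface_patch_size = 6L, contact_target = 6L,
                             clash_floor = 2.5, seed = 1L) {
  stopifnot(receptor_length >= 8L, ligand_length >= 8L,
            interface_patch_size <= min(receptor_length, ligand_length),
            clash_floor > 0)
  structure(list(receptor_length = as.integer(receptor_length),
                 ligand_length = as.integer(ligand_length),
                 interface_patch_size = as.integer(interface_patch_size),
                 contact_target = as.integer(contact_target),
                 clash_floor = clash_floor, seed = as.integer(seed)),
            class = "ToyComplexSpec")
}

#' Specification of an unbound-conformer perturbation
#'
#' `apo_like` uses smaller displacements than `predicted_like`, mirroring the
#' typical accuracy ordering of experimentally resolved unbound structures
#' versus predicted monomers.
#'
#' @param mode `"apo_like"` or `"predicted_like"`.
#' @param backbone_noise_sigma Per-coordinate std of the smoothed backbone
#'   displacement (Angstrom).
#' @param hinge_angle_sigma Std of the single hinge rotation (radians).
#' @param smoothing_window Moving-average window (residues) for the noise.
#' @param seed Integer seed.
#' @return A `FlexPerturbSpec` list.
#' @export
flex_perturb_spec <- function(mode = c("apo_like", "predicted_like"),
                              backbone_noise_sigma = NULL,
                              hinge_angle_sigma = NULL,
                              smoothing_window = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(backbone_noise_sigma)) {
    backbone_noise_sigma <- if (mode == "apo_like") 0.65 else 1.2
  }
  if (is.null(hinge_angle_sigma)) {
    hinge_angle_sigma <- if (mode == "apo_like") 0.05 else 0.10
  }
  stopifnot(backbone_noise_sigma >= 0, hinge_angle_sigma >= 0)
  structure(list(mode = mode, backbone_noise_sigma = backbone_noise_sigma,
                 hinge_angle_sigma = hinge_angle_sigma,
                 smoothing_window = as.integer(smoothing_window),
                 seed = as.integer(seed)),
            class = "FlexPerturbSpec")
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_len(nchar(p))) else as.numeric(p)
    h <- (h * 69069 + v + 12345) %% 2147483563
  }
  as.integer(h) + 1L
}

# Ideal-geometry placement of N, C, O, CB from the local CA-trace frame.
# Frame: e1 toward the next CA, e2 the orthogonalized direction to the
# previous CA, e3 = e1 x e2.  Deterministic and rigid-equivariant.
.place_backbone <- function(ca) {
  L <- nrow(ca)
  coords <- array(0, c(L, 5L, 3L))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (i in seq_len(L)) {
    fwd <- if (i < L) ca[i + 1, ] - ca[i, ] else ca[L, ] - ca[L - 1, ]
    bwd <- if (i > 1 && i < L) {
      ca[i - 1, ] - ca[i, ]
    } else if (i == 1L) {
      ca[3, ] - ca[2, ]       # second bond: generally non-collinear with e1
    } else {
      ca[L - 2, ] - ca[L - 1, ]
    }
    e1 <- fwd / sqrt(sum(fwd^2))
    u <- bwd - sum(bwd * e1) * e1
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) {
      # collinear neighbors: pick any perpendicular deterministically
      ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * e1) * e1
      nu <- sqrt(sum(u^2))
    }
    e2 <- u / nu
    e3 <- cross3(e1, e2)
    co <- ca[i, ]
    coords[i, 2, ] <- co                                    # CA
    coords[i, 1, ] <- co + 1.46 * (-0.50 * e1 + 0.866 * e2) # N
    coords[i, 3, ] <- co + 1.52 * (0.866 * e1 - 0.50 * e2)  # C
    coords[i, 4, ] <- coords[i, 3, ] + 1.23 * (0.30 * e1 - 0.55 * e2 + 0.78 * e3) # O
    coords[i, 5, ] <- co + 1.53 * (-0.35 * e1 - 0.45 * e2 + 0.82 * e3)            # CB
  }
  coords
}

#' Generate a random toy chain
#'
#' Self-avoiding smoothed random-walk CA trace with 3.8 A virtual bonds;
#' N, C, O and CB are placed with ideal geometry from the local frame. A
#' contiguous interface window carries a distinct residue-composition bias
#' (the learnable docking signal); its indices are attached as the
#' `interface_patch` attribute.
#'
#' @param length Residue count (>= 8).
#' @param patch_size Interface window length (default `max(4, length %/% 4)`).
#' @param patch_start First residue of the window (default: drawn at random).
#' @return A `ChainStructure` with attribute `interface_patch`.
#' @export
generate_chain <- function(length, patch_size = NULL, patch_start = NULL,
                           chain_id = "A") {
  stopifnot(length >= 8L)
  if (is.null(patch_size)) patch_size <- max(4L, length %/% 4L)
  for (attempt in seq_len(60L)) {
    ca <- .try_ca_trace(length)
    if (!is.null(ca)) break
    ca <- NULL
  }
  if (is.null(ca)) stop("self-avoiding trace failed after bounded retries")
  if (is.null(patch_start)) {
    patch_start <- sample.int(length - patch_size + 1L, 1L)
  }
  patch <- patch_start:(patch_start + patch_size - 1L)
  seqv <- sample(BACKGROUND_RESIDUES, length, replace = TRUE)
  seqv[patch] <- sample(INTERFACE_RESIDUES, patch_size, replace = TRUE)
  coords <- .place_backbone(ca)
  ch <- chain_structure(chain_id, paste(seqv, collapse = ""), coords)
  attr(ch, "interface_patch") <- patch
  ch
}

# One attempt at a persistent self-avoiding CA walk (3.8 A steps, non-neighbor
# CA pairs kept > 3.2 A). Returns NULL on failure.
.try_ca_trace <- function(L, bond = 3.8, min_sep = 3.2, persistence = 0.75) {
  ca <- matrix(0, L, 3)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  for (i in 2:L) {
    placed <- FALSE
    for (try in seq_len(40L)) {
      prop <- persistence * dir + (1 - persistence) * stats::rnorm(3)
      prop <- prop / sqrt(sum(prop^2))
      cand <- ca[i - 1, ] + bond * prop
      if (i > 2) {
        d2 <- rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
        if (min(d2) < min_sep^2) next
      }
      ca[i, ] <- cand
      dir <- prop
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  ca
}

#' Patch-contact score of a candidate pose
#'
#' Counts CB contacts (< 8 A) between the two interface patches (doubled)
#' plus all inter-chain contacts (halved), minus a small mean patch-distance
#' tie-break. Used both by the bound-pose generator and by the trivial
#' nearest-biased-patch docking baseline.
#' @keywords internal
pose_patch_score <- function(rec, lig, rec_patch, lig_patch) {
  cbr_all <- .pseudo_cb(rec); cbl_all <- .pseudo_cb(lig)
  cbr <- cbr_all[rec_patch, , drop = FALSE]
  cbl <- cbl_all[lig_patch, , drop = FALSE]
  d2p <- outer(rowSums(cbr^2), rowSums(cbl^2), "+") - 2 * tcrossprod(cbr, cbl)
  d2a <- outer(rowSums(cbr_all^2), rowSums(cbl_all^2), "+") -
    2 * tcrossprod(cbr_all, cbl_all)
  # residue-registered pairing (receptor patch runs against the reversed
  # ligand patch) pins down a unique preferred orientation, so the planted
  # pose is recoverable from sequence + geometry alone
  w <- length(rec_patch)
  paired <- mean(sqrt(pmax(d2p[cbind(seq_len(w), rev(seq_len(w)))], 0)))
  2 * sum(d2p < 64) + 0.5 * sum(d2a < 64) - 2 * paired
}

# Shared rigid-pose search over Haar orientations with a translation
# line-search along the receptor patch normal. Works on flat coordinate
# matrices for speed; consumes the active RNG stream. Returns the winning
# rotation (about the ligand CA centroid) and translation, or NULL.
.pose_search <- function(rec, lig, rec_patch, lig_patch, p_rec, nrm,
                         clash_floor = 2.5, contact_target = 0L,
                         n_orient = 300L, align_floor = 0.4,
                         s_grid = seq(1, 14, by = 0.25),
                         orientations = NULL) {
  rec_atoms <- chain_atoms_flat(rec)$coords
  lig_cen <- colMeans(chain_ca(lig))
  lig_atoms0 <- sweep(chain_atoms_flat(lig)$coords, 2, lig_cen)
  lig_ca0 <- sweep(chain_ca(lig), 2, lig_cen)
  cbr_all <- .pseudo_cb(rec)
  cbr_p <- cbr_all[rec_patch, , drop = FALSE]
  cbl0 <- sweep(.pseudo_cb(lig), 2, lig_cen)
  w <- length(rec_patch)
  reg_idx <- cbind(seq_len(w), rev(seq_len(w)))
  best_score <- -Inf
  best <- NULL
  n_try <- if (is.null(orientations)) n_orient else length(orientations)
  for (o in seq_len(n_try)) {
    Q <- if (is.null(orientations)) sample_uniform_rotation() else orientations[[o]]
    ca_rot <- lig_ca0 %*% t(Q)
    v_patch <- colMeans(ca_rot[lig_patch, , drop = FALSE])
    align <- -sum((v_patch / sqrt(sum(v_patch^2))) * nrm)
    if (align < align_floor) next
    atoms_rot <- lig_atoms0 %*% t(Q)
    base <- p_rec - v_patch
    U <- sweep(atoms_rot, 2, base, "+")
    # d^2(a, u + s n) = |a - u|^2 - 2 s <a - u, n> + s^2
    A1 <- outer(rowSums(rec_atoms^2), rowSums(U^2), "+") -
      2 * tcrossprod(rec_atoms, U)
    A2 <- outer(as.vector(rec_atoms %*% nrm), as.vector(U %*% nrm), "-")
    for (s in s_grid) {
      if (min(A1 - 2 * s * A2) + s^2 < clash_floor^2) next
      cbl <- sweep(cbl0 %*% t(Q), 2, base + s * nrm, "+")
      d2a <- outer(rowSums(cbr_all^2), rowSums(cbl^2), "+") -
        2 * tcrossprod(cbr_all, cbl)
      if (sum(d2a < 64) >= contact_target) {
        d2p <- d2a[rec_patch, lig_patch, drop = FALSE]
        paired <- mean(sqrt(pmax(d2p[reg_idx], 0)))
        sc <- 2 * sum(d2p < 64) + 0.5 * sum(d2a < 64) - 2 * paired
        if (sc > best_score) {
          best_score <- sc
          best <- list(Q = Q, shift = base + s * nrm, score = sc)
        }
      }
      break   # first clash-free separation is the tightest for this rotation
    }
  }
  best
}

# CB coordinates (falling back to CA where CB is absent, e.g. glycine).
.pseudo_cb <- function(chain) {
  cb <- chain$coords[, "CB", ]
  dim(cb) <- c(chain_length(chain), 3L)
  miss <- !chain$atom_mask[, "CB"]
  if (any(miss)) cb[miss, ] <- chain_ca(chain)[miss, , drop = FALSE]
  cb
}

#' Count inter-chain CB-CB contacts below a cutoff
#' @keywords internal
cb_contacts <- function(chain_a, chain_b, cutoff = 8.0) {
  da <- .pseudo_cb(chain_a); db <- .pseudo_cb(chain_b)
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * tcrossprod(da, db)
  sum(d2 < cutoff^2)
}

# Minimum inter-chain distance over all present atoms.
.min_interchain_dist <- function(chain_a, chain_b) {
  fa <- chain_atoms_flat(chain_a)$coords
  fb <- chain_atoms_flat(chain_b)$coords
  d2 <- outer(rowSums(fa^2), rowSums(fb^2), "+") - 2 * tcrossprod(fa, fb)
  sqrt(max(min(d2), 0))
}

#' Generate a bound toy complex
#'
#' Builds receptor and ligand chains, then rigidly poses the ligand so the two
#' interface patches face each other, at least `contact_target` CB-CB contacts
#' (< 8 A) form, and no inter-chain atom pair is closer than `clash_floor`.
#' The pose is found by a seeded orientation search plus a translation
#' line-search along the receptor patch normal, and is a deterministic
#' function of the seed.
#'
#' @param spec A [toy_complex_spec()].
#' @return A `ComplexConformation` (chains "R" and "L") with per-chain
#'   `interface_patch` attributes.
#' @export
generate_bound_complex <- function(spec) {
  set.seed(spec$seed)
  rec <- generate_chain(spec$receptor_length, spec$interface_patch_size,
                        chain_id = "R")
  lig <- generate_chain(spec$ligand_length, spec$interface_patch_size,
                        chain_id = "L")
  rec_patch <- attr(rec, "interface_patch")
  lig_patch <- attr(lig, "interface_patch")

  rec_ca <- chain_ca(rec)
  rec_cen <- colMeans(rec_ca)
  p_rec <- colMeans(rec_ca[rec_patch, , drop = FALSE])
  nrm <- p_rec - rec_cen
  nrm <- nrm / sqrt(sum(nrm^2))

  lig_ca <- chain_ca(lig)
  lig_cen <- colMeans(lig_ca)

  # orientation search: among clash-free patch-facing placements, keep the
  # pose with the best patch-contact score (deterministic given the seed);
  # this makes the planted interface signal as clean as the patch geometry
  # allows
  sr <- .pose_search(rec, lig, rec_patch, lig_patch, p_rec, nrm,
                     clash_floor = spec$clash_floor,
                     contact_target = spec$contact_target,
                     n_orient = 300L, align_floor = 0.4)
  if (is.null(sr)) {
    stop(sprintf("no clash-free bound pose found (seed %d)", spec$seed))
  }
  best <- map_chain_coords(lig, function(p) {
    t(sr$Q %*% t(sweep(p, 2, lig_cen))) +
      matrix(sr$shift, nrow(p), 3, byrow = TRUE)
  })
  attr(best, "interface_patch") <- lig_patch
  cx <- complex_conformation(list(rec, best), 1L, 2L, "holo")
  attr(cx, "interface_patches") <- list(R = rec_patch, L = lig_patch)
  cx
}

#' Dock two toy chains with the trivial nearest-biased-patch baseline
#'
#' Identifies the interface patches from sequence alone (the biased residue
#' set), then searches rigid ligand placements that face the two patches and
#' maximize the same patch-contact score the generator optimizes, with a
#' short annealed local refinement. No learned model is involved: this
#' baseline establishes that the planted docking signal is recoverable from
#' sequence plus geometry, i.e. that the dataset is learnable.
#'
#' @param cx A `ComplexConformation` supplying the two chains (the ligand's
#'   pose in `cx` is ignored).
#' @param seed Integer seed for the orientation search.
#' @param n_orient Number of Haar-random trial orientations.
#' @param n_refine Annealed local refinement steps.
#' @return A `ComplexConformation` with the baseline ligand pose.
#' @export
baseline_dock <- function(cx, seed = 1L, n_orient = 400L, n_refine = 120L) {
  rec <- receptor_chain(cx); lig <- ligand_chain(cx)
  seq_r <- strsplit(rec$sequence, "")[[1]]
  seq_l <- strsplit(lig$sequence, "")[[1]]
  pr <- which(seq_r %in% INTERFACE_RESIDUES)
  pl <- which(seq_l %in% INTERFACE_RESIDUES)
  if (!length(pr) || !length(pl)) stop("no biased interface residues found")
  rec_ca <- chain_ca(rec)
  p_rec <- colMeans(rec_ca[pr, , drop = FALSE])
  nrm <- p_rec - colMeans(rec_ca)
  nrm <- nrm / sqrt(sum(nrm^2))
  set.seed(seed)
  sr <- .pose_search(rec, lig, pr, pl, p_rec, nrm, n_orient = n_orient,
                     align_floor = 0.3)
  if (is.null(sr)) stop("baseline found no clash-free pose")
  # annealed local refinement of the orientation (coarse-to-fine rounds)
  per_round <- max(1L, n_refine %/% 3L)
  for (sg in c(0.18, 0.08, 0.04)) {
    perturbed <- lapply(seq_len(per_round), function(i) {
      so3_exp(stats::rnorm(3, 0, sg)) %*% sr$Q
    })
    sr2 <- .pose_search(rec, lig, pr, pl, p_rec, nrm, align_floor = -1,
                        orientations = perturbed)
    if (!is.null(sr2) && sr2$score > sr$score) sr <- sr2
  }
  lig_cen <- colMeans(chain_ca(lig))
  posed <- map_chain_coords(lig, function(p) {
    t(sr$Q %*% t(sweep(p, 2, lig_cen))) +
      matrix(sr$shift, nrow(p), 3, byrow = TRUE)
  })
  complex_conformation(list(rec, posed), 1L, 2L, "sampled")
}

#' Perturb a chain into an unbound-like conformer
#'
#' Applies a smoothed correlated Gaussian displacement to the CA trace plus a
#' single hinge rotation about a random interior residue, then re-idealizes
#' the backbone (bond lengths restored, N/C/O/CB rebuilt from the local
#' frame). Sequence and length are preserved. With both sigmas zero the chain
#' is returned bit-identical.
#'
#' @param chain A `ChainStructure` whose non-CA atoms follow the generator's
#'   ideal local geometry.
#' @param spec A [flex_perturb_spec()].
#' @return A perturbed `ChainStructure`.
#' @export
perturb_unbound <- function(chain, spec) {
  if (spec$backbone_noise_sigma == 0 && spec$hinge_angle_sigma == 0) {
    return(chain)
  }
  set.seed(spec$seed)
  L <- chain_length(chain)
  ca <- chain_ca(chain)
  bonds <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))

  # smoothed noise, rescaled so the post-smoothing per-coordinate std equals
  # backbone_noise_sigma
  w <- spec$smoothing_window
  noise <- matrix(stats::rnorm(L * 3), L, 3)
  if (w > 1L) {
    k <- rep(1 / w, w)
    sm <- apply(noise, 2, function(col) {
      as.vector(stats::filter(col, k, sides = 2, circular = FALSE))
    })
    sm[is.na(sm)] <- noise[is.na(sm)] * sqrt(sum(k^2))
    noise <- sm / sqrt(sum(k^2))
  }
  ca2 <- ca + spec$backbone_noise_sigma * noise

  # one hinge rotation about an interior residue
  if (spec$hinge_angle_sigma > 0 && L >= 6L) {
    hinge <- sample(seq(max(2L, L %/% 4L), min(L - 1L, (3L * L) %/% 4L)), 1L)
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- stats::rnorm(1, 0, spec$hinge_angle_sigma)
    Rh <- so3_exp(ang * axis)
    pivot <- ca2[hinge, ]
    down <- (hinge + 1L):L
    ca2[down, ] <- t(Rh %*% t(sweep(ca2[down, , drop = FALSE], 2, pivot))) +
      matrix(pivot, length(down), 3, byrow = TRUE)
  }

  # re-idealize: restore the original bond lengths along the walk
  ca3 <- ca2
  for (i in 2:L) {
    d <- ca2[i, ] - ca2[i - 1, ]
    d <- d / sqrt(sum(d^2))
    ca3[i, ] <- ca3[i - 1, ] + bonds[i - 1] * d
  }
  coords <- .place_backbone(ca3)
  out <- chain_structure(chain$chain_id, chain$sequence, coords,
                         bfactor = chain$bfactor)
  attr(out, "interface_patch") <- attr(chain, "interface_patch")
  out
}

#' Build a synthetic docking dataset on disk
#'
#' For each complex: a bound PDB, per-chain holo / apo-like / predicted-like
#' monomer PDBs, and a JSON-lines manifest record. The dataset is a pure
#' function of `seed`. Individual failures are skipped with a warning; more
#' than 10 percent failures is an error.
#'
#' @param n_complexes Number of complexes.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param length_range Chain lengths drawn uniformly from this range.
#' @param interface_patch_size,contact_target,clash_floor Passed to
#'   [toy_complex_spec()].
#' @return Path to the manifest file (`manifest.jsonl`), invisibly a character
#'   scalar.
#' @export
build_dataset <- function(n_complexes, out_dir, seed = 1L,
                          length_range = c(16L, 24L),
                          interface_patch_size = 6L, contact_target = 6L,
                          clash_floor = 2.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  records <- character(0)
  n_fail <- 0L
  for (i in seq_len(n_complexes)) {
    cseed <- derive_seed(seed, "complex", i)
    set.seed(cseed)
    lens <- sample(length_range[1]:length_range[2], 2L, replace = TRUE)
    spec <- toy_complex_spec(lens[1], lens[2], interface_patch_size,
                             contact_target, clash_floor, seed = cseed)
    cx <- tryCatch(generate_bound_complex(spec), error = function(e) NULL)
    if (is.null(cx)) {
      n_fail <- n_fail + 1L
      warning(sprintf("complex %d failed to generate; skipped", i))
      next
    }
    id <- sprintf("cx%04d", i)
    bound_path <- file.path(out_dir, paste0(id, "_bound.pdb"))
    write_pdb(cx, bound_path)
    monomers <- list()
    for (ci in seq_along(cx$chains)) {
      ch <- cx$chains[[ci]]
      cid <- ch$chain_id
      paths <- list()
      holo_path <- file.path(out_dir, sprintf("%s_%s_holo.pdb", id, cid))
      .write_monomer_pdb(ch, holo_path)
      paths$holo <- basename(holo_path)
      for (mode in c("apo_like", "predicted_like")) {
        ps <- flex_perturb_spec(mode, seed = derive_seed(cseed, mode, ci))
        pert <- perturb_unbound(ch, ps)
        p <- file.path(out_dir, sprintf("%s_%s_%s.pdb", id, cid, mode))
        .write_monomer_pdb(pert, p)
        paths[[mode]] <- basename(p)
      }
      monomers[[cid]] <- paths
    }
    patches <- attr(cx, "interface_patches")
    rec <- list(id = id, seed = cseed, bound = basename(bound_path),
                receptor = receptor_chain(cx)$chain_id,
                ligand = ligand_chain(cx)$chain_id,
                lengths = vapply(cx$chains, chain_length, 1L),
                interface_patches = patches, monomers = monomers)
    records <- c(records, jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  if (n_fail > 0.1 * n_complexes) {
    stop(sprintf("%d of %d complexes failed to generate", n_fail, n_complexes))
  }
  writeLines(records, manifest_path)
  manifest_path
}

# Write a single chain as a 1-chain PDB (structio::write_pdb requires 2+
# chains for role assignment, so monomers are written directly).
.write_monomer_pdb <- function(chain, path) {
  out <- character(0)
  serial <- 1L
  ch <- chain
  L <- chain_length(ch)
  seqv <- strsplit(ch$sequence, "")[[1]]
  for (ri in seq_len(L)) {
    for (ai in seq_len(5L)) {
      if (!ch$atom_mask[ri, ai]) next
      xyz <- ch$coords[ri, ai, ]
      out <- c(out, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, BACKBONE_ATOMS[ai], AA3[[seqv[ri]]], ch$chain_id, ri,
        xyz[1], xyz[2], xyz[3], 1.00, ch$bfactor[ri]))
      serial <- serial + 1L
    }
  }
  out <- c(out, sprintf("TER   %5d      %3s %s%4d", serial,
                        AA3[[seqv[L]]], ch$chain_id, L), "END")
  writeLines(out, path)
  invisible(path)
}

#' Read a single-chain monomer PDB
#' @param path PDB file with exactly one chain.
#' @return A `ChainStructure`.
#' @export
read_monomer_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atom)) stop("no ATOM records in ", path)
  name <- trimws(substr(atom, 13, 16))
  resn <- trimws(substr(atom, 18, 20))
  cid <- unique(substr(atom, 22, 22))
  if (length(cid) != 1L) stop("expected a single chain in ", path)
  resno <- as.integer(substr(atom, 23, 26))
  xyz <- cbind(as.numeric(substr(atom, 31, 38)),
               as.numeric(substr(atom, 39, 46)),
               as.numeric(substr(atom, 47, 54)))
  b <- suppressWarnings(as.numeric(substr(atom, 61, 66)))
  b[is.na(b)] <- 0
  keep <- name %in% BACKBONE_ATOMS
  name <- name[keep]; resn <- resn[keep]; resno <- resno[keep]
  xyz <- xyz[keep, , drop = FALSE]; b <- b[keep]
  resnos <- unique(resno)
  L <- length(resnos)
  coords <- array(0, c(L, 5L, 3L))
  mask <- matrix(FALSE, L, 5L)
  seqv <- character(L)
  bfac <- numeric(L)
  for (ri in seq_len(L)) {
    sel <- which(resno == resnos[ri])
    seqv[ri] <- AA1_FROM_3[[resn[sel[1]]]]
    for (k in sel) {
      ai <- match(name[k], BACKBONE_ATOMS)
      coords[ri, ai, ] <- xyz[k, ]
      mask[ri, ai] <- TRUE
    }
    bfac[ri] <- b[sel[name[sel] == "CA"][1]]
  }
  chain_structure(cid, paste(seqv, collapse = ""), coords, mask, bfac)
}
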