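# Template-style pair featurization of a (noisy) complex: CB distogram,
# local-frame unit vectors, masks, residue-pair identities, clipped relative
# positions, and Fourier time conditioning. All geometric features are
# invariant to global rigid transforms; inter-chain entries are computed, not
# masked.

#' Default distogram bin edges (AF-template convention)
#'
#' 38 bins spanning 3.25 to 50.75 Angstrom; distances below the first edge
#' fall in the first bin, above the last edge in the last bin.
#' @export
default_distogram_edges <- function() seq(3.25, 50.75, length.out = 39L)

REL_POS_CLIP <- 32L
TIME_FOURIER_K <- 8L   # 8 sin + 8 cos channels

#' One-hot CB distogram
#'
#' @param cb n x 3 matrix of CB positions (pseudo-CB allowed).
#' @param mask Logical vector: which residues have a CB.
#' @param edges Strictly increasing bin edges (Angstrom); `B = length(edges) - 1`
#'   bins with underflow into the first and overflow into the last bin.
#' @return `n x n x B` one-hot array; masked pairs are all-zero; the diagonal
#'   (distance 0) falls in the first bin.
#' @export
distogram <- function(cb, mask = rep(TRUE, nrow(cb)),
                      edges = default_distogram_edges()) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  n <- nrow(cb)
  B <- length(edges) - 1L
  d <- sqrt(pmax(outer(rowSums(cb^2), rowSums(cb^2), "+") -
                   2 * tcrossprod(cb), 0))
  bin <- matrix(findInterval(d, edges), n, n)
  bin[bin < 1L] <- 1L
  bin[bin > B] <- B
  out <- array(0, c(n, n, B))
  pm <- outer(mask, mask, "&")
  idx <- which(pm)
  out[cbind(arrayInd(idx, c(n, n)), bin[idx])] <- 1
  out
}

#' Local-frame inter-residue unit vectors
#'
#' Entry (i, j) is the unit displacement from residue i's CA to residue j's
#' CA expressed in residue i's backbone frame; invariant to global rigid
#' transforms because the frame rotation cancels them.
#'
#' @param frames A [backbone_frames()] result.
#' @param ca n x 3 CA coordinates.
#' @return List with `vectors` (`n x n x 3`) and `mask` (`n x n` logical;
#'   FALSE on the diagonal, for invalid frames, and for coincident CAs).
#' @export
unit_vectors <- function(frames, ca) {
  n <- nrow(ca)
  vec <- array(0, c(n, n, 3))
  mask <- matrix(FALSE, n, n)
  for (i in which(frames$valid)) {
    disp <- sweep(ca, 2, ca[i, ])
    nn <- sqrt(rowSums(disp^2))
    ok <- nn > 1e-6
    ok[i] <- FALSE
    loc <- (disp / pmax(nn, 1e-12)) %*% frames$rotations[[i]]
    vec[i, ok, ] <- loc[ok, , drop = FALSE]
    mask[i, ok] <- TRUE
  }
  list(vectors = vec, mask = mask)
}

#' Fourier time embedding
#' @param t Scalar in `[0, 1]`.
#' @return Numeric vector of length `2 * TIME_FOURIER_K`.
#' @export
time_embedding <- function(t) {
  k <- seq_len(TIME_FOURIER_K)
  c(sin(2 * pi * k * t), cos(2 * pi * k * t))
}

#' Number of channels in the positional pair features
#' @keywords internal
n_pair_feature_channels <- function() {
  B <- length(default_distogram_edges()) - 1L
  # distogram + cb/frame masks + unit vectors + residue pair one-hot +
  # rel-position one-hot + same-chain flag
  B + 2L + 3L + 2L * length(AA1) + (2L * REL_POS_CLIP + 1L) + 1L
}

#' Assemble pair features for a complex
#'
#' Builds the template-style positional features of the (possibly noisy)
#' complex. Inter-chain distogram and unit-vector entries are computed — no
#' inter-chain masking. The conditioning set is the same features plus the
#' Fourier time embedding broadcast over all pairs.
#'
#' @param x A `ComplexConformation` or `DecomposedState` (recomposed
#'   internally).
#' @param t Path time for the conditioning features.
#' @param use_seq_embed If FALSE the residue-identity channels are zeroed
#'   (shapes unchanged) — the structure-only ablation.
#' @return List with `noisy` (`L^2 x C` matrix, column-major pair flattening),
#'   `cond` (`L^2 x (C + 2 * TIME_FOURIER_K)`), `L`, `chain_of` (integer
#'   vector), and `chain_lengths`.
#' @export
assemble_features <- function(x, t = 0, use_seq_embed = TRUE) {
  if (inherits(x, "DecomposedState")) x <- recompose(x)
  lens <- vapply(x$chains, chain_length, 1L)
  L <- sum(lens)
  chain_of <- rep(seq_along(x$chains), lens)
  pos_in_chain <- unlist(lapply(lens, seq_len))

  ca <- do.call(rbind, lapply(x$chains, chain_ca))
  cb <- do.call(rbind, lapply(x$chains, .pseudo_cb))
  cb_mask <- unlist(lapply(x$chains, function(ch) ch$atom_mask[, "CB"]))
  seq_all <- unlist(lapply(x$chains, function(ch) strsplit(ch$sequence, "")[[1]]))

  frames <- list(rotations = vector("list", L), origins = matrix(0, L, 3),
                 valid = logical(L))
  off <- 0L
  for (ch in x$chains) {
    fr <- backbone_frames(ch)
    n <- chain_length(ch)
    frames$rotations[off + seq_len(n)] <- fr$rotations
    frames$origins[off + seq_len(n), ] <- fr$origins
    frames$valid[off + seq_len(n)] <- fr$valid
    off <- off + n
  }

  B <- length(default_distogram_edges()) - 1L
  dg <- distogram(cb, cb_mask)
  uv <- unit_vectors(frames, ca)

  n_ch <- n_pair_feature_channels()
  feat <- matrix(0, L * L, n_ch)
  col <- 0L
  feat[, col + seq_len(B)] <- matrix(dg, L * L, B)
  col <- col + B
  feat[, col + 1L] <- as.vector(outer(cb_mask, cb_mask, "&")) * 1
  feat[, col + 2L] <- as.vector(outer(frames$valid, frames$valid, "&")) * 1
  col <- col + 2L
  feat[, col + seq_len(3L)] <- matrix(uv$vectors, L * L, 3L)
  col <- col + 3L
  aa_idx <- match(seq_all, AA1)
  if (use_seq_embed) {
    row_i <- rep(seq_len(L), times = L)   # i index of pair (i, j)
    col_j <- rep(seq_len(L), each = L)
    feat[cbind(seq_len(L * L), col + aa_idx[row_i])] <- 1
    feat[cbind(seq_len(L * L), col + 20L + aa_idx[col_j])] <- 1
  }
  col <- col + 40L
  # clipped signed offset within chain, one-hot; zero across chains
  row_i <- rep(seq_len(L), times = L)
  col_j <- rep(seq_len(L), each = L)
  same <- chain_of[row_i] == chain_of[col_j]
  offs <- pos_in_chain[col_j] - pos_in_chain[row_i]
  offs <- pmax(pmin(offs, REL_POS_CLIP), -REL_POS_CLIP)
  sel <- which(same)
  feat[cbind(sel, col + offs[sel] + REL_POS_CLIP + 1L)] <- 1
  col <- col + 2L * REL_POS_CLIP + 1L
  feat[, col + 1L] <- same * 1

  te <- time_embedding(t)
  cond <- cbind(feat, matrix(te, L * L, length(te), byrow = TRUE))
  list(noisy = feat, cond = cond, L = L, chain_of = chain_of,
       chain_lengths = lens)
}
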