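# Docking-quality metrics and benchmark statistics: native contacts, fnat,
# interface/ligand RMSD, DockQ with quality classes, per-subunit interface
# RMSD, bootstrapped top-k / oracle success rates, and the paired one-sided
# Wilcoxon test.
#
# Contacts use all represented atoms (N, CA, C, O, CB) since the toy data
# model carries no sidechains; the DockQ constants (5 A contacts, 10 A
# interface, 1.5 / 8.5 A scaling) are unchanged.

DOCKQ_THRESHOLDS <- c(acceptable = 0.23, medium = 0.49, high = 0.80)

# Backbone (N, CA, C, O) coordinates of selected residues, stacked.
.backbone_coords <- function(chain, residues = seq_len(chain_length(chain))) {
  keep <- c("N", "CA", "C", "O")
  out <- NULL
  for (ri in residues) {
    pres <- keep[chain$atom_mask[ri, keep]]
    out <- rbind(out, chain$coords[ri, pres, , drop = TRUE])
  }
  out
}

# n_a x n_b matrix of minimal inter-residue atom distances.
.residue_min_dist <- function(chain_a, chain_b) {
  fa <- chain_atoms_flat(chain_a); fb <- chain_atoms_flat(chain_b)
  d2 <- outer(rowSums(fa$coords^2), rowSums(fb$coords^2), "+") -
    2 * tcrossprod(fa$coords, fb$coords)
  d2 <- pmax(d2, 0)
  La <- chain_length(chain_a); Lb <- chain_length(chain_b)
  out <- matrix(Inf, La, Lb)
  for (ia in seq_len(La)) {
    rows <- which(fa$residue == ia)
    sub <- d2[rows, , drop = FALSE]
    mins <- tapply(apply(sub, 2, min), fb$residue, min)
    out[ia, as.integer(names(mins))] <- sqrt(mins)
  }
  out
}

#' Native inter-chain residue contacts
#'
#' Residue pairs (receptor i, ligand j) with any represented-atom distance
#' below `cutoff`.
#'
#' @param native A `ComplexConformation`.
#' @param cutoff Contact distance (Angstrom, default 5).
#' @return Two-column integer matrix (receptor residue, ligand residue).
#'   Errors if the structure has no contacts (not a complex).
#' @export
native_contacts <- function(native, cutoff = 5.0) {
  d <- .residue_min_dist(receptor_chain(native), ligand_chain(native))
  idx <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(idx)) stop("no inter-chain contacts: structure is not a complex")
  colnames(idx) <- c("receptor", "ligand")
  idx
}

# Interface residues under the 10 A any-atom rule, per chain.
.interface_residues <- function(native, cutoff = 10.0) {
  d <- .residue_min_dist(receptor_chain(native), ligand_chain(native))
  list(receptor = which(apply(d, 1, min) < cutoff),
       ligand = which(apply(d, 2, min) < cutoff))
}

#' DockQ score of a model complex against its native structure
#'
#' fnat is the fraction of native contacts (5 A, represented atoms) present
#' in the model; iRMSD is the backbone RMSD over native interface residues
#' (10 A rule) after superposition on those residues; LRMSD is the ligand
#' backbone RMSD after superposition on the receptor backbone. The combined
#' score is `(fnat + 1/(1+(irmsd/1.5)^2) + 1/(1+(lrmsd/8.5)^2)) / 3` with
#' strict quality thresholds: acceptable > 0.23, medium > 0.49, high > 0.80.
#'
#' @param model,native `ComplexConformation`s with identical chain topology.
#' @return A `DockQResult` list: `fnat`, `irmsd`, `lrmsd`, `dockq`,
#'   `quality`.
#' @export
dockq <- function(model, native) {
  if (length(model$chains) != length(native$chains) ||
      any(vapply(model$chains, chain_length, 1L) !=
            vapply(native$chains, chain_length, 1L))) {
    stop("model/native chain topology mismatch")
  }
  ncon <- native_contacts(native)
  dmod <- .residue_min_dist(receptor_chain(model), ligand_chain(model))
  fnat <- mean(dmod[ncon] < 5.0)

  ifr <- .interface_residues(native)
  mob <- rbind(.backbone_coords(receptor_chain(model), ifr$receptor),
               .backbone_coords(ligand_chain(model), ifr$ligand))
  ref <- rbind(.backbone_coords(receptor_chain(native), ifr$receptor),
               .backbone_coords(ligand_chain(native), ifr$ligand))
  irmsd <- kabsch_align(mob, ref)$rmsd

  tf <- kabsch_align(.backbone_coords(receptor_chain(model)),
                     .backbone_coords(receptor_chain(native)))
  lig_aligned <- apply_transform(.backbone_coords(ligand_chain(model)), tf)
  lig_ref <- .backbone_coords(ligand_chain(native))
  lrmsd <- sqrt(mean(rowSums((lig_aligned - lig_ref)^2)))

  dockq_from_components(fnat, irmsd, lrmsd)
}

#' Combine fnat / iRMSD / LRMSD into a DockQ score and quality class
#' @param fnat Fraction of native contacts in `[0, 1]`.
#' @param irmsd,lrmsd Interface and ligand RMSD (Angstrom).
#' @return A `DockQResult` list.
#' @export
dockq_from_components <- function(fnat, irmsd, lrmsd) {
  score <- (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
  structure(list(fnat = fnat, irmsd = irmsd, lrmsd = lrmsd, dockq = score,
                 quality = dockq_quality(score)),
            class = "DockQResult")
}

#' Quality class of a DockQ score (strict thresholds)
#'
#' `acceptable > 0.23`, `medium > 0.49`, `high > 0.80`; a score exactly at a
#' threshold falls in the lower class.
#' @param score DockQ score in `[0, 1]`.
#' @return One of `"incorrect"`, `"acceptable"`, `"medium"`, `"high"`.
#' @export
dockq_quality <- function(score) {
  if (score > DOCKQ_THRESHOLDS[["high"]]) "high"
  else if (score > DOCKQ_THRESHOLDS[["medium"]]) "medium"
  else if (score > DOCKQ_THRESHOLDS[["acceptable"]]) "acceptable"
  else "incorrect"
}

#' Per-subunit interface RMSD
#'
#' Isolates internal deformation from rigid-body motion: for each subunit,
#' structure `a` is superposed onto structure `b` on that subunit alone, then
#' the backbone RMSD is measured over the native-interface residues of that
#' subunit. Pure rigid motion of a subunit therefore contributes zero.
#'
#' @param a,b `ComplexConformation`s to compare.
#' @param native Structure defining the interface residues (10 A rule).
#' @param align `"all"` (default) superposes on all backbone atoms of the
#'   subunit; `"interface"` superposes on the interface backbone only.
#' @return Named numeric vector `c(receptor = ..., ligand = ...)` (Angstrom).
#' @export
ps_irmsd <- function(a, b, native, align = c("all", "interface")) {
  align <- match.arg(align)
  ifr <- .interface_residues(native)
  if (!length(ifr$receptor) || !length(ifr$ligand)) stop("empty interface")
  one <- function(get_chain, iface) {
    ca_a <- .backbone_coords(get_chain(a))
    ca_b <- .backbone_coords(get_chain(b))
    n_at <- sum(get_chain(a)$atom_mask[, c("N", "CA", "C", "O")])
    sel_rows <- .backbone_rows(get_chain(a), iface)
    if (align == "all") {
      tf <- kabsch_align(ca_a, ca_b)
    } else {
      tf <- kabsch_align(ca_a[sel_rows, , drop = FALSE],
                         ca_b[sel_rows, , drop = FALSE])
    }
    al <- apply_transform(ca_a, tf)
    sqrt(mean(rowSums((al[sel_rows, , drop = FALSE] -
                         ca_b[sel_rows, , drop = FALSE])^2)))
  }
  c(receptor = one(receptor_chain, ifr$receptor),
    ligand = one(ligand_chain, ifr$ligand))
}

# Row indices of the given residues inside the stacked backbone coordinates.
.backbone_rows <- function(chain, residues) {
  keep <- c("N", "CA", "C", "O")
  counts <- rowSums(chain$atom_mask[, keep, drop = FALSE])
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  unlist(lapply(residues, function(ri) seq(starts[ri], ends[ri])))
}

#' Build a ranked prediction set for one target
#'
#' @param id Target identifier.
#' @param predictions List of `ComplexConformation`s.
#' @param confidences Numeric confidence scores (same length).
#' @param native Ground-truth complex; DockQ is computed per prediction.
#' @return A `PredictionSet`: predictions sorted by confidence (descending,
#'   ties broken by original index), with `dockq` per prediction.
#' @export
prediction_set <- function(id, predictions, confidences, native) {
  stopifnot(length(predictions) == length(confidences),
            length(predictions) >= 1L)
  ord <- order(-confidences, seq_along(confidences))
  dq <- vapply(predictions[ord], function(p) dockq(p, native)$dockq, 0)
  structure(list(id = id, predictions = predictions[ord],
                 confidence = confidences[ord], dockq = dq),
            class = "PredictionSet")
}

# Percentile bootstrap CI of the mean of per-target values.
.boot_ci <- function(values, n_boot = 10000L, level = 0.95) {
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  stat <- rowMeans(matrix(values[idx], n_boot, n))
  a <- (1 - level) / 2
  stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
}

#' Top-k and oracle success rates with bootstrap confidence intervals
#'
#' A target is a success at rank k if the best DockQ among its top-k ranked
#' predictions exceeds `threshold`; the oracle uses all predictions. CIs are
#' percentile bootstrap over targets (default 10,000 resamples at 95%).
#'
#' @param sets List of `PredictionSet`s.
#' @param ks Ranks to evaluate (default 1 and 5).
#' @param threshold DockQ class threshold (default acceptable, 0.23).
#' @param n_boot,level Bootstrap resamples and confidence level.
#' @return List keyed `top1`, `top5`, ..., `oracle`; each entry has `rate`
#'   and `ci` (length-2 vector).
#' @export
success_rates <- function(sets, ks = c(1L, 5L), threshold = 0.23,
                          n_boot = 10000L, level = 0.95) {
  stopifnot(length(sets) >= 1L)
  sizes <- vapply(sets, function(s) length(s$dockq), 1L)
  out <- list()
  for (k in ks) {
    kk <- pmin(k, sizes)
    if (any(kk < k)) warning(sprintf("k=%d clamped to set size for some targets", k))
    succ <- mapply(function(s, m) max(s$dockq[seq_len(m)]) > threshold,
                   sets, kk)
    out[[paste0("top", k)]] <- list(rate = mean(succ),
                                    ci = .boot_ci(succ, n_boot, level))
  }
  succ <- vapply(sets, function(s) max(s$dockq) > threshold, TRUE)
  out$oracle <- list(rate = mean(succ), ci = .boot_ci(succ, n_boot, level))
  out
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' Tests whether `x` is stochastically smaller than `y` (alternative: the
#' median of `x - y` is negative). Zero differences are dropped (standard
#' signed-rank convention); if all differences are zero the p-value is 1 with
#' a warning.
#'
#' @param x,y Paired numeric vectors, length >= 5.
#' @return One-sided p-value.
#' @export
paired_one_sided_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(x[nz], y[nz], paired = TRUE,
                       alternative = "less")$p.value
  )
}

#' @export
print.DockQResult <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s): fnat %.3f, iRMSD %.2f A, LRMSD %.2f A\n",
              x$dockq, x$quality, x$fnat, x$irmsd, x$lrmsd))
  invisible(x)
}
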