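# Backbone-plus-CB data model and fixed-column PDB I/O.

#' Atom names carried by the data model
#' @export
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

# 20 standard amino acids, one-letter and three-letter codes.
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
names(AA3) <- AA1
AA1_FROM_3 <- stats::setNames(AA1, AA3)

#' Construct a ChainStructure
#'
#' One polymer chain: residue identities plus per-residue backbone and CB
#' coordinates (Angstrom). CB may be absent (glycine); the atom mask records
#' which atoms are present.
#'
#' @param chain_id Single character chain identifier.
#' @param sequence One-letter amino-acid string.
#' @param coords Numeric array `L x 5 x 3` with second dimension named
#'   `c("N","CA","C","O","CB")`.
#' @param atom_mask Logical `L x 5` matrix (same atom order); defaults to all
#'   atoms present except CB at glycines.
#' @param bfactor Optional per-residue numeric scalar annotation (written to
#'   the B-factor column of PDB output).
#' @return An object of class `ChainStructure`.
#' @export
chain_structure <- function(chain_id, sequence, coords, atom_mask = NULL,
                            bfactor = NULL) {
  stopifnot(nchar(chain_id) == 1L)
  L <- nchar(sequence)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[1] == L,
            dim(coords)[2] == 5L, dim(coords)[3] == 3L)
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  seq_vec <- strsplit(sequence, "")[[1]]
  if (!all(seq_vec %in% AA1)) stop("sequence contains non-standard residues")
  if (is.null(atom_mask)) {
    atom_mask <- matrix(TRUE, L, 5L, dimnames = list(NULL, BACKBONE_ATOMS))
    atom_mask[seq_vec == "G", "CB"] <- FALSE
  }
  dimnames(atom_mask) <- list(NULL, BACKBONE_ATOMS)
  if (!all(atom_mask[, "CA"])) stop("every residue must have a CA atom")
  # canonical form: absent atoms carry zero coordinates
  for (ai in seq_len(5L)) {
    miss <- !atom_mask[, ai]
    if (any(miss)) coords[miss, ai, ] <- 0
  }
  if (is.null(bfactor)) bfactor <- rep(0, L)
  x <- structure(list(chain_id = chain_id, sequence = sequence,
                      coords = coords, atom_mask = atom_mask,
                      bfactor = bfactor),
                 class = "ChainStructure")
  validate_chain(x)
  x
}

#' Validate ChainStructure invariants
#'
#' Checks sequence/coordinate agreement and the CA-CA virtual-bond sanity
#' range (2.0 to 5.0 Angstrom between consecutive present residues).
#' @param chain A `ChainStructure`.
#' @return The chain, invisibly; errors on violation.
#' @export
validate_chain <- function(chain) {
  L <- nchar(chain$sequence)
  if (dim(chain$coords)[1] != L) stop("sequence length != coordinate records")
  ca <- chain$coords[, "CA", , drop = FALSE]
  if (L >= 2L) {
    d <- sqrt(rowSums((ca[-1, 1, , drop = FALSE] - ca[-L, 1, , drop = FALSE])^2))
    bad <- which(d < 2.0 | d > 5.0)
    if (length(bad)) {
      stop(sprintf("CA-CA virtual bond out of [2,5] A at residue %d (%.2f A)",
                   bad[1], d[bad[1]]))
    }
  }
  invisible(chain)
}

#' @export
chain_length <- function(chain) nchar(chain$sequence)

#' CA coordinates of a chain as an L x 3 matrix
#' @param chain A `ChainStructure`.
#' @export
chain_ca <- function(chain) {
  m <- chain$coords[, "CA", , drop = FALSE]
  dim(m) <- c(dim(m)[1], 3L)
  m
}

#' All present atoms of a chain as an n x 3 matrix (with residue index map)
#' @keywords internal
chain_atoms_flat <- function(chain) {
  L <- chain_length(chain)
  keep <- which(t(chain$atom_mask))  # column-major over (atom, residue)
  res <- rep(seq_len(L), each = 5L)[keep]
  atom <- rep(BACKBONE_ATOMS, L)[keep]
  mat <- matrix(aperm(chain$coords, c(2, 1, 3)), L * 5L, 3L)[keep, , drop = FALSE]
  list(coords = mat, residue = res, atom = atom)
}

# Apply f (n x 3 -> n x 3) to every present atom of the chain.
map_chain_coords <- function(chain, f) {
  L <- chain_length(chain)
  flat <- matrix(aperm(chain$coords, c(2, 1, 3)), L * 5L, 3L)
  keep <- which(t(chain$atom_mask))
  flat[keep, ] <- f(flat[keep, , drop = FALSE])
  arr <- array(flat, c(5L, L, 3L))
  chain$coords <- aperm(arr, c(2, 1, 3))
  dimnames(chain$coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  chain
}

#' Construct a ComplexConformation
#'
#' An ordered multi-chain structure with receptor/ligand role labels; the
#' state that flows through the docking model.
#'
#' @param chains List of `ChainStructure` objects with unique chain ids.
#' @param receptor_index,ligand_index Positions of the receptor (anchored) and
#'   ligand (mobile) chains; must differ.
#' @param provenance One of `"holo"`, `"apo"`, `"predicted"`, `"noisy"`,
#'   `"sampled"`.
#' @return An object of class `ComplexConformation`.
#' @export
complex_conformation <- function(chains, receptor_index = 1L,
                                 ligand_index = 2L, provenance = "holo") {
  stopifnot(length(chains) >= 2L)
  ids <- vapply(chains, function(ch) ch$chain_id, "")
  if (anyDuplicated(ids)) stop("chain ids are not unique")
  if (receptor_index == ligand_index) stop("receptor and ligand must differ")
  provenance <- match.arg(provenance,
                          c("holo", "apo", "predicted", "noisy", "sampled"))
  structure(list(chains = chains, receptor_index = as.integer(receptor_index),
                 ligand_index = as.integer(ligand_index),
                 provenance = provenance),
            class = "ComplexConformation")
}

#' @export
receptor_chain <- function(x) x$chains[[x$receptor_index]]

#' @export
ligand_chain <- function(x) x$chains[[x$ligand_index]]

#' Read a two-or-more-chain backbone structure from PDB
#'
#' Parses fixed-column ATOM records, retaining only the N/CA/C/O/CB atoms;
#' other atom names are ignored (a count is reported via message). HETATM-only
#' chains are dropped with a warning. Alternate locations, insertion codes and
#' multi-model files are rejected. Residue B-factors are taken from the CA
#' atom.
#'
#' @param path PDB file path.
#' @param receptor_index,ligand_index Role assignment over the chains in file
#'   order (defaults: first chain receptor, second ligand).
#' @return A `ComplexConformation`.
#' @export
read_pdb <- function(path, receptor_index = 1L, ligand_index = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (any(startsWith(lines, "MODEL ") | startsWith(lines, "MODEL"))) {
    nmodel <- sum(startsWith(lines, "MODEL"))
    if (nmodel > 1L) stop("multi-model PDB files are not supported")
  }
  atom <- lines[startsWith(lines, "ATOM  ")]
  het_chains <- unique(substr(lines[startsWith(lines, "HETATM")], 22, 22))
  if (!length(atom)) stop("no ATOM records in ", path)
  altloc <- substr(atom, 17, 17)
  if (any(!altloc %in% c(" ", "A"))) stop("alternate locations are not supported")
  icode <- substr(atom, 27, 27)
  if (any(icode != " ")) stop("insertion codes are not supported")
  name <- trimws(substr(atom, 13, 16))
  resn <- trimws(substr(atom, 18, 20))
  chain <- substr(atom, 22, 22)
  resno <- as.integer(substr(atom, 23, 26))
  x <- as.numeric(substr(atom, 31, 38))
  y <- as.numeric(substr(atom, 39, 46))
  z <- as.numeric(substr(atom, 47, 54))
  b <- suppressWarnings(as.numeric(substr(atom, 61, 66)))
  b[is.na(b)] <- 0
  keep <- name %in% BACKBONE_ATOMS
  n_dropped <- sum(!keep)
  if (n_dropped) message(sprintf("read_pdb: ignored %d non-backbone/CB atoms", n_dropped))
  df <- data.frame(name = name[keep], resn = resn[keep], chain = chain[keep],
                   resno = resno[keep], x = x[keep], y = y[keep], z = z[keep],
                   b = b[keep], stringsAsFactors = FALSE)
  chain_ids <- unique(df$chain)
  dropped_het <- setdiff(het_chains, chain_ids)
  dropped_het <- dropped_het[dropped_het != " "]
  if (length(dropped_het)) {
    warning(sprintf("dropping HETATM-only chain(s): %s",
                    paste(dropped_het, collapse = ", ")))
  }
  chains <- lapply(chain_ids, function(cid) {
    sub <- df[df$chain == cid, , drop = FALSE]
    resnos <- unique(sub$resno)
    L <- length(resnos)
    coords <- array(0, c(L, 5L, 3L))
    mask <- matrix(FALSE, L, 5L)
    seqv <- character(L)
    bfac <- numeric(L)
    for (ri in seq_len(L)) {
      rows <- sub[sub$resno == resnos[ri], , drop = FALSE]
      rn <- rows$resn[1]
      if (!rn %in% AA3) stop(sprintf("unknown residue %s in chain %s", rn, cid))
      seqv[ri] <- AA1_FROM_3[[rn]]
      for (k in seq_len(nrow(rows))) {
        ai <- match(rows$name[k], BACKBONE_ATOMS)
        coords[ri, ai, ] <- c(rows$x[k], rows$y[k], rows$z[k])
        mask[ri, ai] <- TRUE
      }
      if (!mask[ri, 2L]) {
        stop(sprintf("missing CA for chain %s residue %d", cid, resnos[ri]))
      }
      bfac[ri] <- rows$b[rows$name == "CA"][1]
    }
    chain_structure(cid, paste(seqv, collapse = ""), coords, mask, bfac)
  })
  if (length(chains) < 2L) {
    stop("need at least 2 polymer chains to assign receptor/ligand roles")
  }
  complex_conformation(chains, receptor_index, ligand_index)
}

#' Write a complex to a PDB file
#'
#' Standard fixed-column ATOM records, one TER per chain, occupancy 1.00,
#' per-residue `bfactor` written to the B-factor column. Residues are numbered
#' 1-based contiguous per chain. Coordinates are written with 3 decimals.
#'
#' @param conformation A `ComplexConformation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformation, path) {
  out <- character(0)
  serial <- 1L
  for (ch in conformation$chains) {
    L <- chain_length(ch)
    seqv <- strsplit(ch$sequence, "")[[1]]
    for (ri in seq_len(L)) {
      for (ai in seq_len(5L)) {
        if (!ch$atom_mask[ri, ai]) next
        xyz <- ch$coords[ri, ai, ]
        if (any(!is.finite(xyz))) {
          stop(sprintf("non-finite coordinate at chain %s residue %d atom %s",
                       ch$chain_id, ri, BACKBONE_ATOMS[ai]))
        }
        nm <- BACKBONE_ATOMS[ai]
        # PDB atom-name convention: short names start in column 14
        out <- c(out, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, nm, AA3[[seqv[ri]]], ch$chain_id, ri,
          xyz[1], xyz[2], xyz[3], 1.00, ch$bfactor[ri]))
        serial <- serial + 1L
      }
    }
    out <- c(out, sprintf("TER   %5d      %3s %s%4d", serial,
                          AA3[[seqv[L]]], ch$chain_id, L))
    serial <- serial + 1L
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.ComplexConformation <- function(x, ...) {
  lens <- vapply(x$chains, chain_length, 1L)
  ids <- vapply(x$chains, function(ch) ch$chain_id, "")
  cat(sprintf("ComplexConformation: %d chains (%s), provenance=%s\n",
              length(x$chains),
              paste(sprintf("%s:%d", ids, lens), collapse = ", "),
              x$provenance))
  cat(sprintf("  receptor=%s ligand=%s\n", ids[x$receptor_index],
              ids[x$ligand_index]))
  invisible(x)
}
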