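#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the C-alpha trace of one chain and model from PDB-format
#' coordinates (via `bio3d::read.pdb`), keeping only the first alternate
#' location of each residue and ordering by residue number. Ligands,
#' waters and peptide chains other than the requested one are ignored.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier (default `"A"`).
#' @param model Model index for multi-model files (default 1).
#' @param structure_id Label for the structure; defaults to the file name.
#' @return List of class `coord_set`: `structure_id`, `chain`, `resno`
#'   (integer vector) and `xyz` (n x 3 matrix, Angstrom).
#' @export
read_calpha <- function(path, chain = "A", model = 1L, structure_id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  sel <- atoms$elety == "CA" & atoms$type == "ATOM"
  if (!any(atoms$chain[sel] == chain)) {
    stop_invalid("chain '", chain, "' not found; available: ",
                 paste(sort(unique(atoms$chain[sel])), collapse = ", "))
  }
  sel <- sel & atoms$chain == chain
  # first alternate location only
  alt <- atoms$alt[sel]
  resno <- atoms$resno[sel]
  keep <- !duplicated(resno)  # records are file-ordered; altloc A precedes B
  idx <- which(sel)[keep]
  resno <- resno[keep]
  nmodels <- nrow(pdb$xyz)
  if (model > nmodels) stop_invalid("model ", model, " not present (file has ", nmodels, ")")
  xyz_row <- pdb$xyz[model, ]
  xyz <- matrix(xyz_row[as.vector(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))],
                ncol = 3, byrow = TRUE)
  ord <- order(resno)
  structure(list(structure_id = structure_id %||% basename(path),
                 chain = chain, resno = as.integer(resno[ord]),
                 xyz = xyz[ord, , drop = FALSE]),
            class = "coord_set")
}

#' Construct a coordinate set directly
#'
#' @param structure_id Label.
#' @param resno Integer residue numbers (no duplicates).
#' @param xyz n x 3 coordinate matrix (Angstrom, finite).
#' @param chain Chain label.
#' @return A `coord_set` object.
#' @export
coord_set <- function(structure_id, resno, xyz, chain = "A") {
  if (anyDuplicated(resno)) stop_invalid("duplicate residue numbers")
  if (!all(is.finite(xyz))) stop_invalid("coordinates must be finite")
  if (nrow(xyz) != length(resno)) stop_invalid("resno/xyz length mismatch")
  ord <- order(resno)
  structure(list(structure_id = structure_id, chain = chain,
                 resno = as.integer(resno[ord]), xyz = xyz[ord, , drop = FALSE]),
            class = "coord_set")
}

#' Pair two coordinate sets on common residue numbers
#'
#' @param a,b `coord_set` objects.
#' @return List: `xyz_a`, `xyz_b` (paired n x 3 matrices), `resno`,
#'   `n_common`, `n_a`, `n_b`.
#' @export
common_residues <- function(a, b) {
  common <- intersect(a$resno, b$resno)
  if (length(common) == 0L) stop_invalid("no common residue numbers between structures")
  common <- sort(common)
  list(xyz_a = a$xyz[match(common, a$resno), , drop = FALSE],
       xyz_b = b$xyz[match(common, b$resno), , drop = FALSE],
       resno = common, n_common = length(common),
       n_a = length(a$resno), n_b = length(b$resno))
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares rigid-body superposition of two paired coordinate arrays:
#' both are centred, the optimal rotation is obtained from the SVD of the
#' covariance matrix with the determinant sign corrected so only proper
#' rotations (no reflections) are returned, and the RMSD is the
#' root-mean-square of paired distances after superposition.
#'
#' @param xyz_a,xyz_b Paired n x 3 matrices (n >= 3, non-collinear).
#' @return List: `rmsd` (Angstrom), `rotation` (3 x 3, applied to centred
#'   `b`), `translation` (maps `b` onto `a` as `b %*% t(R) + t`).
#' @export
kabsch_rmsd <- function(xyz_a, xyz_b) {
  if (nrow(xyz_a) != nrow(xyz_b)) stop_invalid("coordinate arrays must pair 1:1")
  if (nrow(xyz_a) < 3L) stop_invalid("need >= 3 paired atoms")
  ca <- colMeans(xyz_a); cb <- colMeans(xyz_b)
  A <- sweep(xyz_a, 2, ca); B <- sweep(xyz_b, 2, cb)
  if (min(svd(A)$d) < 1e-9 * max(svd(A)$d)) {
    stop_invalid("degenerate (collinear) coordinates")
  }
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  B_rot <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - B_rot)^2)))
  list(rmsd = rmsd, rotation = R, translation = ca - as.vector(cb %*% t(R)))
}

#' Pairwise C-alpha RMSD matrix over a structure set
#'
#' Superposes every pair of structures on their common residue numbers and
#' reports the RMSD matrix (diagonal 0) along with per-pair residue
#' counts, the standard way of summarising how similar a family of
#' near-identical crystal structures is.
#'
#' @param structures List of `coord_set` objects.
#' @return List of class `rmsd_matrix`: `rmsd` (symmetric matrix,
#'   Angstrom), `n_common` (matrix of paired residue counts).
#' @export
pairwise_rmsd_matrix <- function(structures) {
  k <- length(structures)
  if (k < 2L) stop_invalid("need >= 2 structures")
  ids <- vapply(structures, `[[`, character(1), "structure_id")
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  nmat <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    nmat[i, i] <- length(structures[[i]]$resno)
    for (j in seq_len(k)) {
      if (j <= i) next
      pr <- common_residues(structures[[i]], structures[[j]])
      fit <- kabsch_rmsd(pr$xyz_a, pr$xyz_b)
      m[i, j] <- m[j, i] <- fit$rmsd
      nmat[i, j] <- nmat[j, i] <- pr$n_common
    }
  }
  structure(list(rmsd = m, n_common = nmat), class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise C-alpha RMSD (Angstrom):\n")
  print(round(x$rmsd, digits))
  invisible(x)
}
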