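#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{mobile} onto \code{target}. Reflections are excluded.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows.
#' @return list with \code{rotation} (3x3), \code{translation} (3),
#'   \code{rmsd} (Angstrom). The superposed coordinates are
#'   \code{mobile \%*\% t(rotation) + translation}.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3, ncol(target) == 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

#' RMSD after optimal superposition
#'
#' Least-squares optimal-superposition RMSD (rotation + translation, no
#' reflection) between two coarse-grained structures with matched beads.
#'
#' @param a,b \code{cg_structure} objects with equal bead counts and
#'   matching bead roles, or bare n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b) {
  pa <- if (inherits(a, "cg_structure")) a$pos else a
  pb <- if (inherits(b, "cg_structure")) b$pos else b
  if (nrow(pa) != nrow(pb)) {
    stop("bead count mismatch: ", nrow(pa), " vs ", nrow(pb))
  }
  if (inherits(a, "cg_structure") && inherits(b, "cg_structure") &&
      !all(a$role == b$role)) {
    stop("bead roles do not match")
  }
  kabsch(pa, pb)$rmsd
}

#' RMSD without re-superposition
#'
#' Plain root-mean-square deviation between matched coordinates in a common
#' (receptor) frame.
#'
#' @param a,b \code{cg_structure} objects or n x 3 matrices with matched rows.
#' @return RMSD in Angstrom.
#' @export
fixed_rmsd <- function(a, b) {
  pa <- if (inherits(a, "cg_structure")) a$pos else a
  pb <- if (inherits(b, "cg_structure")) b$pos else b
  if (nrow(pa) != nrow(pb)) {
    stop("bead count mismatch: ", nrow(pa), " vs ", nrow(pb))
  }
  sqrt(mean(rowSums((pa - pb)^2)))
}
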