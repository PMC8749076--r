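## Optimal rigid-body superposition (Kabsch, via SVD) and per-frame RMSD
## traces for multi-model coordinate sets.

#' Optimal least-squares superposition of two coordinate sets
#'
#' Computes the proper rotation and translation minimizing the RMSD of
#' \code{coords_a} onto \code{coords_b} over a selection of matched rows
#' (Kabsch algorithm via singular value decomposition, with reflection
#' correction so the rotation determinant is +1).
#'
#' @param coords_a,coords_b numeric \code{n x 3} matrices of matched
#'   coordinates (a is mobile, b is the reference).
#' @param selection optional integer vector of rows to superpose on (default
#'   all rows). The RMSD is computed over the selection after the transform.
#' @return A list of class \code{superposition} with elements
#'   \code{rotation} (3x3, det +1), \code{translation} (length 3),
#'   \code{rmsd} (Angstrom), \code{selection}, and \code{transform(x)}, a
#'   function applying the fit to any \code{m x 3} matrix.
#' @export
kabsch_superpose <- function(coords_a, coords_b, selection = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (ncol(coords_a) != 3 || ncol(coords_b) != 3)
    stop("coordinates must be n x 3 matrices")
  if (is.null(selection)) selection <- seq_len(nrow(coords_a))
  if (length(selection) != length(intersect(selection, seq_len(nrow(coords_a)))) ||
      max(selection) > nrow(coords_b))
    stop("selection out of range")
  if (length(selection) < 3) stop("need at least 3 matched atoms")
  A <- coords_a[selection, , drop = FALSE]
  B <- coords_b[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  ## degenerate (collinear) selections have rank < 2 covariance
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear or coincident) atom selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- cb - as.vector(R %*% ca)
  transform <- function(x) {
    x <- as.matrix(x)
    sweep(x %*% t(R), 2, trans, "+")
  }
  fitted <- transform(A)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 selection = selection, transform = transform),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD = %.4f A\n",
              length(x$selection), x$rmsd))
  invisible(x)
}

#' RMSD of two coordinate sets after optimal superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(coords_a, coords_b, selection = NULL) {
  kabsch_superpose(coords_a, coords_b, selection)$rmsd
}

#' Per-frame RMSD trace of a multi-model structure against a reference
#'
#' Each frame is optimally superposed on the reference over the selection
#' before the RMSD is computed, so rigid-body motion does not contribute.
#'
#' @param frames a \code{bundle_model} with multiple frames (see
#'   \code{\link{read_pdb}}), or a list of \code{n x 3} coordinate matrices.
#' @param reference an \code{n x 3} coordinate matrix (or \code{bundle_model},
#'   whose first frame is used).
#' @param selection integer vector of atom rows used both for fitting and for
#'   the RMSD (default all).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_trace <- function(frames, reference, selection = NULL) {
  if (inherits(frames, "bundle_model")) frames <- bundle_frames(frames)
  if (inherits(reference, "bundle_model")) reference <- bundle_frames(reference)[[1]]
  reference <- as.matrix(reference)
  vapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != nrow(reference))
      stop(sprintf("frame %d has %d atoms but the reference has %d",
                   i, nrow(f), nrow(reference)))
    kabsch_superpose(f, reference, selection)$rmsd
  }, numeric(1))
}
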