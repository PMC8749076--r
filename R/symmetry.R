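## C2 symmetrization of a half bundle: a two-fold rotation about an axis
## (default: the global z axis, the superhelical axis) generates the mate of
## each chain, as used to assemble a two-branch bundle from one heterodimer.

#' Apply a C2 (two-fold) symmetry operation to a bundle
#'
#' Returns the input chains plus their images under a 180-degree rotation
#' about an axis. Image chains get fresh chain ids (next unused letters, in
#' order of the input chains).
#'
#' @param half_bundle a \code{bundle_model} holding the asymmetric half.
#' @param axis list with \code{point} (a point on the axis) and \code{dir}
#'   (axis direction); default the global z axis through the origin.
#' @param clash_cutoff inter-mate atom distances below this (Angstrom)
#'   trigger a clash report (a warning, not a failure).
#' @return A \code{bundle_model} with twice the chains. The number of
#'   clashing inter-mate pairs is attached as attribute \code{"clashes"}.
#' @export
apply_c2 <- function(half_bundle, axis = list(point = c(0, 0, 0), dir = c(0, 0, 1)),
                     clash_cutoff = 1.5) {
  stopifnot(inherits(half_bundle, "bundle_model"))
  u <- vunit(axis$dir)
  ## 180-degree rotation about u: R = 2 u u^T - I
  R <- 2 * tcrossprod(u) - diag(3)
  xyz <- bundle_coords(half_bundle)
  img <- sweep(sweep(xyz, 2, axis$point) %*% t(R), 2, axis$point, "+")

  old_chains <- unique(half_bundle$atoms$chain)
  free <- setdiff(LETTERS, old_chains)
  if (length(free) < length(old_chains)) stop("not enough free chain ids")
  new_ids <- stats::setNames(free[seq_along(old_chains)], old_chains)

  mate <- half_bundle$atoms
  mate$chain <- unname(new_ids[mate$chain])
  mate$x <- img[, 1]; mate$y <- img[, 2]; mate$z <- img[, 3]
  atoms <- rbind(half_bundle$atoms, mate)
  rownames(atoms) <- NULL

  dmin2 <- clash_cutoff^2
  nclash <- 0L
  for (i in seq_len(nrow(xyz))) {
    d2 <- (img[, 1] - xyz[i, 1])^2 + (img[, 2] - xyz[i, 2])^2 + (img[, 3] - xyz[i, 3])^2
    nclash <- nclash + sum(d2 < dmin2)
  }
  if (nclash > 0)
    warning(sprintf("C2 clash report: %d inter-mate atom pair(s) closer than %.2f A",
                    nclash, clash_cutoff))
  out <- bundle_model(atoms, specs = half_bundle$specs,
                      symmetry_ops = c(half_bundle$symmetry_ops,
                                       list(list(type = "C2", axis = axis))))
  attr(out, "clashes") <- nclash
  out
}
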