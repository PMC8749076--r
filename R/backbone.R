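## Full backbone (N, CA, C, O, CB) reconstruction from a Calpha trace.
##
## Strategy: atoms are placed by expressing ideal-helix offsets in a local
## orthonormal frame built from each residue's Calpha and its two neighbors.
## The offsets are calibrated once against a reference helix constructed by
## internal coordinates (NeRF) at canonical alpha-helical torsions
## (phi = -62, psi = -43 deg) with ideal bond geometry (N-CA 1.46, CA-C 1.52,
## C-N 1.33, C=O 1.23, CA-CB 1.53 A).  Because the frame is rotation- and
## translation-equivariant, reconstruction is exact on ideal helical traces
## and a good approximation on gently supercoiled ones.

IDEAL_GEOM <- list(
  b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23, b_ca_cb = 1.53,
  a_n_ca_c = 111.0, a_ca_c_n = 117.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.1, a_c_ca_cb = 110.1,
  t_phi = -62, t_psi = -43, t_omega = 180, t_cb_improper = 122.5
)

## Place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion
## A-B-C-D (degrees). Natural extension reference frame construction.
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Reference ideal alpha-helix backbone built residue-by-residue (NeRF).
## Returns a list of per-residue atom coordinate lists.
ideal_helix_backbone <- function(n) {
  g <- IDEAL_GEOM
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  C <- nerf_place(c(-1, 1, 0), N, CA, g$b_ca_c, g$a_n_ca_c, 40)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1)) {
    Np <- nerf_place(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                     g$b_c_n, g$a_ca_c_n, g$t_psi)
    CAp <- nerf_place(res[[i]]$CA, res[[i]]$C, Np,
                      g$b_n_ca, g$a_c_n_ca, g$t_omega)
    Cp <- nerf_place(res[[i]]$C, Np, CAp,
                     g$b_ca_c, g$a_n_ca_c, g$t_phi)
    res[[i + 1]] <- list(N = Np, CA = CAp, C = Cp)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    Nn <- if (i < n) res[[i + 1]]$N else
      nerf_place(r$N, r$CA, r$C, IDEAL_GEOM$b_c_n, IDEAL_GEOM$a_ca_c_n, IDEAL_GEOM$t_psi)
    res[[i]]$O <- nerf_place(Nn, r$CA, r$C, g$b_c_o, g$a_ca_c_o, 180)
    res[[i]]$CB <- nerf_place(r$N, r$C, r$CA, g$b_ca_cb, g$a_c_ca_cb, g$t_cb_improper)
  }
  res
}

## Local orthonormal frame at CA_i from neighbors: e1 = bisector of the two
## CA-CA bonds, e3 = their normal, e2 = e3 x e1.
ca_frame <- function(ca_prev, ca, ca_next) {
  u <- vunit(ca_next - ca)
  v <- vunit(ca_prev - ca)
  e1 <- vunit(u + v)
  e3 <- vunit(vcross(u, v))
  e2 <- vcross(e3, e1)
  cbind(e1, e2, e3)
}

## Calibrated offsets of N, C, O, CB from CA in the local frame (memoized).
.backbone_cache <- new.env(parent = emptyenv())

backbone_offsets <- function() {
  if (!is.null(.backbone_cache$offsets)) return(.backbone_cache$offsets)
  ref <- ideal_helix_backbone(12)
  ca <- t(vapply(ref, function(r) r$CA, numeric(3)))
  offs <- list(N = NULL, C = NULL, O = NULL, CB = NULL)
  rows <- 4:9  # interior residues, away from chain-start transients
  acc <- sapply(names(offs), function(a) rep(0, 3), simplify = FALSE)
  for (i in rows) {
    Fr <- ca_frame(ca[i - 1, ], ca[i, ], ca[i + 1, ])
    for (a in names(offs)) {
      d <- ref[[i]][[a]] - ca[i, ]
      acc[[a]] <- acc[[a]] + as.vector(crossprod(Fr, d))
    }
  }
  offsets <- lapply(acc, function(v) v / length(rows))
  .backbone_cache$offsets <- offsets
  offsets
}

## Extrapolate a virtual CA before the first (or after the last) residue by
## the local screw transform estimated from the nearest four CAs.
virtual_ca <- function(ca, end = c("start", "end")) {
  end <- match.arg(end)
  n <- nrow(ca)
  if (end == "start") {
    fit <- kabsch_superpose(ca[2:4, , drop = FALSE], ca[1:3, , drop = FALSE])
    as.vector(fit$transform(ca[1, , drop = FALSE]))
  } else {
    fit <- kabsch_superpose(ca[(n - 3):(n - 1), , drop = FALSE],
                            ca[(n - 2):n, , drop = FALSE])
    as.vector(fit$transform(ca[n, , drop = FALSE]))
  }
}

#' Build a full backbone chain from a Calpha trace
#'
#' Adds N, C, O and CB atoms (CB omitted for glycine) to each residue of a
#' Calpha trace with ideal covalent geometry. Atom positions are
#' deterministic functions of the trace and equivariant under rigid motion.
#'
#' @param ca_trace \code{n x 3} matrix of Calpha coordinates (rownames, if
#'   present, are taken as residue numbers).
#' @param sequence one-letter amino-acid string of length \code{n}.
#' @param chain_id chain label for the output records.
#' @return A data frame of atom records with columns \code{chain},
#'   \code{resno}, \code{resname}, \code{elety}, \code{elem}, \code{x},
#'   \code{y}, \code{z}.
#' @export
build_backbone <- function(ca_trace, sequence, chain_id = "A") {
  ca <- as.matrix(ca_trace)
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 Calpha positions")
  sequence <- toupper(sequence)
  if (nchar(sequence) != n)
    stop("sequence length must match the number of Calpha positions")
  dd <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(dd < 2.5))
    stop(sprintf("geometry error: consecutive Calpha closer than 2.5 A (min %.2f A)",
                 min(dd)))
  resno <- if (!is.null(rownames(ca))) as.integer(rownames(ca)) else seq_len(n)
  seqv <- strsplit(sequence, "")[[1]]
  offs <- backbone_offsets()

  ext <- rbind(virtual_ca(ca, "start"), ca, virtual_ca(ca, "end"))
  ## vectorized local frames at every residue
  rowunit <- function(m) m / sqrt(rowSums(m * m))
  u <- rowunit(ext[3:(n + 2), , drop = FALSE] - ext[2:(n + 1), , drop = FALSE])
  v <- rowunit(ext[1:n, , drop = FALSE] - ext[2:(n + 1), , drop = FALSE])
  e1 <- rowunit(u + v)
  e3 <- rowunit(cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                      u[, 3] * v[, 1] - u[, 1] * v[, 3],
                      u[, 1] * v[, 2] - u[, 2] * v[, 1]))
  e2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  place <- function(a) {
    o <- offs[[a]]
    ca + o[1] * e1 + o[2] * e2 + o[3] * e3
  }
  xyz_by <- list(N = place("N"), CA = ca, C = place("C"),
                 O = place("O"), CB = place("CB"))

  has_cb <- seqv != "G"
  per_res <- ifelse(has_cb, 5L, 4L)
  ridx <- rep(seq_len(n), per_res)
  elety <- unlist(lapply(seq_len(n), function(i)
    c("N", "CA", "C", "O", if (has_cb[i]) "CB")), use.names = FALSE)
  xyz <- matrix(0, length(ridx), 3)
  for (a in c("N", "CA", "C", "O", "CB")) {
    sel <- elety == a
    xyz[sel, ] <- xyz_by[[a]][ridx[sel], , drop = FALSE]
  }
  atoms <- data.frame(
    chain = chain_id, resno = resno[ridx], resname = aa_1to3(seqv)[ridx],
    elety = elety, elem = substr(elety, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  atoms
}

#' Multi-chain bundle model container
#'
#' A light container for multi-chain atomic coordinates: an atom table plus
#' the chain specifications (when built from Crick parameters) and any
#' symmetry operations applied.
#'
#' @param atoms data frame of atom records (as from \code{\link{build_backbone}}).
#' @param specs optional list of \code{\link{chain_spec}} objects.
#' @param symmetry_ops list of rigid transforms applied (bookkeeping).
#' @return An object of class \code{bundle_model}.
#' @export
bundle_model <- function(atoms, specs = NULL, symmetry_ops = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "elety", "elem", "x", "y", "z")
                %in% names(atoms)))
  has_ca <- tapply(atoms$elety == "CA", paste(atoms$chain, atoms$resno), any)
  if (!all(has_ca)) stop("every residue must have at least a CA atom")
  structure(list(atoms = atoms, specs = specs, symmetry_ops = symmetry_ops,
                 frames = NULL),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nf <- length(bundle_frames(x))
  cat(sprintf("bundle_model: %d atoms, %d chain(s) [%s], %d residue(s), %d frame(s)\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              nrow(unique(x$atoms[, c("chain", "resno")])), nf))
  invisible(x)
}

#' Coordinate matrix of a bundle model
#'
#' @param model a \code{bundle_model}.
#' @return \code{n x 3} numeric matrix of atom coordinates (first frame).
#' @export
bundle_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' List of coordinate frames of a (possibly multi-model) bundle
#'
#' @param model a \code{bundle_model}.
#' @return List of \code{n x 3} matrices, one per frame.
#' @export
bundle_frames <- function(model) {
  if (!is.null(model$frames)) model$frames else list(bundle_coords(model))
}

## Replace the coordinates of a bundle model (atom order preserved).
set_bundle_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Build a bundle model from chain specifications
#'
#' Generates each chain's Calpha trace from its Crick parameters and
#' reconstructs the full backbone.
#'
#' @param specs list of \code{\link{chain_spec}} objects.
#' @param ca_only if TRUE, only Calpha atoms are generated (fast path used
#'   by restraint-only optimization).
#' @return A \code{bundle_model}.
#' @export
build_bundle <- function(specs, ca_only = FALSE) {
  if (inherits(specs, "chain_spec")) specs <- list(specs)
  atoms <- do.call(rbind, lapply(specs, function(sp) {
    ca <- generate_chain_ca(sp)
    if (ca_only) {
      seqv <- strsplit(sp$sequence, "")[[1]]
      data.frame(chain = sp$chain_id, resno = as.integer(rownames(ca)),
                 resname = aa_1to3(seqv), elety = "CA", elem = "C",
                 x = ca[, 1], y = ca[, 2], z = ca[, 3],
                 stringsAsFactors = FALSE)
    } else {
      build_backbone(ca, sp$sequence, sp$chain_id)
    }
  }))
  rownames(atoms) <- NULL
  bundle_model(atoms, specs = specs)
}
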