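## Crick parameterization of a supercoiled alpha-helix.
##
## A chain is described by a minor (alpha) helix of radius r0 and rise h per
## residue wound around a superhelical axis of radius r1 and pitch P.  The
## per-residue superhelical phase advance is
##     omega_major = 360 * d_z / P,   d_z = h * cos(alpha),
## with pitch angle alpha = atan(2*pi*r1 / P).  The minor-helix phase advances
## by omega1 per residue (relative to the rotating superhelical frame); phi1
## sets its initial phase and s translates the whole chain along the global z
## axis (the superhelical axis).  Negative P gives a left-handed supercoil.
## In the r1 = 0 limit alpha and omega_major are defined as 0, so the chain
## degenerates to an ideal straight alpha-helix of radius r0, rise h and
## lab-frame twist omega1 about z.

#' Crick parameters for one supercoiled chain
#'
#' @param r1 superhelical (major) radius, in Angstrom; \code{r1 >= 0}.
#' @param P superhelical pitch in Angstrom, signed: negative values give a
#'   left-handed supercoil. Must be nonzero when \code{r1 > 0}; ignored when
#'   \code{r1 = 0}.
#' @param phi1 minor-helix phase (degrees): rotation of the alpha-helix about
#'   its own local axis.
#' @param s z-shift in Angstrom, a rigid translation along the superhelical
#'   (global z) axis.
#' @param h rise per residue along the local helix axis (Angstrom); fixed at
#'   the canonical alpha-helix value 1.51 by default.
#' @param r0 minor (helical) radius (Angstrom); canonical 2.26 by default.
#' @param omega1 minor-helix twist per residue (degrees) relative to the
#'   superhelical frame; 102.857 (= 720/7) by default, the value that keeps a
#'   heptad repeat in register with the supercoil.
#' @param phi_major0 initial superhelical phase (degrees); places the chain
#'   around the bundle axis.
#' @param orientation \code{"parallel"} or \code{"antiparallel"}. Antiparallel
#'   chains run with negated z-progression and reversed residue order.
#' @return An object of class \code{crick_params}.
#' @export
crick_params <- function(r1, P = NA_real_, phi1 = 0, s = 0,
                         h = 1.51, r0 = 2.26, omega1 = 102.857,
                         phi_major0 = 0, orientation = c("parallel", "antiparallel")) {
  orientation <- match.arg(orientation)
  if (r1 < 0) stop("r1 must be >= 0")
  if (r0 <= 0) stop("r0 must be > 0")
  if (h <= 0) stop("h must be > 0")
  if (r1 > 0 && (is.na(P) || P == 0))
    stop("invalid parameters: r1 > 0 requires a nonzero superhelical pitch P")
  structure(list(
    r1 = r1, P = P, phi1 = phi1 %% 360, s = s,
    h = h, r0 = r0, omega1 = omega1,
    phi_major0 = phi_major0 %% 360, orientation = orientation
  ), class = "crick_params")
}

#' @export
print.crick_params <- function(x, ...) {
  cat(sprintf("Crick parameters (%s):\n", x$orientation))
  cat(sprintf("  r1 = %.3f A   P = %s A   phi1 = %.2f deg   s = %.3f A\n",
              x$r1, if (is.na(x$P)) "NA" else sprintf("%.2f", x$P), x$phi1, x$s))
  cat(sprintf("  r0 = %.3f A   h = %.3f A   omega1 = %.4f deg   phi_major0 = %.2f deg\n",
              x$r0, x$h, x$omega1, x$phi_major0))
  invisible(x)
}

#' Chain specification: sequence, numbering and geometry
#'
#' @param chain_id single-character chain label.
#' @param sequence one-letter amino-acid string.
#' @param first_residue_number number of the first residue (residues are
#'   numbered consecutively from it).
#' @param params a \code{\link{crick_params}} object.
#' @return An object of class \code{chain_spec}.
#' @export
chain_spec <- function(chain_id, sequence, first_residue_number = 1L, params) {
  stopifnot(nchar(chain_id) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("sequence must be non-empty")
  if (!all(strsplit(sequence, "")[[1]] %in% AA1))
    stop("sequence contains non-standard residue codes")
  if (!inherits(params, "crick_params")) stop("params must be crick_params")
  structure(list(chain_id = chain_id, sequence = sequence,
                 first_residue_number = as.integer(first_residue_number),
                 params = params),
            class = "chain_spec")
}

#' Generate the Calpha trace of a supercoiled chain
#'
#' Evaluates the Crick parametric equations at each residue. The superhelical
#' axis is the global z axis; the z-shift \code{s} translates the whole trace
#' along z, and \code{phi1} rotates the minor helix about its local axis.
#'
#' @param spec a \code{\link{chain_spec}}, or a \code{\link{crick_params}}
#'   object together with \code{n}.
#' @param n number of residues (only needed when \code{spec} is bare
#'   \code{crick_params}).
#' @return An \code{n x 3} matrix of Calpha coordinates (Angstrom), rows named
#'   by residue number.
#' @export
generate_chain_ca <- function(spec, n = NULL) {
  if (inherits(spec, "chain_spec")) {
    p <- spec$params
    n <- nchar(spec$sequence)
    resno <- seq(spec$first_residue_number, length.out = n)
  } else if (inherits(spec, "crick_params")) {
    p <- spec
    if (is.null(n)) stop("n is required when passing bare crick_params")
    resno <- seq_len(n)
  } else stop("spec must be a chain_spec or crick_params")
  if (n < 2) stop("need at least 2 residues")

  i <- seq_len(n) - 1
  if (p$r1 == 0) {
    alpha <- 0
    w0 <- 0       # no superhelical rotation in the straight-helix limit
    dz <- p$h
  } else {
    alpha <- atan(2 * pi * p$r1 / p$P)   # signed with P
    dz <- p$h * cos(alpha)
    w0 <- deg2rad(360 * dz / p$P)        # superhelical phase advance / residue
  }
  zdir <- if (p$orientation == "antiparallel") -1 else 1

  theta <- deg2rad(p$phi_major0) + w0 * i
  ct <- cos(theta); st <- sin(theta)
  ## minor-helix axis positions
  ax <- p$r1 * ct
  ay <- p$r1 * st
  az <- zdir * dz * i + p$s

  ## local frame: tangent T, inward normal N, binormal B = T x N
  tx <- -p$r1 * w0 * st
  ty <- p$r1 * w0 * ct
  tz <- rep(zdir * dz, n)
  tl <- sqrt(tx^2 + ty^2 + tz^2)
  tx <- tx / tl; ty <- ty / tl; tz <- tz / tl
  nx <- -ct; ny <- -st; nz <- rep(0, n)
  bx <- ty * nz - tz * ny
  by <- tz * nx - tx * nz
  bz <- tx * ny - ty * nx

  psi <- deg2rad(p$phi1) + deg2rad(p$omega1) * i
  cp <- cos(psi); sp <- sin(psi)
  xyz <- cbind(
    ax + p$r0 * (cp * nx + sp * bx),
    ay + p$r0 * (cp * ny + sp * by),
    az + p$r0 * (cp * nz + sp * bz)
  )
  if (p$orientation == "antiparallel") xyz <- xyz[n:1, , drop = FALSE]
  rownames(xyz) <- resno
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
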