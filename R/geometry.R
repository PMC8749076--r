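## Helix-axis fitting, interhelical crossing angles and hydrogen-bond
## detection.

#' Fit a helix axis from Calpha coordinates
#'
#' Consecutive four-Calpha midpoints trace the local helix axis; the axis is
#' the principal direction of those midpoints, oriented from the N- to the
#' C-terminal end.
#'
#' @param ca \code{n x 3} matrix of Calpha coordinates (n >= 6).
#' @return list with \code{point} (centroid on the axis) and \code{dir}
#'   (unit direction).
#' @export
helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 6) stop("need at least 6 Calpha atoms to fit a helix axis")
  mids <- t(vapply(seq_len(n - 3), function(i) colMeans(ca[i:(i + 3), , drop = FALSE]),
                   numeric(3)))
  ctr <- colMeans(mids)
  sv <- svd(sweep(mids, 2, ctr))
  if (sv$d[1] < 1e-8 || sv$d[1] < 2 * sv$d[2])
    stop("degenerate axis fit: midpoints do not define a clear direction")
  dir <- sv$v[, 1]
  if (sum((mids[nrow(mids), ] - mids[1, ]) * dir) < 0) dir <- -dir
  list(point = ctr, dir = dir)
}

#' Signed interhelical crossing angle
#'
#' The packing angle Omega between two helix axes, measured about their
#' mutual perpendicular at closest approach and folded into (-90, 90]
#' degrees. The sign encodes packing handedness; with this convention a
#' right-handed crossing is negative and the helix pairs of a canonical
#' left-handed parallel coiled coil measure about +20 degrees. Swapping the
#' helices leaves the angle unchanged.
#'
#' @param helix_a,helix_b \code{n x 3} Calpha coordinate matrices (>= 6
#'   residues each).
#' @return Signed angle in degrees, in (-90, 90].
#' @export
crossing_angle <- function(helix_a, helix_b) {
  axa <- helix_axis(helix_a)
  axb <- helix_axis(helix_b)
  d1 <- axa$dir; d2 <- axb$dir
  w0 <- axa$point - axb$point
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- a * cc - b * b
  if (abs(den) < 1e-10) {
    ## parallel axes: angle 0 by convention
    return(0)
  }
  t1 <- (b * e - cc * d) / den
  t2 <- (a * e - b * d) / den
  p1 <- axa$point + t1 * d1
  p2 <- axb$point + t2 * d2
  u <- p2 - p1
  if (vnorm(u) < 1e-8) {
    ## intersecting axes: use any perpendicular
    u <- vcross(d1, d2)
  }
  u <- vunit(u)
  ang <- rad2deg(atan2(sum(vcross(d1, d2) * u), sum(d1 * d2)))
  ## fold into (-90, 90]
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Detect hydrogen bonds by heavy-atom geometry
#'
#' Donor-acceptor pairs (backbone amide N donors, carbonyl O acceptors by
#' default) within a distance cutoff and satisfying an angular criterion.
#' With no explicit hydrogens, the angle tested is donor...acceptor-
#' antecedent (N...O=C), which must be at least \code{angle_cutoff}.
#' Pairs within the same or sequence-adjacent residues of one chain are
#' skipped.
#'
#' @param model a \code{bundle_model}.
#' @param d_cutoff maximum donor-acceptor distance (3.5 Angstrom default).
#' @param angle_cutoff minimum angle at the acceptor (120 degrees default).
#' @return data frame with one row per bond: donor/acceptor chain, residue,
#'   atom, \code{distance}, \code{angle}.
#' @export
hydrogen_bonds <- function(model, d_cutoff = 3.5, angle_cutoff = 120) {
  a <- model$atoms
  don <- which(a$elety == "N")
  acc <- which(a$elety == "O")
  xyz <- bundle_coords(model)
  rows <- list()
  for (i in don) {
    d2 <- (xyz[acc, 1] - xyz[i, 1])^2 + (xyz[acc, 2] - xyz[i, 2])^2 +
      (xyz[acc, 3] - xyz[i, 3])^2
    near <- acc[d2 <= d_cutoff^2]
    for (j in near) {
      if (a$chain[j] == a$chain[i] && abs(a$resno[j] - a$resno[i]) < 2) next
      ## acceptor antecedent: carbonyl C of the same residue
      kc <- which(a$chain == a$chain[j] & a$resno == a$resno[j] & a$elety == "C")
      if (length(kc) == 0) next
      ang <- bond_angle(xyz[i, ], xyz[j, ], xyz[kc[1], ])
      if (ang >= angle_cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          donor_chain = a$chain[i], donor_resno = a$resno[i], donor_atom = "N",
          acceptor_chain = a$chain[j], acceptor_resno = a$resno[j],
          acceptor_atom = "O",
          distance = sqrt(sum((xyz[i, ] - xyz[j, ])^2)), angle = ang,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
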