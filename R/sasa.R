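## Solvent-accessible surface area by the Shrake-Rupley sphere-sampling
## method with a deterministic generalized-spiral point set, plus derived
## quantities: group exposure fractions and buried contact areas.

ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

## Deterministic, approximately uniform points on the unit sphere
## (generalized spiral / golden-angle lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(elem) {
  r <- ELEMENT_RADII[toupper(elem)]
  if (anyNA(r))
    stop("unknown element(s) for SASA: ",
         paste(unique(elem[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible areas computed by sampling \code{n_points} points on
#' each atom's solvent-expanded sphere and counting those not buried inside
#' any neighboring sphere. The point lattice is deterministic, so areas are
#' reproducible for a given \code{n_points}.
#'
#' @param model a \code{bundle_model}, or a data frame of atom records.
#' @param probe_radius probe (solvent) radius, 1.4 Angstrom by default.
#' @param n_points sample points per atom (960 by default).
#' @return list of class \code{sasa_report}: \code{atom_area} (per-atom,
#'   Angstrom^2, in atom-table order), \code{total}, and the atom table.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  atoms <- if (inherits(model, "bundle_model")) model$atoms else model
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  R <- atom_radii(atoms$elem) + probe_radius
  pts <- sphere_points(n_points)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  structure(list(atom_area = area, total = sum(area), atoms = atoms,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_report")
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.1f A, %d points/atom)\n",
              x$total, length(x$atom_area), x$probe_radius, x$n_points))
  invisible(x)
}

## Parse a group selector "chain:resnum[:atom1,atom2,...]" (or a vector of
## them) into a logical mask over the atom table.
group_mask <- function(atoms, selector) {
  if (is.logical(selector)) return(selector)
  if (is.numeric(selector)) {
    m <- rep(FALSE, nrow(atoms)); m[selector] <- TRUE; return(m)
  }
  mask <- rep(FALSE, nrow(atoms))
  for (s in selector) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("group selector must be chain:resnum[:atoms]: ", s)
    sel <- atoms$chain == parts[1] & atoms$resno == as.integer(parts[2])
    if (length(parts) >= 3) {
      want <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
      sel <- sel & atoms$elety %in% want
    }
    if (!any(sel)) stop("group selector matches no atoms: ", s)
    mask <- mask | sel
  }
  mask
}

#' Exposure fraction of an atom group
#'
#' Ratio of the group's SASA in the full model to its SASA in a reference
#' state consisting of the group's own residue(s) alone, in the same
#' conformation (all atoms outside those residues removed).
#'
#' @param model a \code{bundle_model}.
#' @param group a group selector: \code{"chain:resnum"} or
#'   \code{"chain:resnum:atom1,atom2"} (vector allowed), atom row indices,
#'   or a logical mask.
#' @param probe_radius,n_points see \code{\link{sasa}}.
#' @return Fraction (about [0, 1]; sampling noise may exceed 1 slightly).
#' @export
group_exposure <- function(model, group, probe_radius = 1.4, n_points = 960) {
  atoms <- model$atoms
  mask <- group_mask(atoms, group)
  if (!any(mask)) stop("empty group")
  full <- sasa(model, probe_radius, n_points)
  g_full <- sum(full$atom_area[mask])
  res_keys <- unique(paste(atoms$chain[mask], atoms$resno[mask]))
  ref_sel <- paste(atoms$chain, atoms$resno) %in% res_keys
  ref_atoms <- atoms[ref_sel, , drop = FALSE]
  ref <- sasa(ref_atoms, probe_radius, n_points)
  g_ref <- sum(ref$atom_area[mask[ref_sel]])
  if (g_ref <= 0) stop("zero reference area for the group")
  g_full / g_ref
}

#' Buried contact area between two atom groups
#'
#' Total area buried at the interface, computed in the complex's
#' conformation as SASA(a alone) + SASA(b alone) - SASA(a and b together).
#' Reported as the total buried area (both faces; not halved).
#'
#' @param model a \code{bundle_model}.
#' @param group_a,group_b disjoint group selectors (see
#'   \code{\link{group_exposure}}); commonly whole chains, e.g. all atoms
#'   with \code{chain == "A"} via a logical mask.
#' @param probe_radius,n_points see \code{\link{sasa}}.
#' @return Buried area (Angstrom^2, >= 0 up to sampling noise).
#' @export
contact_area <- function(model, group_a, group_b, probe_radius = 1.4,
                         n_points = 960) {
  atoms <- model$atoms
  ma <- group_mask(atoms, group_a)
  mb <- group_mask(atoms, group_b)
  if (any(ma & mb)) stop("groups overlap")
  sa <- sasa(atoms[ma, , drop = FALSE], probe_radius, n_points)$total
  sb <- sasa(atoms[mb, , drop = FALSE], probe_radius, n_points)$total
  sab <- sasa(atoms[ma | mb, , drop = FALSE], probe_radius, n_points)$total
  sa + sb - sab
}

#' Chain selector helper
#'
#' Logical mask over a model's atoms for one or more chain ids.
#'
#' @param model a \code{bundle_model}.
#' @param chains character vector of chain ids.
#' @return Logical mask.
#' @export
chain_mask <- function(model, chains) {
  model$atoms$chain %in% chains
}
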