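## Nonbonded (Lennard-Jones 12-6 + Coulomb) and sigmoidal distance-restraint
## energies for reduced backbone models (N, CA, C, O, CB atom classes).
##
## The LJ/charge table is CHARMM22-like for the five backbone atom classes
## and is read from a flat key-value config (a packaged default is provided);
## hydrogens are not modeled, so per-residue charge sums are not neutral.
## Coulomb uses a distance-dependent dielectric eps(r) = 4r by default.
## Both terms are switched smoothly to zero across a 10-12 A window,
## mirroring common simulation practice for LJ cutoffs.

DEFAULT_LJ <- list(
  N  = c(rmin2 = 1.850, eps = 0.200, q = -0.47),
  CA = c(rmin2 = 2.275, eps = 0.020, q =  0.07),
  C  = c(rmin2 = 2.000, eps = 0.110, q =  0.51),
  O  = c(rmin2 = 1.700, eps = 0.120, q = -0.51),
  CB = c(rmin2 = 2.175, eps = 0.055, q =  0.00)
)
COULOMB_CONST <- 332.0636  # kcal/mol * A / e^2

#' Nonbonded energy configuration
#'
#' @param lj named list of atom classes, each \code{c(rmin2, eps, q)}:
#'   half-Rmin (Angstrom), well depth (kcal/mol) and partial charge (e).
#' @param dielectric \code{"4r"} for the distance-dependent model
#'   \code{eps(r) = 4r}, or a positive number for a constant dielectric.
#' @param cutoff nonbonded cutoff (Angstrom).
#' @param switch_start start of the switching window (Angstrom); energies are
#'   switched smoothly to zero between \code{switch_start} and \code{cutoff}.
#' @param weights named vector of term weights (\code{vdw}, \code{elec},
#'   \code{restraint}) applied when terms are combined into a total.
#' @return Object of class \code{energy_config}.
#' @export
energy_config <- function(lj = DEFAULT_LJ, dielectric = "4r",
                          cutoff = 12, switch_start = 10,
                          weights = c(vdw = 1, elec = 1, restraint = 1)) {
  if (!(cutoff > switch_start && switch_start > 0))
    stop("need cutoff > switch_start > 0")
  if (any(vapply(lj, function(v) v[["eps"]] < 0, logical(1))))
    stop("all LJ well depths must be >= 0")
  structure(list(lj = lj, dielectric = dielectric, cutoff = cutoff,
                 switch_start = switch_start, weights = weights),
            class = "energy_config")
}

#' Read an energy configuration from a flat key-value file
#'
#' Recognized keys: \code{lj.<CLASS>.rmin2}, \code{lj.<CLASS>.eps},
#' \code{charge.<CLASS>}, \code{dielectric} (\code{4r} or a number),
#' \code{cutoff}, \code{switch_start}, \code{weight.vdw}, \code{weight.elec},
#' \code{weight.restraint}. Lines starting with \code{#} are comments.
#' Missing keys keep their defaults.
#'
#' @param path config file path.
#' @return Object of class \code{energy_config}.
#' @export
read_energy_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[ \t=]+")
  lj <- DEFAULT_LJ
  diel <- "4r"; cutoff <- 12; sw <- 10
  w <- c(vdw = 1, elec = 1, restraint = 1)
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = " "))
    key <- p[1]; val <- p[2]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "lj" && length(parts) == 3) {
      cls <- parts[2]
      if (is.null(lj[[cls]])) lj[[cls]] <- c(rmin2 = 2, eps = 0.1, q = 0)
      lj[[cls]][[parts[3]]] <- as.numeric(val)
    } else if (parts[1] == "charge" && length(parts) == 2) {
      cls <- parts[2]
      if (is.null(lj[[cls]])) lj[[cls]] <- c(rmin2 = 2, eps = 0.1, q = 0)
      lj[[cls]][["q"]] <- as.numeric(val)
    } else if (key == "dielectric") {
      diel <- if (val == "4r") "4r" else as.numeric(val)
    } else if (key == "cutoff") cutoff <- as.numeric(val)
    else if (key == "switch_start") sw <- as.numeric(val)
    else if (parts[1] == "weight" && length(parts) == 2) w[[parts[2]]] <- as.numeric(val)
    else stop("unknown config key: ", key)
  }
  energy_config(lj = lj, dielectric = diel, cutoff = cutoff,
                switch_start = sw, weights = w)
}

## CHARMM-style switching function on energies over [ron, roff].
switch_fn <- function(r, ron, roff) {
  s <- rep(1, length(r))
  s[r >= roff] <- 0
  mid <- r > ron & r < roff
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- ron^2; roff2 <- roff^2
    s[mid] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  s
}

## Precompute the nonbonded pair list for a model's topology + coordinates-
## independent parameters. Pairs separated by fewer than 3 bonds (1-2, 1-3)
## are excluded.
nonbonded_setup <- function(model, config) {
  a <- model$atoms
  n <- nrow(a)
  cls <- a$elety
  unknown <- setdiff(unique(cls), names(config$lj))
  if (length(unknown) > 0)
    stop("unknown atom class(es) in LJ table: ", paste(unknown, collapse = ", "))
  par <- do.call(rbind, config$lj[cls])
  ## backbone bond topology
  bonds <- list()
  key <- paste(a$chain, a$resno)
  idx_of <- function(k, el) which(key == k & a$elety == el)
  ukeys <- unique(key)
  for (ki in seq_along(ukeys)) {
    k <- ukeys[ki]
    iN <- idx_of(k, "N"); iCA <- idx_of(k, "CA"); iC <- idx_of(k, "C")
    iO <- idx_of(k, "O"); iCB <- idx_of(k, "CB")
    add <- function(i, j) if (length(i) && length(j)) bonds[[length(bonds) + 1]] <<- c(i, j)
    add(iN, iCA); add(iCA, iC); add(iC, iO); add(iCA, iCB)
    if (ki < length(ukeys)) {
      k2 <- ukeys[ki + 1]
      same_chain <- a$chain[key == k][1] == a$chain[key == k2][1]
      consecutive <- a$resno[key == k2][1] == a$resno[key == k][1] + 1
      if (same_chain && consecutive) add(iC, idx_of(k2, "N"))
    }
  }
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  excl <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(i, j) if (i != j) assign(paste(min(i, j), max(i, j)), TRUE, excl)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      mark(i, j)
      for (k in adj[[j]]) mark(i, k)
    }
  }
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  keep <- !vapply(seq_along(ii),
                  function(t) exists(paste(ii[t], jj[t]), excl), logical(1))
  ii <- ii[keep]; jj <- jj[keep]
  list(i = ii, j = jj,
       eps = sqrt(par[ii, "eps"] * par[jj, "eps"]),
       rmin = par[ii, "rmin2"] + par[jj, "rmin2"],
       qq = par[ii, "q"] * par[jj, "q"],
       config = config)
}

nonbonded_eval <- function(setup, xyz) {
  cfg <- setup$config
  dx <- xyz[setup$i, 1] - xyz[setup$j, 1]
  dy <- xyz[setup$i, 2] - xyz[setup$j, 2]
  dz <- xyz[setup$i, 3] - xyz[setup$j, 3]
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  within <- d < cfg$cutoff
  d <- d[within]
  if (length(d) == 0) return(c(vdw = 0, elec = 0))
  sw <- switch_fn(d, cfg$switch_start, cfg$cutoff)
  sr <- (setup$rmin[within] / d)^6
  vdw <- sum(setup$eps[within] * (sr * sr - 2 * sr) * sw)
  if (identical(cfg$dielectric, "4r")) {
    elec <- sum(COULOMB_CONST * setup$qq[within] / (4 * d * d) * sw)
  } else {
    elec <- sum(COULOMB_CONST * setup$qq[within] / (cfg$dielectric * d) * sw)
  }
  c(vdw = vdw, elec = elec)
}

#' Nonbonded (van der Waals + electrostatic) energy of a bundle
#'
#' Lennard-Jones 12-6 plus Coulomb energy over all atom pairs separated by at
#' least 3 bonds, with energies switched to zero across the configured
#' switching window.
#'
#' @param model a \code{bundle_model}.
#' @param config an \code{\link{energy_config}}.
#' @return Named numeric vector \code{c(vdw = , elec = )} (kcal/mol).
#' @export
nonbonded_energy <- function(model, config = energy_config()) {
  setup <- nonbonded_setup(model, config)
  nonbonded_eval(setup, bundle_coords(model))
}

#' Sigmoidal distance restraints
#'
#' Builds a restraint table in the form used by \code{\link{restraint_energy}}
#' and \code{\link{mc_sample}}. Each restraint contributes
#' \deqn{E(d) = w / (1 + \exp(-k (d - d_0))),}
#' a sigmoid rising from 0 (pair in contact, well below \eqn{d_0}) to the
#' maximum penalty \eqn{w} (pair far apart), with \eqn{E(d_0) = w/2}. This is
#' the standard "soft upper bound" used to encode evolutionary-coupling
#' contacts.
#'
#' @param chain_a,res_a,chain_b,res_b identity of the restrained residue pair.
#' A \code{type = "well"} restraint is the symmetric variant: the sum of two
#' opposing sigmoids,
#' \deqn{E(d) = w [\sigma(k(d - d_0 - \delta)) + \sigma(-k(d - d_0 + \delta))],}
#' approximately zero within \eqn{d_0 \pm \delta} (\code{halfwidth}) and
#' rising to \eqn{w} on both sides. Wells encode a known target distance
#' (both an upper and a lower bound), which makes geometry recovery
#' well-posed under restraints alone.
#'
#' @param d0 inflection distance (Angstrom).
#' @param w maximum penalty (energy units).
#' @param k steepness (1/Angstrom).
#' @param atom atom used per residue: \code{"CB"} (default; CA is used for
#'   glycine or when CB is absent) or \code{"CA"}.
#' @param type \code{"upper"} (one-sided sigmoid, default) or \code{"well"}.
#' @param halfwidth flat half-width \eqn{\delta} of a well restraint
#'   (Angstrom); ignored for type "upper".
#' @return data frame of class \code{restraint_table}.
#' @export
restraints <- function(chain_a, res_a, chain_b, res_b,
                       d0 = 8, w = 10, k = 2, atom = "CB",
                       type = "upper", halfwidth = 0.25) {
  df <- data.frame(chain_a = chain_a, res_a = as.integer(res_a),
                   chain_b = chain_b, res_b = as.integer(res_b),
                   d0 = d0, w = w, k = k, atom = atom,
                   type = type, halfwidth = halfwidth,
                   stringsAsFactors = FALSE)
  if (any(df$d0 <= 0) || any(df$w < 0) || any(df$k <= 0))
    stop("restraints require d0 > 0, w >= 0, k > 0")
  if (!all(df$type %in% c("upper", "well")))
    stop("restraint type must be 'upper' or 'well'")
  class(df) <- c("restraint_table", class(df))
  df
}

#' Read a restraint list from TSV
#'
#' Expects a header with columns \code{chain_a, res_a, chain_b, res_b, d0, w,
#' k} (optional \code{atom}).
#'
#' @param path TSV file path.
#' @return data frame of class \code{restraint_table}.
#' @export
read_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "d0", "w", "k")
  if (!all(need %in% names(df)))
    stop("restraint TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$atom)) df$atom <- "CB"
  if (is.null(df$type)) df$type <- "upper"
  if (is.null(df$halfwidth)) df$halfwidth <- 0.25
  restraints(df$chain_a, df$res_a, df$chain_b, df$res_b,
             df$d0, df$w, df$k, df$atom, df$type, df$halfwidth)
}

## Resolve restraint endpoints to atom row indices once per topology.
restraint_setup <- function(atoms, restraints) {
  find <- function(chain, resno, atom, r) {
    lab <- sprintf("#%d (%s:%d-%s:%d)", r, restraints$chain_a[r], restraints$res_a[r],
                   restraints$chain_b[r], restraints$res_b[r])
    sel <- which(atoms$chain == chain & atoms$resno == resno)
    if (length(sel) == 0)
      stop(sprintf("restraint %s: residue %s:%d not found in the model",
                   lab, chain, resno))
    hit <- sel[atoms$elety[sel] == atom]
    if (length(hit) == 0 && atom == "CB") hit <- sel[atoms$elety[sel] == "CA"]
    if (length(hit) == 0)
      stop(sprintf("restraint %s: atom %s of residue %s:%d not found",
                   lab, atom, chain, resno))
    hit[1]
  }
  nr <- nrow(restraints)
  list(ia = vapply(seq_len(nr), function(r)
         find(restraints$chain_a[r], restraints$res_a[r], restraints$atom[r], r),
         integer(1)),
       ib = vapply(seq_len(nr), function(r)
         find(restraints$chain_b[r], restraints$res_b[r], restraints$atom[r], r),
         integer(1)))
}

restraint_eval <- function(setup, xyz, restraints) {
  dv <- xyz[setup$ia, , drop = FALSE] - xyz[setup$ib, , drop = FALSE]
  d <- sqrt(rowSums(dv * dv))
  if (is.null(restraints$type)) restraints$type <- "upper"
  e <- restraints$w / (1 + exp(-restraints$k * (d - restraints$d0)))
  wl <- restraints$type == "well"
  if (any(wl)) {
    dl <- restraints$halfwidth[wl]
    e[wl] <- restraints$w[wl] *
      (1 / (1 + exp(-restraints$k[wl] * (d[wl] - restraints$d0[wl] - dl))) +
       1 / (1 + exp(restraints$k[wl] * (d[wl] - restraints$d0[wl] + dl))))
  }
  list(d = d, e = e)
}

#' Evaluate sigmoidal distance restraints on a model
#'
#' @param model a \code{bundle_model}.
#' @param restraints a \code{restraint_table} (see \code{\link{restraints}}).
#' @return list with \code{total} and \code{table} (the restraint table with
#'   measured distance \code{d} and per-restraint \code{energy} appended).
#' @export
restraint_energy <- function(model, restraints) {
  setup <- restraint_setup(model$atoms, restraints)
  ev <- restraint_eval(setup, bundle_coords(model), restraints)
  tab <- restraints
  tab$d <- ev$d
  tab$energy <- ev$e
  list(total = sum(ev$e), table = tab)
}
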