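## Seeded generators for every input the analyses consume, each emitting a
## machine-readable ground-truth record so downstream recovery is testable
## without any external data.

NONPOLAR_CORE <- c("L", "I", "V", "A", "F", "M")
OTHER_RESIDUES <- c("L", "I", "V", "A", "F", "M", "S", "T", "G", "W", "Y", "C", "P")

## Synthetic E. coli-like reference pair (see the packaged annotation
## fixture): published anchor residues at their positions, generic residues
## elsewhere. FtsB block = residues 29-63, FtsL block = residues 60-94.
REF_FTSB <- "LEAVKSAIAAQSAKNAELSARNEALSKELSDIKGG"
REF_FTSL <- "LQAIKESRAELSKERAELSVKWAELSEQEARLGKS"

## Default per-column polar probabilities for the paired-alignment
## generator, in heptad order (1a 1d 2a 2d 3a 3d 4a 4d 5a 5d) per protein.
## Calibrated (Poisson-binomial) so the generating-truth summary statistics
## equal 71% (>=1 polar at the FtsL-block a/d of heptads 1-2), 39% (class
## (3,3)) and 84% (>= 5 polar) over complete pairs.
PAIRED_PROBS_B <- c(`1a` = 0.003587, `1d` = 0.003587, `2a` = 0.003587,
                    `2d` = 0.877593, `3a` = 0.877593, `3d` = 0.003587,
                    `4a` = 0.877593, `4d` = 0.003587, `5a` = 0.003587,
                    `5d` = 0.003587)
PAIRED_PROBS_L <- c(`1a` = 0.014326, `1d` = 0.014326, `2a` = 0.697171,
                    `2d` = 0.014326, `3a` = 0.937056, `3d` = 0.014326,
                    `4a` = 0.014326, `4d` = 0.014326, `5a` = 0.937056,
                    `5d` = 0.014326)

## Poisson-binomial pmf over the number of successes.
poisbinom_pmf <- function(p) {
  f <- 1
  for (pi in p)
    f <- stats::convolve(c(f, 0), rev(c(1 - pi, pi)), type = "open")[seq_len(length(f) + 1)]
  pmax(f, 0)
}

#' Generate synthetic coiled-coil register annotations
#'
#' Entries are drawn per oligomer-order stratum. At core (a/d) positions a
#' residue is polar with the stratum's probability (identity uniform over
#' the polar alphabet, except that 'a' positions are Arg with a separately
#' configurable probability); otherwise it is drawn uniformly from the
#' nonpolar core set. Non-core positions are nonpolar-biased.
#'
#' @param n_entries number of annotation entries.
#' @param order_mix named vector of stratum weights over oligomer orders.
#' @param polar_prob named vector: per-order probability that a core residue
#'   is polar.
#' @param arg_prob_a named vector: per-order probability that an 'a'
#'   position residue is specifically Arg (must be <= polar_prob).
#' @param n_heptads heptads per entry.
#' @param seed RNG seed.
#' @param path optional TSV output path (truth JSON written alongside as
#'   \code{<path>.truth.json}).
#' @return list with \code{annotations} (a \code{register_annotations} data
#'   frame) and \code{truth} (the generating parameters and realized core
#'   counts).
#' @export
gen_cc_annotations <- function(n_entries = 2662,
                               order_mix = c(`2` = 0.80, `3` = 0.12, `4` = 0.08),
                               polar_prob = c(`2` = 0.188, `3` = 0.141, `4` = 0.117),
                               arg_prob_a = c(`2` = 0.045, `3` = 0.020, `4` = 0.005),
                               n_heptads = 5, seed = 1, path = NULL) {
  stopifnot(all(polar_prob >= 0 & polar_prob <= 1),
            all(names(order_mix) %in% names(polar_prob)),
            all(arg_prob_a[names(order_mix)] <= polar_prob[names(order_mix)]))
  set.seed(seed)
  polar <- polar_alphabet()
  reg <- strrep("abcdefg", n_heptads)
  regv <- strsplit(reg, "")[[1]]
  L <- length(regv)
  orders <- sample(names(order_mix), n_entries, replace = TRUE,
                   prob = order_mix / sum(order_mix))
  seqs <- character(n_entries)
  for (i in seq_len(n_entries)) {
    o <- orders[i]
    s <- character(L)
    for (j in seq_len(L)) {
      if (regv[j] %in% c("a", "d")) {
        u <- stats::runif(1)
        if (regv[j] == "a" && u < arg_prob_a[[o]]) {
          s[j] <- "R"
        } else if (u < polar_prob[[o]]) {
          s[j] <- sample(if (regv[j] == "a") setdiff(polar, "R") else polar, 1)
        } else {
          s[j] <- sample(NONPOLAR_CORE, 1)
        }
      } else {
        s[j] <- sample(OTHER_RESIDUES, 1)
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ann <- validate_annotations(data.frame(
    id = sprintf("synth%05d", seq_len(n_entries)),
    sequence = seqs, register = reg,
    oligomer_order = as.integer(orders), orientation = "parallel",
    source = "synthetic census generator", stringsAsFactors = FALSE))
  truth <- list(seed = seed, n_entries = n_entries, n_heptads = n_heptads,
                order_mix = as.list(order_mix), polar_prob = as.list(polar_prob),
                arg_prob_a = as.list(arg_prob_a),
                overall_polar_prob = sum(order_mix / sum(order_mix) *
                                           polar_prob[names(order_mix)]))
  if (!is.null(path)) {
    write_annotations(ann, path)
    jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(annotations = ann, truth = truth)
}

#' Generate a synthetic paired alignment with known conservation structure
#'
#' The reference pair is the packaged E. coli-like pair; the other pairs
#' draw each core (a/d) column as Bernoulli-polar with a per-column
#' probability and fill non-core columns with nonpolar-biased residues.
#' Gaps are inserted at a configurable rate at core columns away from the
#' six anchor (conserved) positions. Default probabilities are calibrated
#' so the generating-truth summaries match the conservation statistics the
#' analysis reports (see \code{\link{conservation_summary}}).
#'
#' @param n_pairs number of sequence pairs (reference included).
#' @param probs_b,probs_l per-core-column polar probabilities, in heptad
#'   order 1a 1d 2a 2d ... 5d.
#' @param gap_rate per-(pair, non-anchor core column) gap probability.
#' @param seed RNG seed.
#' @param dir optional output directory: writes \code{ftsb.aln.fasta},
#'   \code{ftsl.aln.fasta} and \code{truth.json}.
#' @return list with \code{aln} (a \code{paired_alignment}) and
#'   \code{truth} (generating probabilities and their implied summary
#'   statistics).
#' @export
gen_paired_alignment <- function(n_pairs = 2900,
                                 probs_b = PAIRED_PROBS_B,
                                 probs_l = PAIRED_PROBS_L,
                                 gap_rate = 0.01, seed = 1, dir = NULL) {
  stopifnot(length(probs_b) == 10, length(probs_l) == 10,
            all(c(probs_b, probs_l) >= 0 & c(probs_b, probs_l) <= 1))
  set.seed(seed)
  polar <- polar_alphabet()
  reg <- strsplit(strrep("abcdefg", 5), "")[[1]]
  core_cols <- which(reg %in% c("a", "d"))   # heptad order 1a 1d 2a 2d ...
  anchor_core <- c(b = list(c("2d", "3a", "4a")), l = list(c("2a", "3a", "5a")))
  core_names <- paste0(rep(1:5, each = 2), c("a", "d"))

  gen_block <- function(probs, anchors) {
    m <- matrix("", n_pairs - 1, 35)
    for (j in seq_len(35)) {
      if (j %in% core_cols) {
        p <- probs[[core_names[match(j, core_cols)]]]
        pol <- stats::runif(n_pairs - 1) < p
        m[, j] <- ifelse(pol, sample(polar, n_pairs - 1, replace = TRUE),
                         sample(NONPOLAR_CORE, n_pairs - 1, replace = TRUE))
      } else {
        m[, j] <- sample(OTHER_RESIDUES, n_pairs - 1, replace = TRUE)
      }
    }
    gap_cols <- core_cols[!(core_names %in% anchors)]
    for (j in gap_cols) {
      g <- stats::runif(n_pairs - 1) < gap_rate
      m[g, j] <- "-"
    }
    apply(m, 1, paste, collapse = "")
  }
  ids <- c("Ec_ref", sprintf("taxon%05d", seq_len(n_pairs - 1)))
  b <- c(REF_FTSB, gen_block(probs_b, anchor_core$b))
  l <- c(REF_FTSL, gen_block(probs_l, anchor_core$l))
  names(b) <- names(l) <- ids
  aln <- paired_alignment(b, l, "Ec_ref")

  ## implied truth statistics over complete (gap-free) pairs
  fB <- poisbinom_pmf(unname(probs_b)); fL <- poisbinom_pmf(unname(probs_l))
  tot <- stats::convolve(c(fB, rep(0, 10)), rev(c(fL, rep(0, 10))), type = "open")
  l12_cols <- c("1a", "1d", "2a", "2d")
  truth <- list(seed = seed, n_pairs = n_pairs, gap_rate = gap_rate,
                probs_b = as.list(probs_b), probs_l = as.list(probs_l),
                frac_polar_l_heptads12 = 1 - prod(1 - probs_l[l12_cols]),
                class_33 = fB[4] * fL[4],
                frac_ge5 = sum(tot[6:21]))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) writeLines(paste0(">", names(x), "\n", x),
                                    file.path(dir, f))
    wr(b, "ftsb.aln.fasta"); wr(l, "ftsl.aln.fasta")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(aln = aln, truth = truth)
}

#' Generate synthetic per-cell length samples
#'
#' Wild-type lengths are lognormal with median about 2.9 micrometers.
#' The "elongated" phenotype is a mixture replacing a fraction \code{p} of
#' cells with a long-cell component (median scaled by \code{shift}); the
#' "small" phenotype scales the whole distribution down by \code{scale}.
#'
#' @param n number of cells.
#' @param phenotype "wt", "elongated" or "small".
#' @param params list: \code{meanlog}, \code{sdlog} (wild-type lognormal),
#'   \code{p} and \code{shift} (elongated mixture), \code{scale} (small).
#' @param strain strain label (defaults to the phenotype name).
#' @param seed RNG seed.
#' @param path optional CSV output path (truth written alongside).
#' @return list with \code{sample} (a \code{cell_length_sample}) and
#'   \code{truth}.
#' @export
gen_cell_lengths <- function(n = 500, phenotype = c("wt", "elongated", "small"),
                             params = list(), strain = NULL, seed = 1,
                             path = NULL) {
  phenotype <- match.arg(phenotype)
  p <- utils::modifyList(list(meanlog = log(2.93), sdlog = 0.28,
                              p = 0.3, shift = 3, scale = 0.935), params)
  set.seed(seed)
  base <- stats::rlnorm(n, p$meanlog, p$sdlog)
  lengths <- switch(phenotype,
    wt = base,
    elongated = {
      long <- stats::runif(n) < p$p
      base[long] <- stats::rlnorm(sum(long), p$meanlog + log(p$shift), p$sdlog)
      base
    },
    small = base * p$scale)
  strain <- strain %||% phenotype
  smp <- suppressWarnings(cell_length_sample(strain, lengths))
  truth <- c(list(seed = seed, n = n, phenotype = phenotype), p,
             list(median = exp(p$meanlog) *
                    switch(phenotype, wt = 1, elongated = 1, small = p$scale)))
  if (!is.null(path)) {
    utils::write.csv(data.frame(strain = strain, length_um = lengths),
                     path, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(sample = smp, truth = truth)
}

#' Generate a synthetic thermal melting curve
#'
#' Two-state sigmoid with linear baselines (the model of
#' \code{\link{fit_melt}}) plus Gaussian noise, sampled every 3 degrees C
#' from 4 to 89 degrees C.
#'
#' @param tm transition midpoint (degrees C), inside the sampled range.
#' @param width transition width (degrees C).
#' @param baseline1,baseline2 numeric (intercept, slope) of the pre- and
#'   post-transition baselines.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param temperatures sampling temperatures.
#' @param seed RNG seed.
#' @param path optional CSV output path (truth written alongside).
#' @return list with \code{curve} (a \code{melt_curve}) and \code{truth}.
#' @export
gen_melt_curve <- function(tm = 40, width = 3,
                           baseline1 = c(-20, 0.02), baseline2 = c(-5, 0.01),
                           noise_sd = 0, temperatures = seq(4, 89, by = 3),
                           seed = 1, path = NULL) {
  if (tm < min(temperatures) || tm > max(temperatures))
    stop("tm must lie inside the sampled temperature range")
  set.seed(seed)
  b1 <- baseline1[1] + baseline1[2] * temperatures
  b2 <- baseline2[1] + baseline2[2] * temperatures
  y <- b1 + (b2 - b1) / (1 + exp((tm - temperatures) / width)) +
    stats::rnorm(length(temperatures), sd = noise_sd)
  curve <- melt_curve(temperatures, y, wavelength = "224 nm")
  truth <- list(seed = seed, tm = tm, width = width,
                baseline1 = baseline1, baseline2 = baseline2,
                noise_sd = noise_sd)
  if (!is.null(path)) {
    utils::write.csv(data.frame(temperature_C = temperatures, signal = y),
                     path, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(curve = curve, truth = truth)
}

#' Generate a two-helix restraint-recovery case
#'
#' Builds a known two-chain parallel coiled coil (the reference), samples
#' Calpha-pair distances from it as sigmoidal-well restraint targets
#' (d0 = true distance), and returns a perturbed starting state plus a
#' Monte Carlo schedule suited to restraint-only recovery (tied chains,
#' free superhelical radius, pitch, helical phase and z-shift, physical
#' parameter bounds).
#'
#' @param r1,P,phi1 reference Crick parameters (both chains; the second
#'   chain sits at superhelical phase 180 degrees).
#' @param n_res residues per chain (poly-Ala).
#' @param w,k,halfwidth restraint weight, steepness and well half-width.
#' @param perturb named vector of parameter offsets applied to the
#'   reference to form the starting state.
#' @param n_steps,seed Monte Carlo schedule settings.
#' @param dir optional output directory: writes \code{chains.tsv},
#'   \code{restraints.tsv}, \code{reference.pdb} and \code{truth.json}.
#' @return list with \code{ref_specs}, \code{ref_model}, \code{restraints},
#'   \code{start_specs}, \code{schedule} and \code{truth}.
#' @export
gen_restraint_case <- function(r1 = 4.0, P = -140, phi1 = 15, n_res = 30,
                               w = 10, k = 10, halfwidth = 0.25,
                               perturb = c(r1 = 1.2, P = -25, phi1 = 35, s = 0.8),
                               n_steps = 5000, seed = 1, dir = NULL) {
  mk <- function(r1, P, phi1, s) list(
    chain_spec("A", strrep("A", n_res), 1,
               crick_params(r1 = r1, P = P, phi1 = phi1, s = s, phi_major0 = 0)),
    chain_spec("B", strrep("A", n_res), 1,
               crick_params(r1 = r1, P = P, phi1 = phi1, s = s, phi_major0 = 180)))
  ref_specs <- mk(r1, P, phi1, 0)
  ref_model <- build_bundle(ref_specs)
  caA <- generate_chain_ca(ref_specs[[1]])
  caB <- generate_chain_ca(ref_specs[[2]])
  ## restrained pairs: same-index cross pairs, offset cross pairs, and a few
  ## reversed-offset pairs, spread along the chains
  ii <- c(3, 6, 9, 12, 15, 18, 21, 24, 27, 4, 8, 12, 16, 20, 24, 5, 11, 17, 23, 7, 19)
  jj <- c(3, 6, 9, 12, 15, 18, 21, 24, 27, 8, 12, 16, 20, 24, 28, 5, 11, 17, 23, 11, 23)
  keep <- ii <= n_res & jj <= n_res
  ii <- ii[keep]; jj <- jj[keep]
  d0 <- vapply(seq_along(ii), function(t) vnorm(caA[ii[t], ] - caB[jj[t], ]),
               numeric(1))
  rs <- restraints(rep("A", length(ii)), ii, rep("B", length(jj)), jj,
                   d0 = d0, w = w, k = k, atom = "CA",
                   type = "well", halfwidth = halfwidth)
  start_specs <- mk(r1 + perturb[["r1"]], P + perturb[["P"]],
                    phi1 + perturb[["phi1"]], perturb[["s"]])
  schedule <- mc_schedule(n_steps = n_steps,
                          step_sizes = c(r1 = 0.25, P = 8, phi1 = 8, s = 0.4),
                          t0 = 5, gamma = 0.999, seed = seed,
                          free = c("r1", "P", "phi1", "s"),
                          bounds = list(r1 = c(3, 9), P = c(-250, -80),
                                        s = c(-3, 3)),
                          tie_chains = TRUE)
  truth <- list(seed = seed, r1 = r1, P = P, phi1 = phi1, n_res = n_res,
                w = w, k = k, halfwidth = halfwidth,
                n_restraints = length(ii), perturb = as.list(perturb))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_chain_specs(start_specs, file.path(dir, "chains.tsv"))
    utils::write.table(as.data.frame(rs), file.path(dir, "restraints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pdb(ref_model, file.path(dir, "reference.pdb"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ref_specs = ref_specs, ref_model = ref_model, restraints = rs,
       start_specs = start_specs, schedule = schedule, truth = truth)
}

#' Write / read chain specifications as TSV
#'
#' Columns: chain_id, sequence, first_residue_number, r1, P, phi1, s, h,
#' r0, omega1, phi_major0, orientation.
#'
#' @param specs list of \code{\link{chain_spec}} objects.
#' @param path TSV path.
#' @export
write_chain_specs <- function(specs, path) {
  df <- do.call(rbind, lapply(specs, function(sp) {
    p <- sp$params
    data.frame(chain_id = sp$chain_id, sequence = sp$sequence,
               first_residue_number = sp$first_residue_number,
               r1 = p$r1, P = p$P, phi1 = p$phi1, s = p$s, h = p$h, r0 = p$r0,
               omega1 = p$omega1, phi_major0 = p$phi_major0,
               orientation = p$orientation, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_specs
#' @export
read_chain_specs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    chain_spec(df$chain_id[i], df$sequence[i], df$first_residue_number[i],
               crick_params(r1 = df$r1[i], P = df$P[i], phi1 = df$phi1[i],
                            s = df$s[i], h = df$h[i], r0 = df$r0[i],
                            omega1 = df$omega1[i],
                            phi_major0 = df$phi_major0[i],
                            orientation = df$orientation[i]))
  })
}
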