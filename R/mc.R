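## Metropolis Monte Carlo over Crick parameters with geometric cooling.
##
## Each step perturbs one randomly chosen free parameter of one chain by a
## Gaussian proposal and accepts by the Metropolis rule on the total energy
## (weighted nonbonded + restraint terms); ties in energy are accepted. The
## best-energy state visited is tracked and returned.

#' Monte Carlo schedule
#'
#' @param n_steps number of proposal steps (\code{>= 0}).
#' @param step_sizes named vector of Gaussian proposal standard deviations
#'   for the Crick parameters (\code{r1}, \code{P} in Angstrom, \code{phi1}
#'   degrees, \code{s} Angstrom).
#' @param t0 initial temperature (energy units).
#' @param gamma geometric cooling factor: at step i the temperature is
#'   \code{t0 * gamma^i}.
#' @param seed RNG seed; identical seed and schedule give a bit-identical
#'   trace.
#' @param free character vector naming the free parameters (applies to every
#'   chain), or a list with one character vector per chain.
#' @param bounds optional named list of \code{c(lo, hi)} bounds per
#'   parameter; proposals outside are rejected.
#' @param tie_chains if TRUE, a proposed parameter change is applied to every
#'   chain simultaneously (symmetric bundles); requires the tied parameters
#'   to start equal across chains.
#' @return Object of class \code{mc_schedule}.
#' @export
mc_schedule <- function(n_steps = 5000,
                        step_sizes = c(r1 = 0.25, P = 8, phi1 = 8, s = 0.4),
                        t0 = 5, gamma = 0.999, seed = 1,
                        free = c("r1", "P", "phi1", "s"),
                        bounds = NULL, tie_chains = FALSE) {
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (any(step_sizes <= 0)) stop("step sizes must be > 0")
  structure(list(n_steps = as.integer(n_steps), step_sizes = step_sizes,
                 t0 = t0, gamma = gamma, seed = seed, free = free,
                 bounds = bounds, tie_chains = isTRUE(tie_chains)),
            class = "mc_schedule")
}

## Rebuild a chain_spec with updated Crick parameters.
update_spec_param <- function(spec, param, value) {
  spec$params[[param]] <- value
  spec
}

#' Metropolis Monte Carlo sampling of bundle geometry
#'
#' Optimizes the Crick parameters of one or more chains under sigmoidal
#' distance restraints and (optionally) nonbonded energies, by simulated
#' annealing with geometric cooling.
#'
#' @param specs list of \code{\link{chain_spec}} objects (the initial state).
#' @param restraints a \code{restraint_table}, or NULL.
#' @param config an \code{\link{energy_config}} for the nonbonded terms, or
#'   NULL to run on restraints alone.
#' @param schedule an \code{\link{mc_schedule}}.
#' @return list with \code{best_model} (a \code{bundle_model} at the best
#'   parameters), \code{best_params} (list of \code{crick_params} per chain),
#'   \code{best_energy}, \code{trace} (data frame: step, energy, best_energy,
#'   temperature, accepted), and \code{initial_energy}.
#' @export
mc_sample <- function(specs, restraints = NULL, config = NULL,
                      schedule = mc_schedule()) {
  if (inherits(specs, "chain_spec")) specs <- list(specs)
  free <- schedule$free
  if (!is.list(free)) free <- rep(list(free), length(specs))
  if (schedule$n_steps > 0 && all(lengths(free) == 0))
    stop("need at least one free parameter")
  ## CA-only fast path: no nonbonded terms and no CB-atom restraints
  ca_only <- is.null(config) &&
    (is.null(restraints) || all(restraints$atom == "CA"))
  w <- if (is.null(config)) c(vdw = 1, elec = 1, restraint = 1) else config$weights

  build <- function(sp) build_bundle(sp, ca_only = ca_only)
  model <- build(specs)
  nb_setup <- if (!is.null(config)) nonbonded_setup(model, config) else NULL
  rs_setup <- if (!is.null(restraints)) restraint_setup(model$atoms, restraints) else NULL
  ## atom row block of each chain (topology is fixed during sampling)
  chain_rows <- lapply(specs, function(sp) which(model$atoms$chain == sp$chain_id))

  chain_xyz <- function(sp) {
    if (ca_only) generate_chain_ca(sp)
    else {
      bb <- build_backbone(generate_chain_ca(sp), sp$sequence, sp$chain_id)
      as.matrix(bb[, c("x", "y", "z")])
    }
  }
  energy_of <- function(xyz) {
    e <- 0
    if (!is.null(restraints))
      e <- e + w[["restraint"]] * sum(restraint_eval(rs_setup, xyz, restraints)$e)
    if (!is.null(config)) {
      nb <- nonbonded_eval(nb_setup, xyz)
      e <- e + w[["vdw"]] * nb[["vdw"]] + w[["elec"]] * nb[["elec"]]
    }
    e
  }

  cur_xyz <- bundle_coords(model)
  cur_e <- energy_of(cur_xyz)
  cur_specs <- specs
  best_specs <- specs
  best_e <- cur_e

  n <- schedule$n_steps
  if (n == 0) {
    return(list(best_model = model, best_params = lapply(specs, `[[`, "params"),
                best_energy = cur_e, initial_energy = cur_e,
                trace = data.frame(step = integer(0), energy = numeric(0),
                                   best_energy = numeric(0),
                                   temperature = numeric(0),
                                   accepted = logical(0))))
  }

  set.seed(schedule$seed)
  tr_energy <- numeric(n); tr_best <- numeric(n)
  tr_temp <- numeric(n); tr_acc <- logical(n)
  chains_free <- which(lengths(free) > 0)

  tie <- isTRUE(schedule$tie_chains)
  for (i in seq_len(n)) {
    temp <- schedule$t0 * schedule$gamma^i
    ci <- if (length(chains_free) == 1) chains_free else sample(chains_free, 1)
    pars <- free[[ci]]
    pn <- if (length(pars) == 1) pars else sample(pars, 1)
    old <- cur_specs[[ci]]$params[[pn]]
    prop <- old + stats::rnorm(1, sd = schedule$step_sizes[[pn]])
    ok <- TRUE
    if (!is.null(schedule$bounds) && !is.null(schedule$bounds[[pn]])) {
      b <- schedule$bounds[[pn]]
      ok <- prop >= b[1] && prop <= b[2]
    }
    if (pn == "r1" && prop < 0) ok <- FALSE
    if (pn == "P" && prop == 0) ok <- FALSE
    if (pn == "r1" && prop > 0 && is.na(cur_specs[[ci]]$params$P)) ok <- FALSE
    accepted <- FALSE
    if (ok) {
      targets <- if (tie) seq_along(cur_specs) else ci
      cand_specs <- cur_specs
      cand_xyz <- cur_xyz
      for (t in targets) {
        cand_specs[[t]] <- update_spec_param(cand_specs[[t]], pn, prop)
        cand_xyz[chain_rows[[t]], ] <- chain_xyz(cand_specs[[t]])
      }
      cand_e <- energy_of(cand_xyz)
      if (cand_e <= cur_e || stats::runif(1) < exp((cur_e - cand_e) / temp)) {
        cur_specs <- cand_specs
        cur_xyz <- cand_xyz
        cur_e <- cand_e
        accepted <- TRUE
        if (cur_e <= best_e) {
          best_e <- cur_e
          best_specs <- cur_specs
        }
      }
    }
    tr_energy[i] <- cur_e; tr_best[i] <- best_e
    tr_temp[i] <- temp; tr_acc[i] <- accepted
  }

  list(best_model = build_bundle(best_specs),
       best_params = lapply(best_specs, `[[`, "params"),
       best_energy = best_e,
       initial_energy = energy_of(bundle_coords(model)),
       trace = data.frame(step = seq_len(n), energy = tr_energy,
                          best_energy = tr_best, temperature = tr_temp,
                          accepted = tr_acc))
}
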