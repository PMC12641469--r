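# Full free-energy legs: lambda schedules, absolute decoupling (solvation
# free energy), a dual-topology relative-transformation analog, and
# thermodynamic cycle-closure accounting.

#' Lambda schedule
#'
#' An ordered set of coupling-parameter values starting at 0, ending at 1,
#' strictly increasing.
#'
#' @param preset `"asfe15"` for the production 15-value set
#'   `{i/19 : i = 0..9, 11, 13, 15, 17, 19}` (denser near the coupled end,
#'   where the integrand changes fastest), or `"uniform"` with `n` values.
#' @param n number of values for the uniform preset.
#' @param values explicit schedule (overrides `preset`); validated.
#' @return numeric vector of lambda values.
#' @examples
#' lambda_schedule("asfe15")
#' lambda_schedule("uniform", n = 5)
#' @export
lambda_schedule <- function(preset = c("asfe15", "uniform"), n = NULL,
                            values = NULL) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
      stop("lambda values must lie in [0, 1]")
    }
    if (is.unsorted(values, strictly = TRUE)) {
      stop("lambda values must be strictly increasing")
    }
    if (values[1] != 0 || values[length(values)] != 1) {
      stop("schedule must start at 0 and end at 1")
    }
    return(values)
  }
  preset <- match.arg(preset)
  if (preset == "asfe15") {
    c(0:9, 11, 13, 15, 17, 19) / 19
  } else {
    if (is.null(n) || n < 2) stop("uniform preset requires n >= 2")
    seq(0, 1, length.out = n)
  }
}

# shared machinery: run every window of a schedule by Langevin dynamics,
# re-evaluate retained samples at neighboring states, BAR per window pair,
# sum, repeat with independent seeds
run_leg <- function(system, model, schedule, settings, scheme = 2,
                    selector = "solute-solvent", atom_modes = NULL,
                    n_repeats = 3, seeds = seq_len(n_repeats),
                    epsilon = 1e-4, n_equil_steps = 1000,
                    keep_samples = FALSE) {
  schedule <- lambda_schedule(values = schedule)
  K <- length(schedule)
  stopifnot(length(seeds) == n_repeats)
  thermo <- settings$thermo
  beta <- thermo$beta
  per_window <- matrix(NA_real_, n_repeats, K - 1)
  samples_kept <- NULL
  for (r in seq_len(n_repeats)) {
    specs <- lapply(schedule, function(l) {
      alchemical_spec(scheme = scheme, lambda = l, epsilon = epsilon,
                      selector = selector, atom_modes = atom_modes)
    })
    frames_k <- vector("list", K)
    u_own <- vector("list", K)
    pos <- system$positions
    if (n_equil_steps > 0) {
      # per-repeat pre-equilibration at the first state (windows then
      # inherit sequentially, each with its own 20% discard on top)
      se <- settings
      se$n_steps <- as.integer(n_equil_steps)
      se$save_interval <- as.integer(n_equil_steps)
      se$seed <- (seeds[r] %% 1000003) * 1000
      eq <- run_window(system, model, specs[[1]], se)
      pos <- eq$final$positions
    }
    for (k in seq_len(K)) {
      sysk <- system
      sysk$positions <- pos
      sk <- settings
      # derived window seed, kept within 32-bit integer range
      sk$seed <- (seeds[r] %% 1000003) * 1000 + k
      traj <- run_window(sysk, model, specs[[k]], sk)
      pos <- traj$final$positions
      idx <- subsample_frames(traj)
      frames_k[[k]] <- traj$frames[idx, , , drop = FALSE]
      u_own[[k]] <- beta * traj$energies[idx]
    }
    for (k in seq_len(K - 1)) {
      wf <- beta * frame_energies(frames_k[[k]], system, model,
                                  specs[[k + 1]]) - u_own[[k]]
      wr <- beta * frame_energies(frames_k[[k + 1]], system, model,
                                  specs[[k]]) - u_own[[k + 1]]
      per_window[r, k] <- bar(wf, wr, thermo)$dg
    }
    if (keep_samples && r == n_repeats) {
      samples_kept <- list(frames = frames_k, u_own = u_own, specs = specs)
    }
  }
  totals <- rowSums(per_window)
  st <- repeat_statistics(totals)
  structure(list(dg = st$mean, sd = st$sd, per_repeat = totals,
                 per_window = per_window, schedule = schedule,
                 scheme = scheme, estimator = "BAR",
                 n_repeats = n_repeats, samples = samples_kept),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf(
    "<free_energy_result> dG = %.3f +/- %s kcal/mol (%s, scheme %d, %d windows, %d repeats)\n",
    x$dg, if (is.na(x$sd)) "NA" else sprintf("%.3f", x$sd), x$estimator,
    x$scheme, length(x$schedule) - 1, x$n_repeats))
  invisible(x)
}

#' Absolute solvation free energy by decoupling
#'
#' Runs every lambda window in solution (solute-solvent cross pairs shifted,
#' everything else untouched), estimates the decoupling free energy as a sum
#' of per-window BAR estimates, and returns
#' `dG_solv = -dG(coupled -> decoupled)`. The corresponding gas-phase
#' decoupling leg is identically zero because intrasolute interactions are
#' never modified; this is verified numerically on the gas system at every
#' lambda of the schedule, not assumed.
#'
#' @param solvated a [particle_system()] of the solute in solvent (solute
#'   indices set).
#' @param gas the same solute alone in a box (same species, same order).
#' @param model a [toy_pair_potential()].
#' @param schedule a [lambda_schedule()].
#' @param settings a [sampler_settings()].
#' @param scheme shifting scheme 1-4 (default 2, linear-to-cutoff).
#' @param n_repeats independent repeats (default 3); the repeat standard
#'   deviation is the reported uncertainty.
#' @param seeds integer seed per repeat.
#' @param epsilon guard distance, Angstrom.
#' @return A `free_energy_result` whose `dg` is the solvation free energy
#'   (kcal/mol), with `gas_leg_dg` (per-window, exactly zero) and
#'   `gas_verified` attached.
#' @export
run_asfe <- function(solvated, gas, model, schedule, settings, scheme = 2,
                     n_repeats = 3, seeds = seq_len(n_repeats),
                     epsilon = 1e-4, n_equil_steps = 1000) {
  schedule <- lambda_schedule(values = schedule)
  if (!identical(solvated$species[solvated$solute], gas$species)) {
    stop("solvated and gas systems must share the solute definition")
  }
  leg <- run_leg(solvated, model, schedule, settings, scheme = scheme,
                 selector = "solute-solvent", n_repeats = n_repeats,
                 seeds = seeds, epsilon = epsilon,
                 n_equil_steps = n_equil_steps)
  # gas-phase check: with no solvent there are no modified pairs, so the
  # energy of any gas configuration is the same at every lambda
  e_gas <- vapply(schedule, function(l) {
    system_energy(gas, model,
                  alchemical_spec(scheme = scheme, lambda = l,
                                  epsilon = epsilon,
                                  selector = "solute-solvent"))
  }, numeric(1))
  gas_verified <- all(e_gas == e_gas[1])
  out <- leg
  out$dg <- -leg$dg
  out$per_repeat <- -leg$per_repeat
  out$gas_leg_dg <- rep(0, length(schedule) - 1)
  out$gas_verified <- gas_verified
  out$quantity <- "dG_solv"
  out
}

#' Dual-topology construction for a single-site variant pair
#'
#' Given two systems identical except for the position of one variant atom,
#' builds a combined system holding both sites: the vanishing atom (T1's
#' site) and the appearing atom (T2's site). The two variant atoms never
#' interact with each other; each is held near its site by its flat-bottom
#' restraint.
#'
#' @param t1,t2 [particle_system()]s sharing all atoms except the variant
#'   atom's position.
#' @param variant_atom index of the variant atom (defaults to the
#'   `variant_atom` attribute set by [make_toy_solute_pair()]).
#' @return list with `system` (the dual topology), `vanish` and `appear`
#'   (atom indices of the two variant copies).
#' @export
build_dual_topology <- function(t1, t2,
                                variant_atom = attr(t1, "variant_atom")) {
  if (is.null(variant_atom)) stop("variant_atom must be given")
  v <- as.integer(variant_atom)
  n <- n_atoms(t1)
  if (n_atoms(t2) != n || !identical(t1$species, t2$species)) {
    stop("t1 and t2 must share the same atoms")
  }
  same <- apply(t1$positions == t2$positions, 1, all)
  if (any(!same & seq_len(n) != v)) {
    stop("topology mismatch: systems differ at more than the variant site")
  }
  pos <- rbind(t1$positions, t2$positions[v, , drop = FALSE])
  species <- c(t1$species, t2$species[v])
  masses <- c(t1$masses, t2$masses[v])
  res1 <- t1$restraints
  res2v <- Filter(function(r) r$atom == v, t2$restraints)
  res1v <- Filter(function(r) r$atom == v, t1$restraints)
  if (length(res1v) != length(res2v)) {
    stop("variant atom must carry the same number of restraints in t1 and t2")
  }
  for (q in seq_along(res1v)) {
    if (res1v[[q]]$kf != res2v[[q]]$kf || res1v[[q]]$r0 != res2v[[q]]$r0) {
      stop("variant restraint definitions differ between end states; ",
           "their contributions would not cancel")
    }
  }
  res2v <- lapply(res2v, function(r) { r$atom <- n + 1L; r })
  sys <- particle_system(pos, species, t1$box, masses,
                         solute = sort(c(t1$solute, n + 1L)),
                         restraints = c(res1, res2v))
  attr(sys, "vanish") <- v
  attr(sys, "appear") <- n + 1L
  if (!is.null(attr(t1, "solvate_anchor"))) {
    attr(sys, "solvate_anchor") <- attr(t1, "solvate_anchor")
  }
  list(system = sys, vanish = v, appear = n + 1L)
}

#' Relative transformation by per-atom decoupling (dual-topology analog)
#'
#' Computes `dG(T1 -> T2)` in a given phase for two systems differing at a
#' single variant atom site. Both variant copies are present throughout:
#' the vanishing copy is decoupled by per-atom distance shifting from
#' coupled (lambda = 0) to fully excluded (lambda = 1) while the appearing
#' copy runs the reverse; each copy is held near its site by a flat-bottom
#' restraint. Identical restraint definitions at both end states are
#' asserted at construction, so their contributions cancel in the
#' difference.
#'
#' @inheritParams run_asfe
#' @param t1,t2 the two end-state systems (gas phase as given; see
#'   `solvent_box` for solution phase).
#' @param solvent_box optional solvent [particle_system()]; when supplied,
#'   the dual topology is embedded in it (solution-phase leg).
#' @return A `free_energy_result` for `dG(T1 -> T2)` in the given phase.
#' @export
run_rsfe_analog <- function(t1, t2, model, schedule, settings, scheme = 2,
                            n_repeats = 3, seeds = seq_len(n_repeats),
                            epsilon = 1e-4, solvent_box = NULL,
                            n_equil_steps = 1000) {
  dual <- build_dual_topology(t1, t2)
  sys <- dual$system
  if (!is.null(solvent_box)) sys <- solvate_system(sys, solvent_box)
  modes <- integer(n_atoms(sys))
  modes[dual$vanish] <- 1L
  modes[dual$appear] <- 2L
  leg <- run_leg(sys, model, schedule, settings, scheme = scheme,
                 selector = "per-atom", atom_modes = modes,
                 n_repeats = n_repeats, seeds = seeds, epsilon = epsilon,
                 n_equil_steps = n_equil_steps)
  leg$quantity <- "dG_T1_to_T2"
  leg
}

#' Thermodynamic cycle closure
#'
#' Two routes to the same relative solvation free energy difference must
#' agree: the difference of the two absolute legs, and the difference of
#' the relative legs in solution and gas. The closure
#' `dG_gas + dG_solv(T2) - dG_aq - dG_solv(T1)` is zero for a correct
#' method, within the propagated statistical error (root sum of squares of
#' the four leg uncertainties, Gaussian propagation).
#'
#' @param dg_solv_t1,dg_solv_t2 absolute solvation legs: a
#'   `free_energy_result`, or `c(value, sd)` in kcal/mol.
#' @param dg_gas,dg_aq relative legs `T1 -> T2` in gas and solution.
#' @return Object of class `cycle_ledger` with the four legs, `closure` and
#'   `propagated_error` (kcal/mol).
#' @examples
#' cycle_closure(c(-7.2, 0.4), c(-10.0, 0.1), c(-0.9, 0.0), c(-3.7, 0.0))
#' @export
cycle_closure <- function(dg_solv_t1, dg_solv_t2, dg_gas, dg_aq) {
  legs <- lapply(list(dg_solv_t1 = dg_solv_t1, dg_solv_t2 = dg_solv_t2,
                      dg_gas = dg_gas, dg_aq = dg_aq), as_leg)
  v <- vapply(legs, `[[`, numeric(1), "value")
  s <- vapply(legs, `[[`, numeric(1), "sd")
  closure <- v[["dg_gas"]] + v[["dg_solv_t2"]] - v[["dg_aq"]] -
    v[["dg_solv_t1"]]
  structure(list(legs = legs, closure = unname(closure),
                 propagated_error = sqrt(sum(s^2))),
            class = "cycle_ledger")
}

as_leg <- function(x) {
  if (inherits(x, "free_energy_result")) {
    return(list(value = x$dg, sd = if (is.na(x$sd)) 0 else x$sd))
  }
  if (is.numeric(x) && length(x) %in% 1:2) {
    return(list(value = x[1], sd = if (length(x) == 2) x[2] else 0))
  }
  if (is.list(x) && !is.null(x$value)) {
    return(list(value = x$value, sd = if (is.null(x$sd)) 0 else x$sd))
  }
  stop("each leg must be a free_energy_result or c(value, sd); missing leg?")
}

#' @export
print.cycle_ledger <- function(x, ...) {
  v <- vapply(x$legs, `[[`, numeric(1), "value")
  s <- vapply(x$legs, `[[`, numeric(1), "sd")
  lab <- c("dG_solv(T1)", "dG_solv(T2)", "dG_gas(T1->T2)", "dG_aq(T1->T2)")
  cat("<cycle_ledger> (kcal/mol)\n")
  for (i in seq_along(v)) {
    cat(sprintf("  %-15s %+7.3f +/- %.3f\n", lab[i], v[i], s[i]))
  }
  cat(sprintf("  %-15s %+7.3f +/- %.3f\n", "closure", x$closure,
              x$propagated_error))
  invisible(x)
}

#' Run the full toy validation cycle for one seed
#'
#' Builds the seeded toy fixtures (solvent box, variant solute pair),
#' computes the two absolute solvation legs and the two relative legs, and
#' returns the assembled [cycle_closure()] ledger. This is the end-to-end
#' self-consistency check: both routes use only the package's own legs, so
#' a closure within error demonstrates internal correctness without any
#' external reference.
#'
#' @param seed integer; seeds fixtures and all repeats.
#' @param model a [toy_pair_potential()].
#' @param schedule a [lambda_schedule()].
#' @param settings a [sampler_settings()] used for every window.
#' @param scheme shifting scheme 1-4.
#' @param n_repeats repeats per leg.
#' @param n_solvent solvent particles in the toy box.
#' @param box_length box edge, Angstrom.
#' @return A `cycle_ledger` with the four `free_energy_result` legs.
#' @export
run_toy_cycle <- function(seed, model = default_toy_potential(),
                          schedule = lambda_schedule("uniform", n = 11),
                          settings = sampler_settings(n_steps = 3000,
                                                      save_interval = 10,
                                                      friction = 2),
                          scheme = 2, n_repeats = 3, n_solvent = 50,
                          box_length = 12) {
  pair <- make_toy_solute_pair()
  solvent_raw <- make_toy_solvent_box(n = n_solvent, box_length = box_length,
                                      seed = seed)
  # solvate the dual topology (the union of both end states) once and reuse
  # its surviving solvent for every leg: all four legs then share the exact
  # same solvent particle set and the cycle identity holds at the
  # Hamiltonian level, not just in the thermodynamic limit
  dual <- build_dual_topology(pair$t1, pair$t2)$system
  solvent <- extract_solvent(solvate_system(dual, solvent_raw))
  s1 <- solvate_system(pair$t1, solvent)
  s2 <- solvate_system(pair$t2, solvent)
  base <- (seed %% 10000000L) * 40L
  asfe1 <- run_asfe(s1, pair$t1, model, schedule, settings, scheme = scheme,
                    n_repeats = n_repeats, seeds = base + seq_len(n_repeats))
  asfe2 <- run_asfe(s2, pair$t2, model, schedule, settings, scheme = scheme,
                    n_repeats = n_repeats,
                    seeds = base + 10L + seq_len(n_repeats))
  gasr <- run_rsfe_analog(pair$t1, pair$t2, model, schedule, settings,
                          scheme = scheme, n_repeats = n_repeats,
                          seeds = base + 20L + seq_len(n_repeats))
  aqr <- run_rsfe_analog(pair$t1, pair$t2, model, schedule, settings,
                         scheme = scheme, n_repeats = n_repeats,
                         seeds = base + 30L + seq_len(n_repeats),
                         solvent_box = solvent)
  cycle_closure(asfe1, asfe2, gasr, aqr)
}
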