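# Configuration sampling: BAOAB-discretized Langevin dynamics on the
# alchemically modified potential, one lambda-window at a time.

#' Sampler settings
#'
#' @param n_steps number of integration steps per window.
#' @param timestep integration timestep, ps (default 0.001 = 1 fs; the
#'   instability-retry path falls back to half of this).
#' @param friction Langevin friction coefficient, 1/ps (default 1).
#' @param save_interval save coordinates/energy every this many steps
#'   (default 250, i.e. every 0.25 ps at a 1 fs timestep).
#' @param seed integer RNG seed for the window (velocities and thermostat
#'   noise); `NULL` uses the current RNG state.
#' @param thermo a [thermo_state()].
#' @return Object of class `sampler_settings`.
#' @export
sampler_settings <- function(n_steps, timestep = 0.001, friction = 1,
                             save_interval = 250, seed = NULL,
                             thermo = thermo_state(300)) {
  stopifnot(timestep > 0, save_interval >= 1, n_steps >= 1, friction >= 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, save_interval = as.integer(save_interval),
                 seed = seed, thermo = thermo),
            class = "sampler_settings")
}

#' Maxwell-Boltzmann velocities
#'
#' @param system a [particle_system()].
#' @param thermo a [thermo_state()].
#' @return n x 3 matrix of velocities, Angstrom/ps, drawn from the current
#'   RNG state.
#' @export
maxwell_velocities <- function(system, thermo = thermo_state(300)) {
  n <- n_atoms(system)
  kT <- 1 / thermo$beta
  sdv <- sqrt(kT * FCONV / system$masses)
  matrix(rnorm(3 * n), n, 3) * sdv
}

#' Run one lambda-window of Langevin dynamics
#'
#' Integrates BAOAB Langevin dynamics at the alchemical state `spec`,
#' saving coordinates and potential energy every `save_interval` steps.
#' If the window becomes unstable (non-finite energy, or hard overlap of an
#' unmodified pair), it is retried once from the start with the timestep
#' halved and the saving interval doubled (so the physical trajectory length
#' and frame count are preserved); persistent instability is an error naming
#' the offending atom and step.
#'
#' @param system a [particle_system()]; its positions are the starting
#'   configuration.
#' @param model a [toy_pair_potential()].
#' @param spec an [alchemical_spec()] defining the window's state.
#' @param settings a [sampler_settings()].
#' @param velocities optional n x 3 starting velocities (Angstrom/ps);
#'   drawn from Maxwell-Boltzmann when `NULL`.
#' @param spike optional `list(step =, magnitude =)` fault-injection hook:
#'   adds a random force of the given magnitude (kcal/mol/Angstrom) to every
#'   atom at that step of the first attempt only. Used to exercise the
#'   instability-recovery path.
#' @return Object of class `md_trajectory`: `frames` (array
#'   `n_frames x n_atoms x 3`), `energies` (potential, kcal/mol, per frame),
#'   `final` (positions, velocities), `lambda`, `scheme`, `settings`
#'   (as actually used), `retried` flag.
#' @export
run_window <- function(system, model, spec, settings, velocities = NULL,
                       spike = NULL) {
  stopifnot(inherits(settings, "sampler_settings"))
  with_seed(settings$seed, {
    if (is.null(velocities)) {
      velocities <- maxwell_velocities(system, settings$thermo)
    }
    res <- window_attempt(system, model, spec, settings, velocities, spike)
    retried <- FALSE
    if (!res$ok) {
      retried <- TRUE
      settings <- sampler_settings(
        n_steps = settings$n_steps * 2L, timestep = settings$timestep / 2,
        friction = settings$friction,
        save_interval = settings$save_interval * 2L, seed = NULL,
        thermo = settings$thermo)
      res <- window_attempt(system, model, spec, settings, velocities,
                            spike = NULL)
      if (!res$ok) {
        stop(sprintf(
          "window unstable after timestep-halving retry (lambda = %g, step %d, atom %s)",
          spec$lambda, res$fail_step,
          if (res$fail_atom > 0) res$fail_atom else "?"))
      }
    }
    n <- n_atoms(system)
    nf <- res$n_frames
    fr <- aperm(array(res$frames, dim = c(n, nrow(res$frames) / n, 3)),
                c(2, 1, 3))[seq_len(nf), , , drop = FALSE]
    structure(list(frames = fr, energies = res$energies[seq_len(nf)],
                   final = list(positions = res$positions,
                                velocities = res$velocities),
                   lambda = spec$lambda, scheme = spec$scheme,
                   spec = spec, settings = settings, retried = retried),
              class = "md_trajectory")
  })
}

window_attempt <- function(system, model, spec, settings, velocities, spike) {
  a <- alch_args(system, model, spec)
  kT <- 1 / settings$thermo$beta
  spike_step <- if (is.null(spike)) -1L else as.integer(spike$step)
  spike_mag <- if (is.null(spike)) 0 else spike$magnitude
  tryCatch(
    cpp_run_window(system$positions, velocities, system$masses, system$box,
                   a$epsa, a$siga, model$r_cut, model$switch_start,
                   spec$epsilon, spec$scheme, spec$lambda, a$selector, a$sol,
                   a$mode, a$masked, model$single_precision, a$ratom,
                   a$ratom2, a$ranch, a$rr0, a$rkf, settings$timestep,
                   settings$friction, kT, settings$n_steps,
                   settings$save_interval, spike_step, spike_mag),
    error = function(e) list(ok = FALSE, fail_step = NA_integer_,
                             fail_atom = -1L))
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms, lambda = %g (scheme %d)%s\n",
    dim(x$frames)[1], dim(x$frames)[2], x$lambda, x$scheme,
    if (x$retried) ", retried at halved timestep" else ""))
  invisible(x)
}

#' Re-evaluate trajectory frames at another alchemical state
#'
#' Core of the free energy estimation: each retained configuration sampled
#' at one lambda is re-evaluated at neighboring lambda values.
#'
#' @param frames array `n_frames x n_atoms x 3` (or an `md_trajectory`).
#' @param system the [particle_system()] template (species, box, restraints).
#' @param model a [toy_pair_potential()].
#' @param spec the [alchemical_spec()] to evaluate at.
#' @return numeric vector of potential energies, kcal/mol.
#' @export
frame_energies <- function(frames, system, model, spec) {
  if (inherits(frames, "md_trajectory")) frames <- frames$frames
  a <- alch_args(system, model, spec)
  nf <- dim(frames)[1]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    out[f] <- cpp_energy_forces(frames[f, , ], system$box, a$epsa, a$siga,
                                model$r_cut, model$switch_start, spec$epsilon,
                                spec$scheme, spec$lambda, a$selector, a$sol,
                                a$mode, a$masked, model$single_precision,
                                a$ratom, a$ratom2, a$ranch, a$rr0, a$rkf,
                                FALSE)$energy
  }
  out
}

#' Monte Carlo barostat move (optional NPT helper)
#'
#' One isotropic volume move: the box and all coordinates are rescaled by a
#' common factor and the move is accepted with the standard NPT Metropolis
#' probability `min(1, exp(-beta (dU + P dV) + N log(V'/V)))`. Not used by
#' the default (NVT) protocols.
#'
#' @param system a [particle_system()].
#' @param model a [toy_pair_potential()].
#' @param spec an [alchemical_spec()].
#' @param thermo a [thermo_state()] with a non-NULL `pressure` (atm).
#' @param max_dlnv maximum log-volume step (default 0.02).
#' @return list with the (possibly updated) `system` and `accepted` flag.
#' @export
mc_barostat_move <- function(system, model, spec, thermo, max_dlnv = 0.02) {
  if (is.null(thermo$pressure)) stop("barostat requires a pressure")
  # atm * A^3 -> kcal/mol
  p_conv <- thermo$pressure * 1.4584e-5
  n <- n_atoms(system)
  u0 <- system_energy(system, model, spec)
  v0 <- prod(system$box)
  lnv <- log(v0) + runif(1, -max_dlnv, max_dlnv)
  s <- (exp(lnv) / v0)^(1 / 3)
  cand <- system
  cand$box <- system$box * s
  cand$positions <- system$positions * s
  if (any(cand$box <= 2 * model$r_cut)) {
    return(list(system = system, accepted = FALSE))
  }
  u1 <- system_energy(cand, model, spec)
  darg <- -thermo$beta * ((u1 - u0) + p_conv * (exp(lnv) - v0)) +
    (n + 1) * (lnv - log(v0))
  if (log(runif(1)) < darg) {
    list(system = cand, accepted = TRUE)
  } else {
    list(system = system, accepted = FALSE)
  }
}
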