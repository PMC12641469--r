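# Potential backend contract and the toy short-range pair potential.
#
# The contract is deliberately narrow: a potential may depend on the atoms
# only through neighbor-list entries (pair indices, species, distances), so
# masking an atom out of the list is exactly equivalent to deleting it. The
# toy potential stands in for a machine-learned potential: a Lennard-Jones
# pair term multiplied by a cubic switching function so that energy and
# first derivative go to zero continuously at the cutoff. This makes
# dropping shifted pairs at r_cut exact.

#' Toy short-range pair potential
#'
#' Lennard-Jones form with Lorentz-Berthelot combining
#' (`sigma_ij = (sigma_i + sigma_j)/2`, `eps_ij = sqrt(eps_i eps_j)`),
#' multiplied by a cubic switch that takes the pair energy smoothly to zero
#' between `switch_start * r_cut` and `r_cut`.
#'
#' @param params data.frame with columns `species`, `epsilon` (well depth,
#'   kcal/mol) and `sigma` (size, Angstrom), one row per species. A species
#'   with `epsilon = 0` is non-interacting (ideal).
#' @param r_cut cutoff radius, Angstrom (default 5).
#' @param switch_start start of the switching region as a fraction of
#'   `r_cut` (default 0.8).
#' @param single_precision if TRUE, per-pair distances and energies in the
#'   fused evaluation kernel are rounded through IEEE single precision
#'   (a configuration switch; the default is full double precision).
#' @return Object of class `toy_pair_potential`.
#' @examples
#' toy_pair_potential(data.frame(species = "W", epsilon = 0.2, sigma = 3.0))
#' @export
toy_pair_potential <- function(params, r_cut = 5, switch_start = 0.8,
                               single_precision = FALSE) {
  params <- as.data.frame(params)
  stopifnot(all(c("species", "epsilon", "sigma") %in% names(params)),
            r_cut > 0, switch_start > 0, switch_start < 1)
  if (anyDuplicated(params$species)) stop("duplicate species parameters")
  if (any(params$epsilon < 0) || any(params$sigma <= 0)) {
    stop("epsilon must be >= 0 and sigma > 0")
  }
  structure(list(params = params, r_cut = r_cut,
                 switch_start = switch_start,
                 single_precision = isTRUE(single_precision)),
            class = "toy_pair_potential")
}

#' @export
print.toy_pair_potential <- function(x, ...) {
  cat(sprintf(
    "<toy_pair_potential> r_cut = %g A, switch from %g A, %d species\n",
    x$r_cut, x$switch_start * x$r_cut, nrow(x$params)))
  invisible(x)
}

#' Default toy species parameters
#'
#' `W` is a water-oxygen-like solvent particle, `S` a heavier solute core
#' particle, `V` a small hydrogen-like variant particle, and `G` a ghost
#' (non-interacting) species.
#'
#' @param ... passed to [toy_pair_potential()] (e.g. `r_cut`).
#' @return A `toy_pair_potential`.
#' @export
default_toy_potential <- function(...) {
  toy_pair_potential(
    data.frame(species = c("W", "S", "V", "G"),
               epsilon = c(0.2, 0.3, 0.15, 0),
               sigma   = c(3.0, 3.2, 2.5, 2.5)),
    ...)
}

# per-atom epsilon/sigma lookup; errors on unparameterized species
species_params <- function(model, species) {
  idx <- match(species, model$params$species)
  if (anyNA(idx)) {
    stop(sprintf("no potential parameters for species: %s",
                 paste(unique(species[is.na(idx)]), collapse = ", ")))
  }
  list(epsilon = model$params$epsilon[idx], sigma = model$params$sigma[idx])
}

#' Per-pair energy of the toy potential (reference R implementation)
#'
#' Plain-R evaluation of the switched Lennard-Jones pair term; kept as an
#' independent route against the fused C++ kernel.
#'
#' @param model a [toy_pair_potential()].
#' @param d pair distances, Angstrom (evaluated as given; zero at and
#'   beyond `r_cut`).
#' @param species_i,species_j species labels of the two endpoints.
#' @param derivative if TRUE, also return `du`, the derivative of the pair
#'   energy with respect to distance.
#' @return numeric vector of pair energies (kcal/mol), or a list
#'   `(u, du)` when `derivative = TRUE`.
#' @export
pair_energy <- function(model, d, species_i, species_j, derivative = FALSE) {
  pi_ <- species_params(model, species_i)
  pj <- species_params(model, species_j)
  eps <- sqrt(pi_$epsilon * pj$epsilon)
  sig <- (pi_$sigma + pj$sigma) / 2
  rc <- model$r_cut
  ron <- model$switch_start * rc
  u <- du <- numeric(length(d))
  act <- which(d < rc & eps > 0)
  if (length(act)) {
    dd <- d[act]
    sr6 <- (sig[act] / dd)^6
    lj <- 4 * eps[act] * (sr6^2 - sr6)
    ljd <- 4 * eps[act] * (-12 * sr6^2 + 6 * sr6) / dd
    w <- rc - ron
    t <- pmax(0, (dd - ron) / w)
    s <- 1 - t^2 * (3 - 2 * t)
    sdv <- -6 * t * (1 - t) / w
    u[act] <- lj * s
    du[act] <- ljd * s + lj * sdv
  }
  if (derivative) list(u = u, du = du) else u
}

#' Total potential energy from a neighbor list
#'
#' The energy is a sum of per-pair terms evaluated at the (possibly
#' alchemically modified) distances tabulated in the list. The potential
#' never sees atoms that are absent from the list.
#'
#' @param model a potential model (currently [toy_pair_potential()]).
#' @param anl a `neighbor_list` or `alchemical_neighbor_list` built against
#'   the same `r_cut` as the model.
#' @param ... passed to methods.
#' @return total potential energy, kcal/mol.
#' @export
energy <- function(model, anl, ...) UseMethod("energy")

#' @rdname energy
#' @export
energy.toy_pair_potential <- function(model, anl, ...) {
  if (abs(anl$r_cut - model$r_cut) > 1e-12) {
    stop("neighbor list was built with a different r_cut than the model")
  }
  e <- anl$entries
  if (!nrow(e)) return(0)
  d <- if ("modified_distance" %in% names(e)) e$modified_distance else e$d
  sum(pair_energy(model, d, e$species_i, e$species_j))
}

#' Per-atom forces from a neighbor list
#'
#' Minus the gradient of [energy()] with respect to the real coordinates.
#' For alchemically shifted pairs the per-pair derivative is evaluated at
#' the modified distance and multiplied by the chain factor
#' d(modified)/d(true); the fictitious fourth dimension contributes no force
#' component. The net force over all atoms is zero.
#'
#' @param model a [toy_pair_potential()].
#' @param system the [particle_system()] the list was built from.
#' @param anl a `neighbor_list` or `alchemical_neighbor_list`.
#' @return n x 3 matrix of forces, kcal/mol/Angstrom.
#' @export
forces <- function(model, system, anl) {
  e <- anl$entries
  F <- matrix(0, n_atoms(system), 3)
  if (!nrow(e)) return(F)
  d_eval <- if ("modified_distance" %in% names(e)) e$modified_distance else e$d
  cf <- if ("chain_factor" %in% names(e)) e$chain_factor else rep(1, nrow(e))
  pu <- pair_energy(model, d_eval, e$species_i, e$species_j,
                    derivative = TRUE)
  if (any(e$d < 1e-6 & cf == 1 & pu$du != 0)) {
    stop("overlapping atom pair (d = 0) in force evaluation")
  }
  fac <- ifelse(e$d < 1e-6, 0, pu$du * cf / e$d)
  fp <- cbind(fac * e$dx, fac * e$dy, fac * e$dz)
  for (k in 1:3) {
    F[, k] <- F[, k] +
      unname(tapply(c(fp[, k], -fp[, k]), factor(c(e$i, e$j),
             levels = seq_len(n_atoms(system))), sum, default = 0))
  }
  F[is.na(F)] <- 0
  F
}

#' Flat-bottom restraint
#'
#' Zero inside a well of radius `r0` around the anchor, harmonic
#' (`0.5 * kf * (r - r0)^2`) outside; C1-continuous at `r0`. Used to keep
#' weakly coupled atoms near their site.
#'
#' @param atom index of the restrained atom.
#' @param anchor either a length-3 coordinate (fixed anchor point, Angstrom)
#'   or a single integer (anchor atom index).
#' @param r0 well radius, Angstrom (>= 0).
#' @param kf force constant, kcal/mol/Angstrom^2.
#' @return Object of class `flat_bottom_restraint`.
#' @export
flat_bottom_restraint <- function(atom, anchor, r0, kf) {
  stopifnot(r0 >= 0, kf >= 0)
  anchor_atom <- NA_integer_
  anchor_point <- NULL
  if (length(anchor) == 1) {
    anchor_atom <- as.integer(anchor)
  } else if (length(anchor) == 3) {
    anchor_point <- as.numeric(anchor)
  } else stop("anchor must be a length-3 point or a single atom index")
  structure(list(atom = as.integer(atom), anchor_atom = anchor_atom,
                 anchor_point = anchor_point, r0 = r0, kf = kf),
            class = "flat_bottom_restraint")
}

#' Flat-bottom restraint energy
#'
#' @param restraint a [flat_bottom_restraint()].
#' @param system a [particle_system()] supplying coordinates (and the box
#'   for the minimum-image displacement to the anchor).
#' @return energy in kcal/mol: 0 if the displacement is within `r0`, else
#'   `0.5 * kf * (r - r0)^2`.
#' @export
restraint_energy <- function(restraint, system) {
  a <- restraint$atom
  if (a < 1 || a > n_atoms(system)) stop("restrained atom index out of range")
  ref <- if (!is.na(restraint$anchor_atom)) {
    system$positions[restraint$anchor_atom, ]
  } else restraint$anchor_point
  r <- minimum_image_displacement(ref, system$positions[a, ],
                                  system$box)$distance
  if (r <= restraint$r0) 0 else 0.5 * restraint$kf * (r - restraint$r0)^2
}

# ---- fused evaluation (C++ kernel) ----------------------------------------

# marshal system + model + spec into the argument set of the C++ kernels
alch_args <- function(system, model, spec) {
  n <- n_atoms(system)
  sp <- species_params(model, system$species)
  sel <- c("none" = 0L, "solute-solvent" = 1L, "per-atom" = 2L)[spec$selector]
  mode <- if (is.null(spec$atom_modes)) integer(n) else spec$atom_modes
  if (length(mode) != n) stop("atom_modes must have one entry per atom")
  if (length(spec$masked_atoms) && max(spec$masked_atoms) > n) {
    stop("masked_atoms out of range")
  }
  res <- system$restraints
  nr <- length(res)
  ratom <- ratom2 <- integer(nr)
  ranch <- matrix(0, nr, 3)
  rr0 <- rkf <- numeric(nr)
  for (r in seq_len(nr)) {
    ratom[r] <- res[[r]]$atom - 1L
    ratom2[r] <- if (is.na(res[[r]]$anchor_atom)) -1L
                 else res[[r]]$anchor_atom - 1L
    if (!is.null(res[[r]]$anchor_point)) ranch[r, ] <- res[[r]]$anchor_point
    rr0[r] <- res[[r]]$r0
    rkf[r] <- res[[r]]$kf
  }
  list(epsa = sp$epsilon, siga = sp$sigma, selector = sel,
       sol = as.integer(seq_len(n) %in% system$solute), mode = mode,
       masked = as.integer(seq_len(n) %in% spec$masked_atoms),
       ratom = ratom, ratom2 = ratom2, ranch = ranch, rr0 = rr0, rkf = rkf)
}

#' Total system energy (fused evaluation)
#'
#' Rebuilds the neighbor list, applies the alchemical specification and sums
#' pair plus restraint energies in one pass. Identical in result to
#' [build_neighbor_list()] + [apply_alchemy()] + [energy()] plus
#' [restraint_energy()] over the system's restraints; this is the fast path
#' used by the dynamics engine.
#'
#' @param system a [particle_system()].
#' @param model a [toy_pair_potential()].
#' @param spec an [alchemical_spec()]; default is the unmodified state.
#' @return total potential energy, kcal/mol.
#' @export
system_energy <- function(system, model,
                          spec = alchemical_spec(lambda = 0,
                                                 selector = "none")) {
  a <- alch_args(system, model, spec)
  cpp_energy_forces(system$positions, system$box, a$epsa, a$siga,
                    model$r_cut, model$switch_start, spec$epsilon,
                    spec$scheme, spec$lambda, a$selector, a$sol, a$mode,
                    a$masked, model$single_precision, a$ratom, a$ratom2,
                    a$ranch, a$rr0, a$rkf, FALSE)$energy
}

#' Per-atom forces (fused evaluation)
#'
#' @inheritParams system_energy
#' @return list with `energy` (kcal/mol) and `forces` (n x 3,
#'   kcal/mol/Angstrom), including restraint forces and the alchemical
#'   chain rule.
#' @export
system_forces <- function(system, model,
                          spec = alchemical_spec(lambda = 0,
                                                 selector = "none")) {
  a <- alch_args(system, model, spec)
  cpp_energy_forces(system$positions, system$box, a$epsa, a$siga,
                    model$r_cut, model$switch_start, spec$epsilon,
                    spec$scheme, spec$lambda, a$selector, a$sol, a$mode,
                    a$masked, model$single_precision, a$ratom, a$ratom2,
                    a$ranch, a$rr0, a$rkf, TRUE)
}
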