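# Seeded synthetic-system generation. Every test input in the package is
# built by these generators: toy solvent boxes, a variant solute pair, and
# their combinations. Generation is deterministic given the seed (R's
# default Mersenne-Twister RNG), so identical recipes reproduce bit-identical
# systems across runs and platforms.

#' Generate a toy solvent box
#'
#' Places `n` solvent particles uniformly at random in an orthorhombic box
#' and relaxes them by steepest descent on the toy potential until no pair
#' is closer than `0.85 * sigma`. Deterministic given `seed`.
#'
#' @param n number of particles (`n = 0` yields an empty system).
#' @param box_length box edge, Angstrom (scalar or length 3).
#' @param seed integer seed.
#' @param species solvent species label (default `"W"`).
#' @param model a [toy_pair_potential()] providing the species parameters
#'   used for relaxation.
#' @param mass particle mass, amu.
#' @param relax_iter steepest-descent iterations.
#' @return A [particle_system()] with an empty solute set.
#' @export
make_toy_solvent_box <- function(n = 50, box_length = 12, seed = 1,
                                 species = "W",
                                 model = default_toy_potential(),
                                 mass = 18, relax_iter = 500) {
  if (length(box_length) == 1) box_length <- rep(box_length, 3)
  if (n == 0) {
    return(particle_system(matrix(numeric(0), 0, 3), character(0),
                           box_length))
  }
  sigma <- species_params(model, species)$sigma
  if (n * (4 / 3) * pi * (0.425 * sigma)^3 > prod(box_length)) {
    stop("requested density does not admit non-overlapping placement")
  }
  pos <- with_seed(seed, matrix(runif(3 * n), n, 3)) %*% diag(box_length)
  sp <- species_params(model, rep(species, n))
  pos <- cpp_relax(pos, box_length, sp$epsilon, sp$sigma, model$r_cut,
                   model$switch_start, relax_iter, 0.05)
  sys <- particle_system(pos, rep(species, n), box_length,
                         masses = rep(mass, n))
  dmin <- min_pair_distance(sys)
  if (is.finite(dmin) && dmin < 0.85 * sigma) {
    stop(sprintf(
      "relaxation failed to separate particles (min distance %.2f < %.2f A); lower the density",
      dmin, 0.85 * sigma))
  }
  sys
}

# smallest minimum-image pair distance (Inf for < 2 atoms)
min_pair_distance <- function(system) {
  n <- n_atoms(system)
  if (n < 2) return(Inf)
  m <- cpp_build_nl(system$positions, system$box,
                    min(system$box) / 2 - 1e-9)
  if (!nrow(m)) Inf else min(m[, "d"])
}

#' Recipe for the toy variant solute pair
#'
#' A rigid 3-particle core (species `S`, held by flat-bottom restraints to
#' its sites) plus one small variant particle (species `V`) that occupies
#' one of two alternative sites - a toy analog of two tautomers differing
#' only in the position of a single hydrogen. The two sites sit at
#' different distances from the core, so the two end states genuinely
#' differ in energy.
#'
#' @param site1,site2 length-3 coordinates of the two variant sites,
#'   Angstrom (solute frame, core centered near the origin).
#' @param core_kf,core_r0 flat-bottom parameters holding the core atoms
#'   (kcal/mol/A^2, Angstrom).
#' @param variant_kf,variant_r0 flat-bottom parameters holding the variant
#'   atom near its site.
#' @return list of recipe fields consumed by [make_toy_solute_pair()].
#' @export
toy_solute_recipe <- function(site1 = c(-2.9, 0, 0),
                              site2 = c(1.7, 6.24, 0),
                              core_kf = 25, core_r0 = 0.25,
                              variant_kf = 10, variant_r0 = 0.5) {
  list(core = rbind(c(0, 0, 0), c(3.4, 0, 0), c(1.7, 2.94, 0)),
       core_species = "S", core_mass = 16,
       variant_species = "V", variant_mass = 2,
       site1 = site1, site2 = site2,
       core_kf = core_kf, core_r0 = core_r0,
       variant_kf = variant_kf, variant_r0 = variant_r0)
}

#' Build the toy variant solute pair
#'
#' @param recipe a [toy_solute_recipe()].
#' @param box box edge for the gas-phase systems, Angstrom.
#' @return list with [particle_system()]s `t1` and `t2`, identical except
#'   for the variant atom's position; each carries flat-bottom restraints
#'   (identical definitions at both sites) and a `variant_atom` attribute.
#' @export
make_toy_solute_pair <- function(recipe = toy_solute_recipe(), box = 12) {
  nc <- nrow(recipe$core)
  v <- nc + 1L
  build <- function(site) {
    pos <- rbind(recipe$core, site)
    res <- c(
      lapply(seq_len(nc), function(i) {
        flat_bottom_restraint(i, recipe$core[i, ], recipe$core_r0,
                              recipe$core_kf)
      }),
      list(flat_bottom_restraint(v, site, recipe$variant_r0,
                                 recipe$variant_kf)))
    sys <- particle_system(
      pos, c(rep(recipe$core_species, nc), recipe$variant_species),
      box, masses = c(rep(recipe$core_mass, nc), recipe$variant_mass),
      solute = seq_len(v), restraints = res)
    attr(sys, "variant_atom") <- v
    # common reference point so t1, t2 and their dual topology are placed
    # identically when solvated
    attr(sys, "solvate_anchor") <- colMeans(recipe$core)
    sys
  }
  list(t1 = build(recipe$site1), t2 = build(recipe$site2))
}

#' Embed a solute into a solvent box
#'
#' Translates the solute (and its restraint anchor points) so its centroid
#' sits at the box center, removes solvent particles closer than
#' `clash_distance` to any solute atom, and concatenates solute first.
#' Remaining solvent coordinates are preserved bit-exactly.
#'
#' @param solute a [particle_system()] whose atoms are all solute.
#' @param solvent_box a [particle_system()] of pure solvent.
#' @param clash_distance removal radius, Angstrom (default 2.5).
#' @return A combined [particle_system()]; solute atoms first, with the
#'   solute index set, restraints, and any `variant_atom`/`vanish`/`appear`
#'   attributes carried over.
#' @export
solvate_system <- function(solute, solvent_box, clash_distance = 2.5) {
  ns <- n_atoms(solute)
  center <- solvent_box$box / 2
  # systems meant to share a solvent environment (e.g. the legs of a
  # thermodynamic cycle) can carry a common reference point so they are
  # placed identically in the box
  anchor <- attr(solute, "solvate_anchor")
  if (is.null(anchor)) anchor <- colMeans(solute$positions)
  shift <- center - anchor
  spos <- sweep(solute$positions, 2, shift, `+`)
  res <- lapply(solute$restraints, function(r) {
    if (!is.null(r$anchor_point)) r$anchor_point <- r$anchor_point + shift
    r
  })
  keep <- rep(TRUE, n_atoms(solvent_box))
  for (w in seq_len(n_atoms(solvent_box))) {
    for (a in seq_len(ns)) {
      d <- minimum_image_displacement(spos[a, ], solvent_box$positions[w, ],
                                      solvent_box$box)$distance
      if (d < clash_distance) {
        keep[w] <- FALSE
        break
      }
    }
  }
  sys <- particle_system(
    rbind(spos, solvent_box$positions[keep, , drop = FALSE]),
    c(solute$species, solvent_box$species[keep]),
    solvent_box$box,
    masses = c(solute$masses, solvent_box$masses[keep]),
    solute = seq_len(ns), restraints = res)
  for (at in c("variant_atom", "vanish", "appear", "solvate_anchor")) {
    if (!is.null(attr(solute, at))) attr(sys, at) <- attr(solute, at)
  }
  sys
}

#' Extract the solvent of a solvated system as a pure solvent box
#'
#' Used to share one consistent solvent environment between the legs of a
#' thermodynamic cycle: solvating the union of the end states first and
#' reusing the surviving solvent for every leg keeps the solvent particle
#' set identical across legs, so the cycle identity holds exactly at the
#' Hamiltonian level.
#'
#' @param solvated a system produced by [solvate_system()].
#' @return A [particle_system()] of the solvent atoms only.
#' @export
extract_solvent <- function(solvated) {
  w <- solvent_indices(solvated)
  particle_system(solvated$positions[w, , drop = FALSE],
                  solvated$species[w], solvated$box, solvated$masses[w])
}
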