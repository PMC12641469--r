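#' Periodic particle system
#'
#' Container for a set of point particles in an orthorhombic periodic box,
#' with a solute/solvent partition that defines which atom pairs are subject
#' to alchemical modification. Restraints (see [flat_bottom_restraint()])
#' attached to the system are evaluated with every energy call.
#'
#' @param positions numeric matrix, n x 3, coordinates in Angstrom.
#' @param species character vector of per-atom species labels.
#' @param box numeric length 3 (or scalar, recycled), box edge lengths in
#'   Angstrom; all must be positive.
#' @param masses numeric per-atom masses in amu; defaults to 1 for every atom.
#' @param solute integer indices of solute atoms (possibly empty). The
#'   complementary set is the solvent.
#' @param restraints list of [flat_bottom_restraint()] objects.
#' @return An object of class `particle_system`.
#' @examples
#' sys <- particle_system(rbind(c(0, 0, 0), c(3, 0, 0)), c("W", "W"),
#'                        box = 12)
#' n_atoms(sys)
#' @export
particle_system <- function(positions, species, box, masses = NULL,
                            solute = integer(0), restraints = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) != n) stop("species length must match atom count")
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || !all(is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive lengths")
  }
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n || any(masses <= 0)) {
    stop("masses must be positive, one per atom")
  }
  solute <- sort(unique(as.integer(solute)))
  if (length(solute) && (min(solute) < 1 || max(solute) > n)) {
    stop("solute indices out of range")
  }
  structure(
    list(positions = unname(positions), species = species,
         masses = as.numeric(masses), box = as.numeric(box),
         solute = solute, restraints = restraints),
    class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d atoms (%d solute, %d solvent)\n",
              n_atoms(x), length(x$solute), n_atoms(x) - length(x$solute)))
  cat(sprintf("  box: %.2f x %.2f x %.2f A, species: %s\n",
              x$box[1], x$box[2], x$box[3],
              paste(names(table(x$species)), table(x$species),
                    sep = ":", collapse = " ")))
  if (length(x$restraints)) {
    cat(sprintf("  %d flat-bottom restraint(s)\n", length(x$restraints)))
  }
  invisible(x)
}

#' Number of atoms in a system
#' @param system a [particle_system()].
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$positions)

#' Solvent atom indices
#' @param system a [particle_system()].
#' @return integer indices of atoms not in the solute set.
#' @export
solvent_indices <- function(system) {
  setdiff(seq_len(n_atoms(system)), system$solute)
}

#' Thermodynamic state
#'
#' @param temperature temperature in K (> 0).
#' @param pressure optional pressure in atm (used only by the Monte Carlo
#'   barostat).
#' @return An object of class `thermo_state` with fields `temperature`,
#'   `pressure`, and `beta` = 1 / (k_B T) in mol/kcal
#'   (k_B = 0.0019872041 kcal/(mol K)).
#' @examples
#' thermo_state(300)$beta
#' @export
thermo_state <- function(temperature = 300, pressure = NULL) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0")
  }
  structure(list(temperature = temperature, pressure = pressure,
                 beta = 1 / (KB * temperature)),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, beta = %.4f mol/kcal%s\n",
              x$temperature, x$beta,
              if (is.null(x$pressure)) "" else
                sprintf(", P = %g atm", x$pressure)))
  invisible(x)
}

#' Minimum-image displacement and distance
#'
#' Displacement from `pos_i` to `pos_j` under the minimum-image convention
#' for an orthorhombic box: each component is wrapped so its magnitude is at
#' most half the corresponding box length.
#'
#' @param pos_i,pos_j numeric length-3 coordinates, Angstrom.
#' @param box numeric length 3 (or scalar), box edge lengths, all > 0.
#' @return list with `displacement` (length-3, `pos_j - pos_i` wrapped) and
#'   `distance` (its Euclidean norm).
#' @examples
#' minimum_image_displacement(c(0.5, 0, 0), c(9.5, 0, 0), c(10, 10, 10))
#' @export
minimum_image_displacement <- function(pos_i, pos_j, box) {
  if (length(box) == 1) box <- rep(box, 3)
  if (any(!is.finite(pos_i)) || any(!is.finite(pos_j))) {
    stop("coordinates must be finite")
  }
  if (any(box <= 0)) stop("box lengths must be positive")
  dx <- as.numeric(pos_j) - as.numeric(pos_i)
  dx <- dx - box * round(dx / box)
  list(displacement = dx, distance = sqrt(sum(dx^2)))
}
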