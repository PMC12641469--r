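# Neighbor-list construction, masking, and the lambda-dependent
# distance-shifting schemes. This is the heart of the method: all alchemical
# modification happens here, never in the potential.

#' Build a cutoff neighbor list
#'
#' Enumerates every unordered atom pair whose minimum-image distance is
#' strictly below `r_cut`. A half list (each unordered pair once, i < j) is
#' the canonical representation. Requires every box length to exceed
#' `2 * r_cut` so the minimum image is unambiguous.
#'
#' @param system a [particle_system()].
#' @param r_cut cutoff radius, Angstrom.
#' @return Object of class `neighbor_list`: a list with `entries` (data.frame
#'   with columns `i`, `j`, `d`, `dx`, `dy`, `dz`, `species_i`, `species_j`;
#'   displacement is `pos_j - pos_i`, minimum image) and `r_cut`.
#' @examples
#' sys <- particle_system(rbind(c(0, 0, 0), c(3, 0, 0)), c("W", "W"), box = 12)
#' build_neighbor_list(sys, 5)$entries
#' @export
build_neighbor_list <- function(system, r_cut) {
  stopifnot(inherits(system, "particle_system"), r_cut > 0)
  if (any(system$box <= 2 * r_cut)) {
    stop(sprintf(
      "every box length must exceed 2 * r_cut = %g A for unambiguous minimum image",
      2 * r_cut))
  }
  m <- cpp_build_nl(system$positions, system$box, r_cut)
  entries <- data.frame(i = as.integer(m[, "i"]), j = as.integer(m[, "j"]),
                        d = m[, "d"], dx = m[, "dx"], dy = m[, "dy"],
                        dz = m[, "dz"])
  entries$species_i <- system$species[entries$i]
  entries$species_j <- system$species[entries$j]
  structure(list(entries = entries, r_cut = r_cut), class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat(sprintf("<neighbor_list> %d pairs, r_cut = %g A\n",
              nrow(x$entries), x$r_cut))
  invisible(x)
}

#' Mask atoms out of a neighbor list
#'
#' Removes every entry with at least one endpoint in `masked`, making those
#' atoms invisible to any potential that consumes the list - exactly
#' equivalent to deleting them from the system.
#'
#' @param nl a `neighbor_list` (or `alchemical_neighbor_list`).
#' @param masked integer atom indices to exclude (empty set is legal).
#' @return The list with the affected entries removed; nothing else altered.
#' @export
mask_atoms <- function(nl, masked) {
  masked <- as.integer(masked)
  keep <- !(nl$entries$i %in% masked | nl$entries$j %in% masked)
  nl$entries <- nl$entries[keep, , drop = FALSE]
  rownames(nl$entries) <- NULL
  nl
}

#' Alchemical specification
#'
#' Bundles everything that defines one alchemical state: the shifting scheme,
#' the coupling parameter, the guard distance, the rule selecting which pairs
#' are modified, and the set of fully masked atoms.
#'
#' Schemes (modified distance as a function of the true distance `d`):
#' \describe{
#'   \item{1}{`d + lambda * r_cut` - linear shift beyond the cutoff.}
#'   \item{2}{`d + lambda * max(0, r_cut - d) + lambda * epsilon` - linear
#'     shift exactly to the cutoff edge.}
#'   \item{3}{`sqrt(d^2 + (lambda * r_cut)^2)` - norm of a 4D vector whose
#'     fourth component grows with lambda.}
#'   \item{4}{`sqrt(d^2 + lambda * max(r_cut^2 - d^2, 0)) + lambda * epsilon`
#'     - 4D variant landing exactly on the cutoff sphere.}
#' }
#' The guard `epsilon` enters scaled by lambda, so lambda = 0 is an exact
#' identity for all four schemes while schemes 2 and 4 still clear the cutoff
#' at lambda = 1 by an epsilon-order excess.
#'
#' @param scheme integer 1-4 selecting the shifting scheme.
#' @param lambda coupling parameter in \[0, 1\]; 0 = fully coupled,
#'   1 = fully decoupled.
#' @param epsilon guard distance, Angstrom (> 0); default 1e-4.
#' @param selector `"solute-solvent"` (default; modified pairs are exactly
#'   those with one solute and one solvent endpoint), `"none"`, or
#'   `"per-atom"` (see `atom_modes`).
#' @param atom_modes for `selector = "per-atom"`: integer vector, one per
#'   atom; 0 = ordinary, 1 = vanishing (effective lambda = lambda),
#'   2 = appearing (effective lambda = 1 - lambda). Pairs between two
#'   nonzero-mode atoms are excluded outright (dual-topology convention).
#' @param masked_atoms integer indices of atoms masked from the list
#'   entirely, at every lambda.
#' @return Object of class `alchemical_spec`.
#' @export
alchemical_spec <- function(scheme = 2, lambda = 0, epsilon = 1e-4,
                            selector = c("solute-solvent", "none", "per-atom"),
                            atom_modes = NULL, masked_atoms = integer(0)) {
  selector <- match.arg(selector)
  if (!scheme %in% 1:4) stop("scheme must be 1, 2, 3 or 4")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (selector == "per-atom" && is.null(atom_modes)) {
    stop("selector 'per-atom' requires atom_modes")
  }
  structure(list(scheme = as.integer(scheme), lambda = lambda,
                 epsilon = epsilon, selector = selector,
                 atom_modes = if (is.null(atom_modes)) NULL
                              else as.integer(atom_modes),
                 masked_atoms = sort(unique(as.integer(masked_atoms)))),
            class = "alchemical_spec")
}

#' @export
print.alchemical_spec <- function(x, ...) {
  cat(sprintf(
    "<alchemical_spec> scheme %d, lambda = %g, epsilon = %g A, selector = %s",
    x$scheme, x$lambda, x$epsilon, x$selector))
  if (length(x$masked_atoms)) {
    cat(sprintf(", %d masked atom(s)", length(x$masked_atoms)))
  }
  cat("\n")
  invisible(x)
}

#' Lambda-dependent distance shift
#'
#' Applies one of the four shifting schemes to true pair distances
#' `0 <= d < r_cut`. At lambda = 0 the result equals `d` exactly; at
#' lambda = 1 it is at least `r_cut` (strictly above for schemes 1 and 3,
#' and above by an epsilon-order excess for schemes 2 and 4). The result is
#' non-decreasing in lambda.
#'
#' @param d numeric vector of true distances, Angstrom; must satisfy
#'   `0 <= d < r_cut` (pairs at or beyond the cutoff are not list entries
#'   and must not be shifted).
#' @param r_cut cutoff radius, Angstrom.
#' @param spec an [alchemical_spec()] (its `scheme`, `lambda`, `epsilon`
#'   are used).
#' @return numeric vector of modified distances.
#' @examples
#' sp <- alchemical_spec(scheme = 1, lambda = 1)
#' shift_distance(2, 5, sp)  # 7
#' @export
shift_distance <- function(d, r_cut, spec) {
  stopifnot(inherits(spec, "alchemical_spec"))
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  if (any(d >= r_cut)) {
    stop("d >= r_cut: a pair at or beyond the cutoff is not a list entry")
  }
  cpp_shift_distance(as.numeric(d), r_cut, spec$scheme, spec$lambda,
                     spec$epsilon)
}

#' Chain factor of the distance shift
#'
#' The derivative d(modified distance)/d(true distance). Forces on the real
#' coordinates require this factor: the shift's fictitious fourth dimension
#' exerts no force component, so the per-pair energy derivative is simply
#' scaled by it. At `d = 0` with schemes 3 or 4 and lambda > 0 the limit is
#' 0 (the shifted distance is stationary in `d` there); this is returned,
#' not an error.
#'
#' @inheritParams shift_distance
#' @return numeric vector of dimensionless derivatives.
#' @export
shift_chain_factor <- function(d, r_cut, spec) {
  stopifnot(inherits(spec, "alchemical_spec"))
  if (any(d < 0) || any(d >= r_cut)) stop("require 0 <= d < r_cut")
  cpp_chain_factor(as.numeric(d), r_cut, spec$scheme, spec$lambda)
}

#' Apply an alchemical specification to a neighbor list
#'
#' Masked-atom entries are removed first. Every pair classified as modified
#' by the spec's selector then has its distance replaced by
#' [shift_distance()] and its chain factor recorded; all other pairs pass
#' through unchanged with chain factor 1. Entries whose modified distance
#' reaches `r_cut` are dropped from the list (exact for any potential that
#' vanishes at the cutoff), so at lambda = 1 no modified pair remains.
#'
#' @param nl a `neighbor_list` built against the same system.
#' @param system the [particle_system()] the list was built from (supplies
#'   the solute partition for the default selector).
#' @param spec an [alchemical_spec()].
#' @return Object of class `alchemical_neighbor_list`: like the input but
#'   with `modified_distance` and `chain_factor` columns, and the generating
#'   spec attached.
#' @export
apply_alchemy <- function(nl, system, spec) {
  stopifnot(inherits(nl, "neighbor_list"), inherits(spec, "alchemical_spec"))
  n <- n_atoms(system)
  if (length(spec$masked_atoms) && max(spec$masked_atoms) > n) {
    stop("masked_atoms out of range")
  }
  if (!is.null(spec$atom_modes) && length(spec$atom_modes) != n) {
    stop("atom_modes must have one entry per atom")
  }
  out <- mask_atoms(nl, spec$masked_atoms)
  e <- out$entries
  cls <- classify_pairs(e$i, e$j, system, spec)
  e$modified_distance <- e$d
  e$chain_factor <- rep(1, nrow(e))
  # per-pair effective lambda (differs per pair only for the per-atom selector)
  lam_eff <- rep(spec$lambda, nrow(e))
  if (spec$selector == "per-atom" && nrow(e)) {
    mi <- spec$atom_modes[e$i]
    mj <- spec$atom_modes[e$j]
    m <- ifelse(mi > 0, mi, mj)
    lam_eff[m == 2] <- 1 - spec$lambda
  }
  mod <- which(cls == 1L)
  for (le in unique(lam_eff[mod])) {
    idx <- mod[lam_eff[mod] == le]
    e$modified_distance[idx] <- cpp_shift_distance(e$d[idx], nl$r_cut,
                                                   spec$scheme, le,
                                                   spec$epsilon)
    e$chain_factor[idx] <- cpp_chain_factor(e$d[idx], nl$r_cut, spec$scheme,
                                            le)
  }
  keep <- cls >= 0L & e$modified_distance < nl$r_cut
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(entries = e, r_cut = nl$r_cut, spec = spec),
            class = c("alchemical_neighbor_list", "neighbor_list"))
}

#' @export
print.alchemical_neighbor_list <- function(x, ...) {
  cat(sprintf(
    "<alchemical_neighbor_list> %d pairs, r_cut = %g A, scheme %d, lambda = %g\n",
    nrow(x$entries), x$r_cut, x$spec$scheme, x$spec$lambda))
  invisible(x)
}

# classify pairs: -1 excluded, 0 unmodified, 1 modified
classify_pairs <- function(i, j, system, spec) {
  n <- n_atoms(system)
  cls <- integer(length(i))
  if (spec$selector == "solute-solvent") {
    sol <- seq_len(n) %in% system$solute
    cls[xor(sol[i], sol[j])] <- 1L
  } else if (spec$selector == "per-atom") {
    mi <- spec$atom_modes[i]
    mj <- spec$atom_modes[j]
    cls[xor(mi > 0, mj > 0)] <- 1L
    cls[mi > 0 & mj > 0] <- -1L
  }
  cls
}
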