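# shared test fixtures and independent oracles (all generated in code)

KB_TEST <- 0.0019872041
FCONV_TEST <- 418.4

# random box of particles, uniform positions, fixed seed
random_system <- function(n, box = 12, seed = 1, species = "W", mass = 18,
                          solute = integer(0)) {
  set.seed(seed)
  particle_system(matrix(runif(3 * n) * box, n, 3), rep(species, n),
                  box, masses = rep(mass, n), solute = solute)
}

# O(N^2) all-pairs brute-force neighbor oracle, independent of the engine
brute_force_pairs <- function(system, r_cut) {
  n <- n_atoms(system)
  out <- NULL
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, length.out = n - i)) {
      dx <- system$positions[j, ] - system$positions[i, ]
      dx <- dx - system$box * round(dx / system$box)
      d <- sqrt(sum(dx^2))
      if (d < r_cut) out <- rbind(out, c(i, j, d))
    }
  }
  out
}

# analytic shift formulas, written out independently of the implementation
shift_reference <- function(d, r_cut, scheme, lam, eps) {
  switch(scheme,
         d + lam * r_cut,
         d + lam * pmax(0, r_cut - d) + lam * eps,
         sqrt(d^2 + (lam * r_cut)^2),
         sqrt(d^2 + lam * pmax(r_cut^2 - d^2, 0)) + lam * eps)
}

# small solvated toy system shared by several tests
toy_solvated <- function(seed = 5, n_solvent = 30, box = 12) {
  pair <- make_toy_solute_pair()
  solvent <- make_toy_solvent_box(n = n_solvent, box_length = box,
                                  seed = seed)
  list(pair = pair,
       solvated = solvate_system(pair$t1, solvent),
       solvent = solvent)
}

# kinetic energy in kcal/mol from velocities (A/ps) and masses (amu)
kinetic_energy <- function(v, m) sum(0.5 * m * rowSums(v^2)) / FCONV_TEST

# independent BAR oracle: direct maximization of the Fermi-function
# log-likelihood (valid stationarity form for equal sample sizes)
bar_ml_oracle <- function(wf, wr) {
  stopifnot(length(wf) == length(wr))
  nll <- function(f) {
    -(sum(stats::plogis(-(wf - f), log.p = TRUE)) +
        sum(stats::plogis(-(wr + f), log.p = TRUE)))
  }
  stats::optimize(nll, c(-50, 50), tol = 1e-12)$minimum
}
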