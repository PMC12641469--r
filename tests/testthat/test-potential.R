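test_that("energy is a pure function of the neighbor list", {
  m <- default_toy_potential()
  sys <- random_system(2, box = 12, seed = 1)
  empty <- build_neighbor_list(
    particle_system(matrix(numeric(0), 0, 3), character(0), 12), m$r_cut)
  expect_equal(energy(m, empty), 0)
  # a pair just inside the cutoff is switched off to ~0
  near <- particle_system(rbind(c(0, 0, 0), c(m$r_cut - 1e-9, 0, 0)),
                          c("W", "W"), 20)
  expect_lt(abs(energy(m, build_neighbor_list(near, m$r_cut))), 1e-12)
  expect_error(energy(m, build_neighbor_list(random_system(3, 12, 1,
                                                           species = "Xx"),
                                             m$r_cut)),
               "no potential parameters")
})

test_that("list-based energy equals the fused kernel for all schemes and lambdas", {
  m <- default_toy_potential()
  tw <- toy_solvated(seed = 6)
  sys <- tw$solvated
  nl <- build_neighbor_list(sys, m$r_cut)
  for (k in 1:4) {
    for (lam in c(0, 0.3, 0.7, 1)) {
      spec <- alchemical_spec(k, lam)
      e_list <- energy(m, apply_alchemy(nl, sys, spec)) +
        sum(vapply(sys$restraints, restraint_energy, numeric(1),
                   system = sys))
      expect_equal(system_energy(sys, m, spec), e_list, tolerance = 1e-12)
    }
  }
})

test_that("masking an atom is exactly equivalent to deleting it", {
  m <- default_toy_potential()
  sys <- random_system(25, box = 12, seed = 4, solute = 1:3)
  for (lam in c(0, 0.5, 1)) {
    spec_masked <- alchemical_spec(2, lam, masked_atoms = c(2, 11, 20))
    keep <- setdiff(1:25, c(2, 11, 20))
    deleted <- particle_system(sys$positions[keep, ], sys$species[keep],
                               sys$box, sys$masses[keep],
                               solute = match(intersect(sys$solute, keep),
                                              keep))
    spec_plain <- alchemical_spec(2, lam)
    expect_equal(system_energy(sys, m, spec_masked),
                 system_energy(deleted, m, spec_plain))
  }
})

test_that("decoupled-state energy is the sum of isolated subsystem energies", {
  m <- default_toy_potential()
  tw <- toy_solvated(seed = 8)
  sys <- tw$solvated
  ns <- length(sys$solute)
  n <- n_atoms(sys)
  solute_only <- particle_system(sys$positions[1:ns, ], sys$species[1:ns],
                                 sys$box, sys$masses[1:ns], solute = 1:ns,
                                 restraints = sys$restraints)
  solvent_only <- particle_system(sys$positions[(ns + 1):n, ],
                                  sys$species[(ns + 1):n], sys$box,
                                  sys$masses[(ns + 1):n])
  for (k in 1:4) {
    e1 <- system_energy(sys, m, alchemical_spec(k, 1))
    e2 <- system_energy(solute_only, m) + system_energy(solvent_only, m)
    expect_equal(e1, e2)
  }
})

test_that("energy is invariant under rigid translation and atom relabeling", {
  m <- default_toy_potential()
  sys <- random_system(20, box = 12, seed = 10, solute = 1:2)
  e0 <- system_energy(sys, m, alchemical_spec(3, 0.4))
  sys_t <- sys
  sys_t$positions <- sweep(sys$positions, 2, c(3.1, -7.7, 100.2), `+`)
  res_t <- sys_t
  expect_equal(system_energy(res_t, m, alchemical_spec(3, 0.4)), e0,
               tolerance = 1e-10)
  set.seed(2)
  perm <- sample(20)
  sys_p <- particle_system(sys$positions[perm, ], sys$species[perm],
                           sys$box, sys$masses[perm],
                           solute = match(sys$solute, perm))
  expect_equal(system_energy(sys_p, m, alchemical_spec(3, 0.4)), e0,
               tolerance = 1e-10)
})

test_that("analytic forces match central finite differences of the energy", {
  m <- default_toy_potential()
  for (seed in c(21, 22)) {
    sys <- random_system(20, box = 12, seed = seed, solute = 1:4)
    # relax a little so no pair sits on the repulsive wall
    sys$positions <- nlalchemy:::cpp_relax(
      sys$positions, sys$box, rep(0.2, 20), rep(3.0, 20), m$r_cut,
      m$switch_start, 100, 0.05)
    for (k in 1:4) {
      for (lam in c(0, 0.3, 0.7, 1)) {
        spec <- alchemical_spec(k, lam)
        F <- system_forces(sys, m, spec)$forces
        expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-9)
        h <- 1e-5
        idx <- cbind(c(1, 3, 7, 15), c(1, 2, 3, 1))
        for (q in seq_len(nrow(idx))) {
          a <- idx[q, 1]; dim_ <- idx[q, 2]
          sp <- sys
          sp$positions[a, dim_] <- sp$positions[a, dim_] + h
          sm <- sys
          sm$positions[a, dim_] <- sm$positions[a, dim_] - h
          fd <- -(system_energy(sp, m, spec) -
                    system_energy(sm, m, spec)) / (2 * h)
          expect_equal(F[a, dim_], fd,
                       tolerance = 1e-5 * max(1, abs(fd)))
        }
      }
    }
  }
})

test_that("list-path forces agree with the fused kernel", {
  m <- default_toy_potential()
  sys <- random_system(15, box = 12, seed = 31, solute = 1:3)
  sys$positions <- nlalchemy:::cpp_relax(
    sys$positions, sys$box, rep(0.2, 15), rep(3.0, 15), m$r_cut,
    m$switch_start, 100, 0.05)
  nl <- build_neighbor_list(sys, m$r_cut)
  for (k in c(1, 4)) {
    spec <- alchemical_spec(k, 0.6)
    F_r <- forces(m, sys, apply_alchemy(nl, sys, spec))
    F_c <- system_forces(sys, m, spec)$forces  # includes no restraints here
    expect_equal(F_r, F_c, tolerance = 1e-10)
  }
})

test_that("scheme 1 forces equal the pair derivative at the offset distance", {
  m <- default_toy_potential()
  sys <- particle_system(rbind(c(0, 0, 0), c(2.4, 0, 0)), c("W", "W"), 20,
                         solute = 1)
  lam <- 0.37
  F <- system_forces(sys, m, alchemical_spec(1, lam))$forces
  du <- pair_energy(m, 2.4 + lam * m$r_cut, "W", "W",
                    derivative = TRUE)$du
  expect_equal(F[1, 1], du)  # chain factor exactly 1
  expect_equal(F[2, 1], -du)
})

test_that("flat-bottom restraint energy follows its closed form", {
  sys <- particle_system(rbind(c(0, 0, 0), c(3, 0, 0)), c("W", "W"), 20)
  r <- flat_bottom_restraint(2, c(0, 0, 0), r0 = 2, kf = 10)
  expect_equal(restraint_energy(r, sys), 5.0)  # 0.5*10*(3-2)^2
  sys$positions[2, 1] <- 1                      # inside the well
  expect_equal(restraint_energy(r, sys), 0)
  sys$positions[2, 1] <- 2                      # exactly at the boundary
  expect_equal(restraint_energy(r, sys), 0)
  # anchor-atom form: forces act on both partners, energy matches
  sys$positions[2, 1] <- 3.5
  ra <- flat_bottom_restraint(2, 1L, r0 = 2, kf = 10)
  sys2 <- sys
  sys2$restraints <- list(ra)
  m <- default_toy_potential()
  ef <- system_forces(sys2, m)
  expect_equal(ef$energy - system_energy(sys, m), 0.5 * 10 * 1.5^2)
  expect_equal(colSums(ef$forces), c(0, 0, 0), tolerance = 1e-12)
})

test_that("overlapping unmodified atoms raise an instability error in forces", {
  m <- default_toy_potential()
  sys <- particle_system(rbind(c(0, 0, 0), c(0, 0, 0)), c("W", "W"), 20)
  expect_error(system_forces(sys, m), "overlap")
})
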