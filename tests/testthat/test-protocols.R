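test_that("lambda schedules validate and the production preset is exact", {
  s <- lambda_schedule("asfe15")
  expect_length(s, 15)
  expect_equal(s[1], 0)
  expect_equal(s[15], 1)
  expect_equal(s, c(0:9, 11, 13, 15, 17, 19) / 19)
  expect_equal(lambda_schedule("uniform", n = 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(lambda_schedule(values = c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_error(lambda_schedule(values = c(0, 0.7, 0.5, 1)), "increasing")
  expect_error(lambda_schedule(values = c(0, 0.5, 1.2)), "\\[0, 1\\]")
  expect_error(lambda_schedule(values = c(0.1, 0.5, 1)), "start at 0")
})

test_that("cycle-closure arithmetic reproduces the printed worked examples", {
  c1 <- cycle_closure(c(-7.2, 0.4), c(-10.0, 0.1), c(-0.9, 0.0),
                      c(-3.7, 0.0))
  expect_equal(c1$closure, 0.0)
  expect_equal(c1$propagated_error, sqrt(0.17))
  c2 <- cycle_closure(c(-9.4, 0.2), c(-15.3, 0.1), c(4.0, 0.1),
                      c(-1.7, 0.1))
  expect_equal(c2$closure, -0.2, tolerance = 1e-12)
  c0 <- cycle_closure(0, 0, 0, 0)
  expect_equal(c0$closure, 0)
  expect_equal(c0$propagated_error, 0)
  expect_error(cycle_closure(c(-7.2, 0.4), NULL, c(-0.9, 0), c(-3.7, 0)),
               "missing leg")
})

test_that("a ghost solute has zero solvation free energy and a verified-zero gas leg", {
  m <- default_toy_potential()
  solvent <- make_toy_solvent_box(n = 25, box_length = 12, seed = 17)
  ghost <- particle_system(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("G", "G"), 12,
                           masses = c(5, 5), solute = 1:2,
                           restraints = list(
                             flat_bottom_restraint(1, c(0, 0, 0), 0.5, 10),
                             flat_bottom_restraint(2, c(1.5, 0, 0), 0.5, 10)))
  solv <- solvate_system(ghost, solvent, clash_distance = 0)
  st <- sampler_settings(n_steps = 300, save_interval = 10, seed = 1)
  res <- run_asfe(solv, ghost, m, lambda_schedule("uniform", n = 3), st,
                  n_repeats = 2, seeds = c(4, 5), n_equil_steps = 100)
  expect_equal(res$dg, 0, tolerance = 1e-8)
  expect_true(res$gas_verified)
  expect_equal(res$gas_leg_dg, c(0, 0))
})

test_that("dual topology construction validates its inputs", {
  pair <- make_toy_solute_pair()
  dual <- build_dual_topology(pair$t1, pair$t2)
  expect_equal(n_atoms(dual$system), n_atoms(pair$t1) + 1)
  expect_equal(dual$vanish, attr(pair$t1, "variant_atom"))
  expect_equal(dual$appear, n_atoms(pair$t1) + 1)
  # more than one differing site is rejected
  t2bad <- pair$t2
  t2bad$positions[1, 1] <- t2bad$positions[1, 1] + 0.5
  expect_error(build_dual_topology(pair$t1, t2bad), "topology mismatch")
  # unequal variant restraints are rejected (their terms would not cancel)
  t2r <- pair$t2
  t2r$restraints[[4]]$kf <- 99
  expect_error(build_dual_topology(pair$t1, t2r), "restraint definitions")
})

test_that("an identical-site variant pair transforms with zero free energy", {
  m <- default_toy_potential()
  rec <- toy_solute_recipe(site1 = c(-2.9, 0, 0), site2 = c(-2.9, 0, 0))
  pair <- make_toy_solute_pair(rec)
  st <- sampler_settings(n_steps = 800, save_interval = 10, seed = 2,
                         friction = 2)
  res <- run_rsfe_analog(pair$t1, pair$t2, m,
                         lambda_schedule("uniform", n = 5), st,
                         n_repeats = 3, seeds = 11:13,
                         n_equil_steps = 200)
  tol <- 3 * max(res$sd, 0.02)
  expect_lt(abs(res$dg), tol)
})

test_that("swapping the end states negates the relative free energy", {
  m <- default_toy_potential()
  pair <- make_toy_solute_pair()
  st <- sampler_settings(n_steps = 1200, save_interval = 10, seed = 3,
                         friction = 2)
  sched <- lambda_schedule("uniform", n = 6)
  f <- run_rsfe_analog(pair$t1, pair$t2, m, sched, st, n_repeats = 3,
                       seeds = 21:23, n_equil_steps = 300)
  r <- run_rsfe_analog(pair$t2, pair$t1, m, sched, st, n_repeats = 3,
                       seeds = 24:26, n_equil_steps = 300)
  comb <- sqrt(f$sd^2 + r$sd^2)
  expect_lt(abs(f$dg + r$dg), 3 * max(comb, 0.02))
})

test_that("the gas-phase transformation matches a quadrature oracle for a stiff core", {
  # single core atom held by a stiff harmonic anchor; the variant atom
  # interacts with it through the pair potential and is confined by a pure
  # harmonic site restraint. With the core effectively fixed, each end
  # state's variant partition function is a 3D integral evaluated here by
  # direct quadrature.
  m <- default_toy_potential()
  th <- thermo_state(300)
  beta <- th$beta
  core <- c(6, 6, 6)
  site1 <- core + c(3.1, 0, 0)
  site2 <- core + c(0, 3.7, 0)
  build <- function(site) {
    sys <- particle_system(rbind(core, site), c("S", "V"), 14,
                           masses = c(16, 2), solute = 1:2,
                           restraints = list(
                             flat_bottom_restraint(1, core, 0, 400),
                             flat_bottom_restraint(2, site, 0, 8)))
    attr(sys, "variant_atom") <- 2L
    sys
  }
  t1 <- build(site1)
  t2 <- build(site2)
  z_quad <- function(site) {
    g <- seq(-2.2, 2.2, length.out = 45)
    gr <- expand.grid(x = g, y = g, z = g)
    p <- sweep(as.matrix(gr), 2, site, `+`)
    dcore <- sqrt(rowSums(sweep(p, 2, core)^2))
    dsite <- sqrt(rowSums(sweep(p, 2, site)^2))
    u <- pair_energy(m, dcore, rep("S", nrow(p)), rep("V", nrow(p))) +
      0.5 * 8 * dsite^2
    sum(exp(-beta * u)) * diff(g)[1]^3
  }
  dg_oracle <- -log(z_quad(site2) / z_quad(site1)) / beta
  st <- sampler_settings(n_steps = 2500, save_interval = 5, seed = 5,
                         friction = 3)
  res <- run_rsfe_analog(t1, t2, m, lambda_schedule("uniform", n = 6), st,
                         n_repeats = 3, seeds = 31:33, n_equil_steps = 500)
  expect_lt(abs(res$dg - dg_oracle), 3 * max(res$sd, 0.02) + 0.02)
})

test_that("free energy totals are robust to doubling the window count", {
  m <- default_toy_potential()
  pair <- make_toy_solute_pair()
  st <- sampler_settings(n_steps = 1200, save_interval = 10, seed = 7,
                         friction = 2)
  a <- run_rsfe_analog(pair$t1, pair$t2, m,
                       lambda_schedule("uniform", n = 5), st,
                       n_repeats = 3, seeds = 41:43, n_equil_steps = 300)
  b <- run_rsfe_analog(pair$t1, pair$t2, m,
                       lambda_schedule("uniform", n = 9), st,
                       n_repeats = 3, seeds = 44:46, n_equil_steps = 300)
  comb <- sqrt(a$sd^2 + b$sd^2)
  expect_lt(abs(a$dg - b$dg), 3 * max(comb, 0.02))
})
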