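test_that("trajectories are deterministic given a seed and have the right frame count", {
  m <- default_toy_potential()
  sys <- make_toy_solvent_box(n = 15, box_length = 12, seed = 2)
  spec <- alchemical_spec(2, 0)
  st <- sampler_settings(n_steps = 400, save_interval = 1, seed = 77)
  t1 <- run_window(sys, m, spec, st)
  t2 <- run_window(sys, m, spec, st)
  expect_equal(dim(t1$frames)[1], 400)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  st2 <- sampler_settings(n_steps = 403, save_interval = 10, seed = 77)
  expect_equal(dim(run_window(sys, m, spec, st2)$frames)[1], 40)
})

test_that("no force, no velocity, no noise leaves positions unchanged", {
  m <- default_toy_potential()
  sys <- random_system(5, box = 12, seed = 3, species = "G")
  st <- sampler_settings(n_steps = 100, save_interval = 100, friction = 0,
                         seed = 1)
  tr <- run_window(sys, m, alchemical_spec(2, 0), st,
                   velocities = matrix(0, 5, 3))
  expect_equal(tr$final$positions, sys$positions)
})

test_that("thermostatted ideal gas satisfies equipartition at 300 K", {
  m <- default_toy_potential()
  n <- 20
  set.seed(5)
  sys <- particle_system(matrix(runif(3 * n) * 12, n, 3), rep("G", n), 12,
                         masses = rep(10, n))
  th <- thermo_state(300)
  st <- sampler_settings(n_steps = 100, save_interval = 100, friction = 5,
                         seed = NULL, thermo = th)
  set.seed(91)
  v <- maxwell_velocities(sys, th)
  kes <- numeric(200)
  cur <- sys
  for (s in 1:200) {
    tr <- run_window(cur, m, alchemical_spec(2, 0), st, velocities = v)
    cur$positions <- tr$final$positions
    v <- tr$final$velocities
    kes[s] <- kinetic_energy(v, cur$masses) / (3 * n)
  }
  target <- KB_TEST * 300 / 2
  se <- sd(kes) / sqrt(length(kes))   # O-step decorrelates between segments
  expect_lt(abs(mean(kes) - target), 3 * se + 0.002)
})

test_that("frictionless limit conserves total energy (NVE drift bound)", {
  m <- default_toy_potential()
  box <- make_toy_solvent_box(n = 30, box_length = 12, seed = 3)
  st <- sampler_settings(n_steps = 500, timestep = 5e-4, friction = 0,
                         save_interval = 500)
  set.seed(11)
  v <- maxwell_velocities(box, thermo_state(300))
  cur <- box
  etot <- system_energy(cur, m) + kinetic_energy(v, cur$masses)
  drift <- 0
  for (s in 1:20) {   # 1e4 steps total at 0.5 fs
    tr <- run_window(cur, m, alchemical_spec(2, 0), st, velocities = v)
    cur$positions <- tr$final$positions
    v <- tr$final$velocities
    e <- system_energy(cur, m) + kinetic_energy(v, cur$masses)
    drift <- max(drift, abs(e - etot))
  }
  expect_lt(drift / (3 * 30), 1e-3)   # kcal/mol per degree of freedom
})

test_that("a decoupled window has zero solute-solvent interaction in every frame", {
  m <- default_toy_potential()
  tw <- toy_solvated(seed = 12)
  sys <- tw$solvated
  st <- sampler_settings(n_steps = 300, save_interval = 30, seed = 6)
  tr <- run_window(sys, m, alchemical_spec(2, 1), st)
  ns <- length(sys$solute)
  n <- n_atoms(sys)
  for (f in seq_len(dim(tr$frames)[1])) {
    cur <- sys
    cur$positions <- tr$frames[f, , ]
    cur$restraints <- list()   # compare pair interactions only
    e_full <- system_energy(cur, m, alchemical_spec(2, 1))
    e_solute <- system_energy(cur, m,
                              alchemical_spec(2, 1,
                                              masked_atoms = (ns + 1):n))
    e_solvent <- system_energy(cur, m,
                               alchemical_spec(2, 1, masked_atoms = 1:ns))
    expect_equal(e_full, e_solute + e_solvent)
  }
})

test_that("decoupled solvated solute samples the gas-phase ensemble", {
  # intrasolute geometry at lambda = 1 in solvent vs. a plain gas run:
  # distributions of the core-variant distance must be indistinguishable
  m <- default_toy_potential()
  tw <- toy_solvated(seed = 13)
  st <- sampler_settings(n_steps = 6000, save_interval = 10, friction = 2,
                         seed = 21)
  tr_sol <- run_window(tw$solvated, m, alchemical_spec(2, 1), st)
  st$seed <- 22
  tr_gas <- run_window(tw$pair$t1, m,
                       alchemical_spec(2, 0, selector = "none"), st)
  dist_cv <- function(tr, sys) {
    f <- tr$frames[subsample_frames(tr), , , drop = FALSE]
    vapply(seq_len(dim(f)[1]), function(q) {
      minimum_image_displacement(f[q, 1, ], f[q, 4, ], sys$box)$distance
    }, numeric(1))
  }
  d_sol <- dist_cv(tr_sol, tw$solvated)
  d_gas <- dist_cv(tr_gas, tw$pair$t1)
  breaks <- c(0, seq(2.2, 4.2, by = 0.4), Inf)   # pre-registered bins
  tab <- rbind(table(cut(d_sol, breaks)), table(cut(d_gas, breaks)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("an injected force spike triggers the halve-timestep retry path", {
  m <- default_toy_potential()
  box <- make_toy_solvent_box(n = 20, box_length = 12, seed = 4)
  st <- sampler_settings(n_steps = 200, save_interval = 10, seed = 14)
  tr <- run_window(box, m, alchemical_spec(2, 0), st,
                   spike = list(step = 50, magnitude = 1e7))
  expect_true(tr$retried)
  expect_equal(tr$settings$timestep, st$timestep / 2)
  expect_equal(tr$settings$save_interval, st$save_interval * 2L)
  expect_equal(dim(tr$frames)[1], 20)   # frame count preserved
  expect_true(all(is.finite(tr$energies)))
})

test_that("persistent instability errors with window identity", {
  m <- default_toy_potential()
  sys <- particle_system(rbind(c(0, 0, 0), c(1e-8, 0, 0)), c("W", "W"), 20)
  st <- sampler_settings(n_steps = 50, save_interval = 10, seed = 1)
  expect_error(run_window(sys, m, alchemical_spec(2, 0.25), st),
               "unstable")
})

test_that("the Monte Carlo barostat proposes valid, sometimes-accepted volume moves", {
  m <- default_toy_potential()
  box <- make_toy_solvent_box(n = 30, box_length = 12, seed = 6)
  th <- thermo_state(300, pressure = 1)
  set.seed(9)
  acc <- 0
  cur <- box
  for (q in 1:40) {
    out <- mc_barostat_move(cur, m, alchemical_spec(2, 0), th)
    cur <- out$system
    acc <- acc + out$accepted
  }
  expect_gt(acc, 0)
  expect_true(all(cur$box > 2 * m$r_cut))
  expect_error(mc_barostat_move(cur, m, alchemical_spec(2, 0),
                                thermo_state(300)), "pressure")
})
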