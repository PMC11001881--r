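single_basin_chain <- function(n, seed = 1) {
  m <- bead_chain_model(n, seed = seed)
  build_single_basin(m, shadow_contact_map(m))
}

test_that("the zero-temperature zero-friction limit conserves energy", {
  topo <- single_basin_chain(20)
  set.seed(5)
  x0 <- topo$coords_nm + matrix(rnorm(topo$n * 3, sd = 0.002), topo$n)
  tr <- run_langevin(topo, x0,
                     sim_params(temperature = 0, gamma = 0, dt = 2e-4,
                                sample_stride = 100, max_steps = 1e4,
                                stop_rmsd = NULL, seed = 1))
  etot <- tr$epot + tr$ekin
  expect_lt(max(etot) - min(etot), 1e-3)
  expect_equal(tr$termination, "max_steps")
})

test_that("sampled kinetic energy satisfies equipartition at T = 0.67", {
  topo <- single_basin_chain(20)
  tr <- run_langevin(topo, topo$coords_nm,
                     sim_params(temperature = 0.67, gamma = 1, dt = 0.001,
                                sample_stride = 200, max_steps = 3e5,
                                stop_rmsd = NULL, seed = 8))
  ke <- tr$ekin[-(1:100)]                     # burn-in
  per_dof <- ke / (3 * topo$n)
  se <- sd(per_dof) / sqrt(length(per_dof))   # samples ~decorrelated at 0.2 tau
  expect_lt(abs(mean(per_dof) - 0.67 / 2), 3 * se + 0.01)
})

test_that("time-averaged temperature is controlled on a 100-atom system", {
  topo <- single_basin_chain(100, seed = 3)
  tr <- run_langevin(topo, topo$coords_nm,
                     sim_params(temperature = 0.67, gamma = 1, dt = 0.001,
                                sample_stride = 200, max_steps = 3e5,
                                stop_rmsd = NULL, seed = 9))
  t_inst <- 2 * tr$ekin[-(1:150)] / (3 * topo$n)
  expect_lt(abs(mean(t_inst) - 0.67) / 0.67, 0.02)
})

test_that("trajectories are reproducible per seed and diverge across seeds", {
  sys <- toy_system()
  p <- sim_params(max_steps = 2e4, dt = 0.001, stop_rmsd = NULL, seed = 5)
  a <- run_langevin(sys$dual, sys$xa, p)
  b <- run_langevin(sys$dual, sys$xa, p)
  p2 <- p; p2$seed <- 6L
  c2 <- run_langevin(sys$dual, sys$xa, p2)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c2$frames))
  ## frame times increase with the sampling spacing
  expect_equal(diff(a$times), rep(p$sample_stride * p$dt,
                                  length(a$times) - 1))
})

test_that("the RMSD stop criterion terminates a run started at its target", {
  sys <- toy_system()
  sw <- which(atoms_in_group(sys$toy$model_a, sys$toy$groups, "KOW"))
  p <- sim_params(temperature = 0.3, dt = 0.001, max_steps = 1e4,
                  stop_rmsd = 0.2, stop_selection = sw,
                  stop_reference = sys$xb[sw, ], seed = 2)
  tr <- run_langevin(sys$dual, sys$xb, p)
  expect_equal(tr$termination, "stop_rmsd")
  expect_equal(n_frames(tr), 1)
})

test_that("best-fit RMSD matches an independent Kabsch evaluation", {
  set.seed(12)
  ref <- matrix(rnorm(60), 20, 3)
  expect_equal(rmsd_fit(ref, ref), 0, tolerance = 1e-12)
  R <- duobasin:::rotation_about_axis(c(1, 1, 0), 73)
  expect_lt(rmsd_fit(ref %*% t(R), ref), 1e-9)
  frame <- ref
  frame[1:10, ] <- frame[1:10, ] + 0.1
  expect_equal(rmsd_fit(frame, ref), oracle_kabsch_rmsd(frame, ref),
               tolerance = 1e-9)
  monitor <- rmsd_to(ref, 1:20)
  expect_equal(monitor(frame), rmsd_fit(frame, ref), tolerance = 1e-12)
})

test_that("basin A is stable at low temperature and switches when heated", {
  sys <- toy_system(toy_sbm_params())
  defs <- toy_op_defs(sys$toy, sys$map_a, sys$map_b)
  ## low T: the helical, anchor-docked state persists
  tr <- run_langevin(sys$dual, sys$xa,
                     sim_params(temperature = 0.3, dt = 0.001,
                                sample_stride = 2000, max_steps = 1e7,
                                stop_rmsd = NULL, seed = 11))
  s <- order_parameters(tr, defs)
  expect_gte(max(s$time), 1e4)
  expect_true(all(s$q_a > 0.8))
  ## at the toy's switching temperature, most replicas reach state B
  sw <- which(atoms_in_group(sys$toy$model_a, sys$toy$groups, "KOW"))
  switched <- 0
  for (sd in 1:20) {
    p <- sim_params(temperature = 1.0, dt = 0.001, sample_stride = 500,
                    max_steps = 8e5, stop_rmsd = 0.2, stop_selection = sw,
                    stop_reference = sys$xb[sw, ], seed = 500 + sd)
    tr <- run_langevin(sys$dual, sys$xa, p)
    if (tr$termination == "stop_rmsd") switched <- switched + 1
  }
  expect_gte(switched, 10)
})
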