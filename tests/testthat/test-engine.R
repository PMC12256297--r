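test_that("AH potential is continuous, reduces to LJ at lambda 1", {
  sig <- 5.0; eps <- 0.2
  rmin <- 2^(1 / 6) * sig
  for (lam in c(0, 0.3, 0.7, 1)) {
    lo <- ah_potential(rmin - 1e-9, sig, lam, eps)
    hi <- ah_potential(rmin + 1e-9, sig, lam, eps)
    expect_equal(lo, hi, tolerance = 1e-6)
    expect_equal(ah_potential(rmin, sig, lam, eps), -lam * eps,
                 tolerance = 1e-12)
  }
  r <- seq(4.2, 15, by = 0.37)
  lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  expect_equal(ah_potential(r, sig, 1, eps), lj, tolerance = 1e-12)
  expect_error(ah_potential(0, sig, 1), "positive")
})

test_that("AH outer branch matches the closed form lambda*LJ", {
  # independent evaluation at lambda 0.5, sigma 6, r 7
  eps <- 0.2
  ref <- 0.5 * 4 * eps * ((6 / 7)^12 - (6 / 7)^6)
  expect_equal(ah_potential(7, 6, 0.5, eps), ref, tolerance = 1e-12)
  # energy-shifted form vanishes at the cutoff and approaches it below
  v <- ah_potential(c(19.999999, 20, 25), 6, 0.5, eps, cutoff = 20)
  expect_equal(v[1], 0, tolerance = 1e-6)
  expect_equal(v[2:3], c(0, 0))
})

test_that("DH potential handles zero charge, zero screening, closed form", {
  expect_equal(dh_potential(5, 0, 1, kappa = 0.1), 0)
  # kappa = 0 is unscreened Coulomb
  expect_equal(dh_potential(7, 1, -1, kappa = 0, dielectric = 80),
               -332.0637 / (80 * 7), tolerance = 1e-12)
  expect_error(dh_potential(-1, 1, 1, 0.1), "positive")
})

test_that("cell-list energies and forces match the brute-force oracle", {
  cfg <- test_config()
  for (seed in 1:20) {
    st <- random_system(n = 60, box = c(72, 80, 90), seed = seed,
                        chain_len = ifelse(seed %% 2, 1, 10),
                        protein_only = FALSE)
    eng <- compute_forces(st, default_ps, cfg)
    ora <- brute_force_oracle(st, default_ps, cfg)
    expect_equal(eng$energy$e_hydropathy, ora$e_hydropathy,
                 tolerance = 1e-9)
    expect_equal(eng$energy$e_elec, ora$e_elec, tolerance = 1e-9)
    expect_equal(eng$energy$e_bond, ora$e_bond, tolerance = 1e-9)
    expect_equal(eng$forces, ora$forces, tolerance = 1e-9)
  }
})

test_that("single isolated bead feels zero force", {
  st <- random_system(n = 1, box = c(80, 80, 80), seed = 1)
  out <- compute_forces(st, default_ps, test_config())
  expect_equal(out$forces, matrix(0, 1, 3))
})

test_that("forces obey Newton's third law and translation invariance", {
  cfg <- test_config()
  st <- small_system(n_res = 30, n_chains = 2, seed = 4)
  out <- compute_forces(st, default_ps, cfg)
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-9)
  # rigid shift (with rewrap) changes nothing
  st2 <- translate_state(st, c(13.7, -8.1, 42.9))
  out2 <- compute_forces(st2, default_ps, cfg)
  expect_equal(out2$energy, out$energy, tolerance = 1e-9)
  expect_equal(out2$forces, out$forces, tolerance = 1e-6)
  # shifting one bead by +L along each axis changes nothing
  st3 <- st
  st3$coords[5, ] <- st3$coords[5, ] + st3$box
  out3 <- compute_forces(st3, default_ps, cfg)
  expect_equal(out3$energy, out$energy, tolerance = 1e-12)
})

test_that("cutoff beyond half the box edge is rejected", {
  st <- small_system(n_res = 15, n_chains = 1, seed = 1, box_spacing = 30)
  expect_error(compute_forces(st, default_ps, test_config()),
               "half the smallest box edge")
})

test_that("trajectory bookkeeping matches the writer convention", {
  cfg <- test_config(n_steps = 1000, write_interval = 100)
  st <- small_system(n_res = 20, n_chains = 2, seed = 2)
  traj <- run_simulation(st, default_ps, cfg)
  expect_equal(traj$n_frames, 10)
  expect_equal(traj$energies$step, seq(100, 1000, by = 100))
  expect_equal(traj$frame_interval, cfg$dt * 100)
  # zero-step run: no frames, state retrievable
  t0 <- run_simulation(st, default_ps, cfg, n_steps = 0)
  expect_equal(t0$n_frames, 0)
  expect_equal(dim(t0$system$coords), dim(st$coords))
})

test_that("same seed and config give bit-identical trajectories", {
  cfg <- test_config(n_steps = 300, write_interval = 100, seed = 1234)
  st <- small_system(n_res = 25, n_chains = 2, seed = 8)
  t1 <- run_simulation(st, default_ps, cfg)
  t2 <- run_simulation(st, default_ps, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  cfg2 <- test_config(n_steps = 300, write_interval = 100, seed = 1235)
  t3 <- run_simulation(st, default_ps, cfg2)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("zero forces, zero velocity, T = 0 leaves positions fixed", {
  # two isolated single-bead chains far beyond every cutoff
  ch <- build_chain("G", "protein")
  st <- replicate_grid(ch, matrix(0, 1, 3), c(2, 1, 1), 90)
  st$vel <- matrix(0, 2, 3)
  cfg <- test_config(temperature = 0, friction = 0)
  out <- langevin_step(st, default_ps, cfg)
  expect_equal(out$coords, st$coords %% 180, tolerance = 1e-14)
})

test_that("compression shrinks the box monotonically to the exact target", {
  cfg <- test_config()
  st <- small_system(n_res = 20, n_chains = 2, seed = 3, box_spacing = 100)
  st <- maxwell_velocities(st, default_ps, 300, 5)
  # run in small bites so the box path is observable
  boxes <- matrix(NA, 10, 3)
  cur <- st
  start_box <- st$box
  target <- c(120, 80, 90)
  for (k in 1:10) {
    step_target <- start_box + (target - start_box) * k / 10
    cur <- compress(cur, default_ps, cfg, step_target, n_steps = 50)
    boxes[k, ] <- cur$box
    expect_true(all(cur$coords >= 0 & cur$coords <=
                      matrix(cur$box, nrow(cur$coords), 3, byrow = TRUE)))
  }
  expect_true(all(diff(boxes[, 1]) <= 0))
  expect_true(all(diff(boxes[, 2]) <= 0))
  expect_equal(cur$box, target, tolerance = 1e-12)
  # target == current: box untouched
  same <- compress(cur, default_ps, cfg, cur$box, n_steps = 20)
  expect_equal(same$box, cur$box)
  # target above current errors
  expect_error(compress(cur, default_ps, cfg, cur$box * 2, 10),
               "exceeds")
})

test_that("chain concentration follows Avogadro arithmetic", {
  expect_equal(concentration(1, c(10, 10, 10)),
               1 / (1000 * 1e-27 * 6.02214076e23), tolerance = 1e-12)
  expect_equal(concentration(0, c(100, 100, 100)), 0)
  expect_error(concentration(10, c(0, 10, 10)), "positive")
})

test_that("energy-convergence check distinguishes plateau from drift", {
  expect_true(check_convergence(rep(-500, 100), window = 50))
  drift <- seq(-100, -400, length.out = 100)
  expect_false(check_convergence(drift, window = 50, tol = 0.05))
  noisy <- -500 + hpslab:::with_seed(31, rnorm(200, sd = 5))
  expect_true(check_convergence(noisy, window = 100, tol = 0.05))
  expect_error(check_convergence(1:10, window = 20), "two windows")
})
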