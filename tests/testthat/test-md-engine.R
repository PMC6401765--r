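test_that("integrator config validates its inputs", {
  expect_error(integrator_config(dt = 0), "dt")
  expect_error(integrator_config(sample_interval = 0), "sample_interval")
  cfg <- integrator_config(thermostat = "nose_hoover", seed = 5)
  expect_equal(cfg$thermostat, "nose_hoover")
  expect_identical(cfg$seed, 5L)
})

test_that("same config and seed give bit-identical trajectories", {
  top <- chain_topology(16, "diblock", 20)
  st <- initial_conformation(top, velocities = "zero")
  cfg <- integrator_config(n_equil = 200, n_prod = 1000,
                           sample_interval = 100, seed = 99)
  t1 <- integrate_chain(st, cfg = cfg)
  t2 <- integrate_chain(st, cfg = cfg)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$pe, t2$pe)
  # and frame times are strictly increasing
  expect_true(all(diff(t1$times) > 0))
})

test_that("NVE energy drift is bounded for a free chain", {
  set.seed(3)
  top <- chain_topology(50, "flexible")
  st <- initial_conformation(top, velocities = "maxwell", T = 1)
  tr <- integrate_chain(st, cfg = integrator_config(
    thermostat = "none", n_equil = 0, n_prod = 10000, sample_interval = 50))
  E <- tr$pe + tr$ke
  expect_lt(max(E) - min(E), 1e-3 * abs(mean(E)))
})

test_that("thermostats satisfy equipartition", {
  # single free bead, Langevin: <KE> = 3/2 kT
  top1 <- chain_topology(2, "flexible")   # minimal chain; bead pair
  st <- initial_conformation(top1, velocities = "zero")
  tr <- integrate_chain(st, cfg = integrator_config(
    n_equil = 5000, n_prod = 100000, sample_interval = 20, seed = 17))
  ke_per_bead <- mean(tr$ke) / 2
  se <- nanopost:::batch_se(tr$ke / 2, 20)
  expect_lt(abs(ke_per_bead - 1.5), max(3 * se, 0.02))

  # interacting chain under Nose-Hoover at the reference relaxation time
  top <- chain_topology(20, "semiflexible", 20)
  st2 <- initial_conformation(top, velocities = "maxwell", T = 1)
  tr2 <- integrate_chain(st2, cfg = integrator_config(
    thermostat = "nose_hoover", tau_T = 0.1,
    n_equil = 20000, n_prod = 150000, sample_interval = 50, seed = 18))
  ke2 <- mean(tr2$ke) / 20
  se2 <- nanopost:::batch_se(tr2$ke / 20, 20)
  expect_lt(abs(ke2 - 1.5), max(3 * se2, 0.03))
})

test_that("free-chain bond length equilibrates near 0.97 sigma", {
  top <- chain_topology(40, "flexible")
  set.seed(4)
  st <- initial_conformation(top, velocities = "maxwell", T = 1)
  tr <- integrate_chain(st, cfg = integrator_config(
    n_equil = 20000, n_prod = 120000, sample_interval = 200, seed = 23))
  bl <- apply(tr$positions, 3, function(p) mean(sqrt(rowSums(diff(p)^2))))
  expect_equal(mean(bl), 0.97, tolerance = 0.011)
})

test_that("phantom-chain turn-angle average matches the Boltzmann quadrature", {
  # independent oracle: numerical quadrature of <cos gamma> under the
  # bending weight exp(b cos gamma)
  oracle <- quadrature_cos_turn(20)
  set.seed(5)
  top <- chain_topology(50, "semiflexible", 20)
  ff <- forcefield_params(pair_wca = FALSE)
  c1 <- replicate(3, {
    st <- initial_conformation(top, velocities = "maxwell",
                               conformation = "wlc")
    tr <- integrate_chain(st, ff, integrator_config(
      n_equil = 10000, n_prod = 80000, sample_interval = 200))
    nanopost:::bond_orientation_correlation(tr, NULL, 1)$C
  })
  expect_equal(mean(c1), oracle, tolerance = 0.02)
})

test_that("mid-run overstretch aborts with the offending step", {
  top <- chain_topology(2, "flexible")
  st <- as_test_state(rbind(c(0, 0, 0), c(1.3, 0, 0)), top)
  st$velocities <- rbind(c(-10, 0, 0), c(10, 0, 0))
  expect_error(
    integrate_chain(st, cfg = integrator_config(
      thermostat = "none", n_equil = 0, n_prod = 1000, sample_interval = 10)),
    "overstretch.*step")
})

test_that("run_experiment is reproducible and records replica seeds", {
  cfg <- default_config(N = 12, d_p = 6.9, n_equil = 200, n_prod = 1000,
                        sample_interval = 200, replicas = 3, seed = 7)
  out <- withr::local_tempdir()
  r1 <- run_experiment(cfg, out_dir = out)
  expect_length(unique(r1$manifest$seeds), 3)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_length(list.files(out, pattern = "replica-.*xyz"), 3)
  r2 <- run_experiment(cfg)
  for (k in 1:3)
    expect_identical(r1$trajectories[[k]]$positions,
                     r2$trajectories[[k]]$positions)
})
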