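test_that("scalar energy terms reproduce their closed forms", {
  # WCA: zero at and beyond the cutoff, epsilon at r = sigma
  expect_equal(wca_pair_energy(2^(1/6)), 0)
  expect_equal(wca_pair_energy(1), 1)
  expect_equal(wca_pair_energy(2), 0)
  expect_error(wca_pair_energy(0), class = "nanopost_overlap")

  # post term is the WCA form at the surface gap
  expect_equal(post_energy(5 + 2^(1/6), D_p = 10), 0)
  expect_equal(post_energy(6, D_p = 10), 1)
  expect_equal(post_energy(0.8, D_p = 0), wca_pair_energy(0.8))
  expect_error(post_energy(4.9, D_p = 10), class = "nanopost_overlap")

  # FENE: ln(1) = 0 at l = 0; frozen value at the equilibrium bond length
  expect_equal(fene_energy(0), 0)
  expect_equal(fene_energy(0.97), -0.5 * 30 * 2.25 * log(1 - (0.97 / 1.5)^2))
  expect_equal(fene_energy(0.97), 18.28, tolerance = 1e-3)
  expect_gt(fene_energy(1.5 * (1 - 1e-14)), 1e3)  # divergence at R_o
  expect_error(fene_energy(1.5), class = "nanopost_overstretch")

  # bending: zero for a straight chain, b*kT at a right angle
  expect_equal(bending_energy(pi, 20), 0)
  expect_equal(bending_energy(pi / 2, 20), 20)
  expect_equal(bending_energy(runif(5, 0, pi), 0), rep(0, 5))
})

test_that("total energy assembles the term sums", {
  # bonded pair beyond the WCA cutoff: FENE only
  top2 <- chain_topology(2, "flexible")
  st <- as_test_state(rbind(c(0, 0, 0), c(1.3, 0, 0)), top2)
  ef <- total_energy_and_forces(st)
  expect_equal(ef$components[["wca"]], 0)          # beyond WCA cutoff
  expect_equal(ef$components[["fene"]], fene_energy(1.3))

  # straight 3-bead semi-flexible rod: bending exactly zero
  top3 <- chain_topology(3, "semiflexible", 20)
  rod <- as_test_state(cbind(c(0, 0.97, 1.94), 0, 0), top3)
  ef3 <- total_energy_and_forces(rod)
  expect_equal(ef3$components[["bend"]], 0)
  expect_equal(ef3$energy, 2 * (fene_energy(0.97) + wca_pair_energy(0.97)),
               tolerance = 1e-12)
})

test_that("two-bead overstretch raises the classed abort signal", {
  top2 <- chain_topology(2, "flexible")
  st <- as_test_state(rbind(c(0, 0, 0), c(1.6, 0, 0)), top2)
  expect_error(total_energy_and_forces(st), class = "nanopost_overstretch")
})

test_that("forces are exact negative gradients of every term", {
  set.seed(7)
  a <- nanopost_array(6, d_p = 3.5)
  configs <- list(
    # free diblock blob: WCA + FENE + bending all active
    list(top = chain_topology(10, "diblock", 20), array = NULL,
         pos = cbind(cumsum(c(0, runif(9, 0.85, 1.05))),
                     rnorm(10, 0, 0.35), rnorm(10, 0, 0.35))),
    # semi-flexible chain near posts: post forces active
    list(top = chain_topology(8, "semiflexible", 20), array = a,
         pos = cbind(cumsum(c(0, runif(7, 0.9, 1.0))),
                     3 + rnorm(8, 0, 0.5), 3 + rnorm(8, 0, 0.5))),
    # phantom chain: bonded WCA + FENE + bending only
    list(top = chain_topology(8, "semiflexible", 20), array = NULL,
         pos = cbind(cumsum(c(0, runif(7, 0.9, 1.0))),
                     rnorm(8, 0, 0.3), rnorm(8, 0, 0.3)),
         ff = forcefield_params(pair_wca = FALSE)))
  for (cc in configs) {
    ff <- if (is.null(cc$ff)) forcefield_params() else cc$ff
    st <- as_test_state(cc$pos, cc$top, cc$array)
    ef <- total_energy_and_forces(st, ff)
    g <- numeric_gradient(st, ff)
    expect_equal(ef$forces, -g, tolerance = 1e-6)
  }
})

test_that("post forces have no x component and lattice translations are exact", {
  set.seed(8)
  a <- nanopost_array(7, d_p = 4.5)
  top <- chain_topology(12, "flexible")
  # chain running along x at ~0.9 sigma surface gap from the post at (0,0),
  # inside the bead-post interaction range
  pos <- cbind(cumsum(c(0, runif(11, 0.9, 1.0))),
               1.9 + rnorm(12, 0, 0.1), 1.9 + rnorm(12, 0, 0.1))
  st <- as_test_state(pos, top, a)
  with_posts <- total_energy_and_forces(st)
  free <- total_energy_and_forces(as_test_state(pos, top, NULL))
  # posts are x-invariant: x-forces identical with and without the array
  expect_identical(with_posts$forces[, 1], free$forces[, 1])

  # rigid translation along x and by one lattice constant in y/z
  for (shift in list(c(3.21, 0, 0), c(0, 7, 0), c(0, 0, -14), c(1, 7, 7))) {
    moved <- st
    moved$positions <- sweep(pos, 2, shift, "+")
    efm <- total_energy_and_forces(moved)
    expect_equal(efm$energy, with_posts$energy, tolerance = 1e-12)
    expect_equal(efm$forces, with_posts$forces, tolerance = 1e-9)
  }
})

test_that("verlet neighbour list reproduces the all-pairs energy bit-identically", {
  set.seed(9)
  for (N in c(20, 100)) {
    top <- chain_topology(N, "flexible")
    pos <- cbind(cumsum(c(0, runif(N - 1, 0.85, 1.05))),
                 cumsum(rnorm(N, 0, 0.3)), cumsum(rnorm(N, 0, 0.3)))
    st <- as_test_state(pos, top)
    ev <- total_energy_and_forces(st, neighbour = "verlet")
    ea <- total_energy_and_forces(st, neighbour = "all")
    expect_identical(ev$energy, ea$energy)
    expect_identical(ev$components, ea$components)
    expect_identical(ev$forces, ea$forces)
  }
})
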