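test_that("axial span matches analytic fixtures and block subsets work", {
  rod <- make_fixture("rod", N = 11, l = 0.97)
  expect_equal(axial_span(rod)$mean, rod$expected$span)
  expect_equal(axial_span(rod, 1)$mean, 0)              # single bead

  # synthetic diblock frame: flexible block compact, semi-flexible extended
  top <- chain_topology(8, "diblock", 20)
  pos <- cbind(c(0, 0.1, 0.2, 0.3, 1, 3, 5, 7), 0, 0)
  tr <- as_test_traj(pos, topology = top)
  expect_equal(axial_span(tr, "flexible")$mean, 0.3)
  expect_equal(axial_span(tr, "semiflexible")$mean, 6)
  expect_equal(axial_span(tr)$mean, 7)
  expect_error(axial_span(tr, integer(0)), class = "nanopost_subset_error")
})

test_that("gyration components resolve anisotropy correctly", {
  # two beads d apart along x
  two <- as_test_traj(rbind(c(0, 0, 0), c(3, 0, 0)))
  g <- gyration_components(two)
  expect_equal(g$Rg_par, 1.5)
  expect_equal(g$Rg_perp, 0)

  # discrete rod: exact second moment l^2 (N^2 - 1)/12
  rod <- make_fixture("rod", N = 11, l = 0.97)
  gr <- gyration_components(rod)
  expect_equal(gr$Rg_par, sqrt(0.97^2 * (11^2 - 1) / 12))
  expect_equal(gr$Rg_perp, 0)

  # isotropic cloud: components agree within sampling error
  set.seed(11)
  cloud <- as_test_traj(array(rnorm(3000), dim = c(100, 3, 10)))
  gc <- gyration_components(cloud)
  expect_equal(gc$Rg_par, gc$Rg_perp, tolerance = 0.1)

  # per-frame component identity Rg^2 = Rgx^2 + Rgy^2 + Rgz^2 against a
  # direct evaluation of the full gyration radius
  for (k in 1:10) {
    p <- cloud$positions[, , k]
    rg2_direct <- mean(rowSums(sweep(p, 2, colMeans(p))^2))
    expect_equal(sum(gc$per_frame[k, ]), rg2_direct, tolerance = 1e-12)
  }
  expect_error(gyration_components(two, 1), class = "nanopost_subset_error")
})

test_that("occupation number counts distinct cells and is lattice invariant", {
  a <- nanopost_array(12, d_p = 6.9)
  one <- make_fixture("cell_filling", cells = rbind(c(0, 0)), array = a)
  expect_equal(occupation_number(one)$mean, 1)
  two <- make_fixture("cell_filling", cells = rbind(c(0, 0), c(1, 0)),
                      array = a)
  expect_equal(occupation_number(two)$mean, 2)
  dup <- make_fixture("cell_filling",
                      cells = rbind(c(0, 0), c(0, 0), c(2, 3)), array = a)
  expect_equal(occupation_number(dup)$mean, 2)

  # lattice translation of the whole configuration leaves n unchanged
  set.seed(12)
  pos <- cbind(rnorm(40, 0, 3), runif(40, 0, 36), runif(40, 0, 36))
  tr <- as_test_traj(pos, array = a)
  n0 <- occupation_number(tr)$mean
  for (shift in list(c(12, 0), c(-24, 36), c(60, -12))) {
    moved <- pos
    moved[, 2] <- moved[, 2] + shift[1]
    moved[, 3] <- moved[, 3] + shift[2]
    expect_equal(occupation_number(as_test_traj(moved, array = a))$mean, n0)
  }
  # a minimum-bead threshold is available
  expect_lte(occupation_number(tr, min_beads = 3)$mean, n0)
})

test_that("structure factor obeys its exact limits and closed forms", {
  q <- exp(seq(log(0.05), log(40), length.out = 60))

  # single bead: S(q) = 1 everywhere
  single <- as_test_traj(matrix(c(0, 0, 0), 1, 3))
  expect_equal(structure_factor(single, q = q)$S, rep(1, 60))

  # two beads at unit distance: closed two-term sum
  two <- make_fixture("two_bead", r = 1)
  S2 <- structure_factor(two, q = q)$S
  expect_equal(S2, two$expected$S(q), tolerance = 1e-12)

  # q -> 0 limit 1 and large-q plateau 1/N on a random blob
  set.seed(13)
  blob <- as_test_traj(matrix(rnorm(60, 0, 2), 20, 3))
  Sb <- structure_factor(blob, q = c(1e-6, 500))$S
  expect_equal(Sb[1], 1, tolerance = 1e-9)
  expect_equal(Sb[2], 1 / 20, tolerance = 5e-3)
})

test_that("histogram-accelerated S(q) matches the direct double sum", {
  set.seed(14)
  pos <- array(rnorm(200 * 3 * 4, 0, 3), dim = c(200, 3, 4))
  tr <- as_test_traj(pos)
  q <- exp(seq(log(0.1), log(2 * pi / 0.5), length.out = 50))
  Sd <- structure_factor(tr, q = q, method = "direct")$S
  Sh <- structure_factor(tr, q = q, method = "histogram")$S
  expect_equal(Sh, Sd, tolerance = 1e-6)
})

test_that("persistence estimator recovers a known P and handles edge cases", {
  set.seed(15)
  fx <- make_fixture("wlc_correlated_bonds", N = 150, P = 19, l = 0.97,
                     n_frames = 800)
  est <- persistence_length(fx, k_max = 20)
  expect_equal(est$P, 19, tolerance = 0.02)

  # rigid rod: correlations all 1, divergent P via the defined contract
  rod <- make_fixture("rod", N = 30, l = 0.97)
  expect_equal(persistence_length(rod)$P, Inf)

  # white-noise bond directions: correlations not positive -> failure
  set.seed(16)
  rw <- make_fixture("wlc_correlated_bonds", N = 60, P = 0.2, l = 1,
                     n_frames = 5)
  expect_error(persistence_length(rw, k_max = 10),
               class = "nanopost_fit_error")
})

test_that("span-scaling fit recovers exact power laws", {
  d_c <- c(4, 6, 8, 12)
  expect_equal(fit_span_scaling(d_c, 100 * d_c^(-2/3))$x, 2/3)
  expect_equal(fit_span_scaling(d_c, 55 * d_c^(-1))$x, 1)
  expect_error(fit_span_scaling(c(4, 6), c(1, 2)),
               class = "nanopost_fit_error")
})
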