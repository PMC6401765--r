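test_that("channel free energies reproduce their closed forms", {
  # prefactors
  expect_equal(odijk_channel_free_energy(1, 1, 1), 2.2072)
  expect_equal(degennes_channel_free_energy(1, 1, 1, 1), 4.0)
  # hand evaluations
  expect_equal(odijk_channel_free_energy(100, 19.23, 2),
               2.2072 * 100 * 19.23^(-1/3) * 2^(-2/3))
  expect_equal(odijk_channel_free_energy(100, 19.23, 2), 51.89,
               tolerance = 2e-4)
  expect_equal(degennes_channel_free_energy(100, 19.23, 0.97, 10), 22.86,
               tolerance = 3e-4)
  # extensivity in L and scaling in D
  L <- runif(1, 1, 50)
  expect_equal(odijk_channel_free_energy(2 * L, 5, 2),
               2 * odijk_channel_free_energy(L, 5, 2))
  expect_equal(degennes_channel_free_energy(L, 5, 1, 2),
               degennes_channel_free_energy(L, 5, 1, 1) * 2^(-5/3))
  # strictly decreasing in the confining width
  D <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(odijk_channel_free_energy(10, 5, D)) < 0))
  expect_true(all(diff(degennes_channel_free_energy(10, 5, 1, D)) < 0))
  expect_error(odijk_channel_free_energy(-1, 1, 1),
               class = "nanopost_theory_error")
})

test_that("slit free energy is half the channel value", {
  expect_equal(slit_free_energy(4.0), 2.0)
  expect_equal(slit_free_energy(2.2072), 1.1036)
  expect_equal(slit_free_energy(0), 0)
})

test_that("semi-flexible transition ratio: closed form and numerical root agree", {
  # reference parameters of the b = 20 chain in the w = 2 array
  expect_equal(semiflexible_transition_ratio(19.23, 2, 0.97), 4.63,
               tolerance = 1e-3)
  # prefactor isolation
  expect_equal(semiflexible_transition_ratio(3, 3, 3), 2.165)
  # closed form vs the independent equal-free-energy root, several
  # parameter sets: agreement within the 0.5% rounding of the prefactor
  set.seed(21)
  for (rep in 1:5) {
    P <- runif(1, 5, 60); w <- runif(1, 1, 6); a <- runif(1, 0.5, 1.5)
    closed <- semiflexible_transition_ratio(P, w, a)
    root <- transition_ratio_root(P, w, a, L = runif(1, 10, 500),
                                  regime = "semiflexible")
    expect_equal(closed, root, tolerance = 5e-3)
  }
})

test_that("flexible transition ratio is the parameter-free constant 2^(3/5)", {
  expect_equal(flexible_transition_ratio(), 2^(3/5))
  expect_equal(flexible_transition_ratio(), 1.52, tolerance = 3e-3)
  expect_equal(flexible_transition_ratio(), exp(0.6 * log(2)))
  # perturbing every parameter of the underlying equal-energy equation
  # leaves the numerical root unchanged
  set.seed(22)
  for (rep in 1:5) {
    root <- transition_ratio_root(P = runif(1, 1, 50), w = runif(1, 0.5, 5),
                                  a = runif(1, 0.5, 2), L = runif(1, 1, 100),
                                  regime = "flexible")
    expect_equal(root, 2^(3/5), tolerance = 1e-9)
  }
})

test_that("detect_transition interpolates occupation curves", {
  # sharp step located by a tight grid around F0
  F0 <- 0.59
  Fs <- seq(0.5, 0.7, by = 0.001)
  n <- ifelse(Fs < F0, 2, 1)   # n decreases with filling fraction
  expect_equal(unname(detect_transition(Fs, n)[1]), F0, tolerance = 2e-3)

  # linear ramp: exact interpolation at the 1 + delta crossing
  x <- seq(1, 5, by = 1)
  n2 <- 0.5 + 0.25 * x          # crosses 1.05 at x = 2.2
  expect_equal(unname(detect_transition(x, n2)[1]), 2.2)

  # both coordinates interpolated at once
  curve <- data.frame(F = c(0.70, 0.65, 0.60, 0.55),
                      dcw = c(6.5, 5.5, 4.5, 3.5))
  n3 <- c(1.00, 1.02, 1.08, 1.30)
  tra <- detect_transition(curve, n3)
  expect_equal(unname(tra["F"]), 0.625)
  expect_equal(unname(tra["dcw"]), 5.0)

  # flat curve below threshold: classed no-transition signal
  expect_error(detect_transition(1:4, rep(1, 4)),
               class = "nanopost_no_transition")
})
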