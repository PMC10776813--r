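# The compiled trace integrator must agree with the pure-R reference step
# and with the closed-form solution of the single-bin two-state system.

test_that("compiled engine reproduces the R reference step exactly", {
  grid <- strain_grid()
  pars <- fibre_params("bag")
  dt <- 1e-4
  n <- 400
  # a wiggly commanded length exercising both advection directions
  time <- (seq_len(n) - 1) * dt
  len <- 1300 + 30 * time * sin(2 * pi * 8 * time)
  proto <- data.frame(time_s = time, length_nm = len, pCa = 6.4)

  tr <- simulate_fibre(proto, pars, dt = dt, grid = grid)

  st <- fibre_state(pars, grid, hs_length = len[1])
  Ca <- pca_to_molar(6.4)
  for (i in seq_len(n - 1)) {
    st <- advance(st, dt, approx(time, len, xout = i * dt)$y, Ca, pars,
                  grid)
  }
  m <- nrow(tr)
  expect_equal(tr$actin_activated[m], st$actin_activated, tolerance = 1e-12)
  expect_equal(tr$cb_attached[m], st$cb_attached, tolerance = 1e-12)
  expect_equal(tr$stress[m], st$stress, tolerance = 1e-9)
  expect_equal(attr(tr, "final_state")$bound_myosin, st$bound_myosin,
               tolerance = 1e-12)
})

test_that("single-bin engine matches the closed-form two-state relaxation", {
  grid <- single_bin_grid()
  f0 <- 2; g0 <- 3; A0 <- 0.5
  pars <- single_bin_params(f0, g0)
  st0 <- fibre_state(pars, grid, actin_activated = A0)
  err <- vapply(c(1e-4, 1e-5), function(dt) {
    tr <- simulate_fibre(isometric_protocol(1), pars, dt = dt,
                         grid = grid, init = st0)
    abs(tr$cb_attached[nrow(tr)] /
          two_state_closed_form(1, f0, g0, A0) - 1)
  }, numeric(1))
  expect_lt(err[2], 1e-6)
  # and the scheme is consistent: error shrinks ~linearly with dt
  expect_lt(err[2], err[1] / 5)
  # and the linearised steady state f0*a/(f0*a + g0) is approached when
  # binding is rare (b << A0, so the available-actin factor is ~frozen)
  pars2 <- single_bin_params(0.05, 10)
  st0 <- fibre_state(pars2, grid, actin_activated = A0)
  tr2 <- simulate_fibre(isometric_protocol(3), pars2, dt = 1e-4,
                        grid = grid, init = st0)
  expect_equal(tr2$cb_attached[nrow(tr2)],
               0.05 * A0 / (0.05 * A0 + 10), tolerance = 1e-2)
})

test_that("myosin is conserved to 1e-12 through a full protocol", {
  # attached + detached = 1 is structural; the non-trivial invariant is
  # that advection neither creates nor destroys mass except through the
  # tracked edge loss, which must stay negligible on the default grid
  pars <- fibre_params("bag")
  tr <- simulate_fibre(triangle_pair(12, 5.6, 5.6, isi = 0), pars)
  expect_lt(attr(tr, "forced_detached"), 1e-12)
  expect_lt(attr(tr, "edge_occupancy"), 1e-6)
  expect_true(all(tr$cb_attached >= 0 & tr$cb_attached <= 1))

  # low-level check of the interpolation shift itself
  set.seed(11)
  for (s in c(-3.2, -0.7, -0.07, 0.07, 0.7, 3.2)) {
    m <- runif(60)
    sh <- spindlesim:::shift_distribution(m, s)
    expect_equal(sum(sh$bound) + sh$lost, sum(m), tolerance = 1e-12)
    expect_true(all(sh$bound >= 0))
  }
})

test_that("state ordering cb <= actin <= overlap holds along shipped protocols", {
  for (fibre in c("bag", "chain")) {
    tr <- simulate_fibre(ramp_hold(36, 5.6), fibre_params(fibre))
    expect_true(all(tr$cb_attached <= tr$actin_activated + 1e-9))
    expect_true(all(tr$actin_activated <= tr$n_overlap + 1e-9))
    expect_true(all(tr$cb_attached >= -1e-15))
  }
})

test_that("halving dt and bin width changes the ramp stress by < 1% RMS", {
  proto <- ramp_hold(36, 5.6)
  pars <- fibre_params("bag")
  base <- simulate_fibre(proto, pars, dt = 1e-4)
  fine <- simulate_fibre(proto, pars, dt = 5e-5,
                         grid = strain_grid(width = 0.125))
  # compare on the coarse time grid
  f <- approx(fine$time_s, fine$stress, xout = base$time_s)$y
  rel <- sqrt(mean((f - base$stress)^2)) / sqrt(mean(base$stress^2))
  expect_lt(rel, 0.01)
})

test_that("slack mode pins stress at zero and never shortens below command", {
  proto <- triangle_pair(12, 5.6, 5.6, isi = 1)
  tr <- simulate_fibre(proto, fibre_params("bag"), allow_slack = TRUE)
  expect_true(all(tr$length_nm >= tr$commanded_nm - 1e-9))
  expect_true(all(tr$stress >= -1e-6))
  slack <- tr$length_nm > tr$commanded_nm + 1e-6
  expect_true(any(slack)) # the shorten leg does make the bag buckle
  expect_true(all(abs(tr$stress[slack]) < 1))
})
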