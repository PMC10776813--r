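test_that("filament overlap follows the linear ramp with clamping", {
  geo <- filament_geometry()
  expect_equal(filament_overlap(1300, geo), 635 / 735)
  expect_equal(filament_overlap(1200, geo), 1)
  expect_equal(filament_overlap(1935, geo), 0)
  # clamped outside the physical range
  expect_equal(filament_overlap(1000, geo), 1)
  expect_equal(filament_overlap(2500, geo), 0)
  broken <- filament_geometry()
  broken$length_bare_zone <- 900 # corrupt past the constructor
  expect_error(filament_overlap(1300, broken), "invalid geometry")
  expect_error(filament_overlap(-5, geo), "positive")
})

test_that("attachment rate is a Gaussian with the documented width", {
  xb <- crossbridge_params()
  expect_equal(attachment_rate(0, xb), xb$attach_slope)
  x <- c(0.5, 1.7, 3, 8, 12)
  expect_equal(attachment_rate(x, xb), attachment_rate(-x, xb))
  # 1/e point at sqrt(const_f / cb_stiffness)
  xe <- sqrt(xb$const_f / xb$cb_stiffness)
  expect_equal(attachment_rate(xe, xb), xb$attach_slope / exp(1))
})

test_that("detachment rate is cubic above the breakpoint and floored below", {
  xb <- crossbridge_params() # bag: offset 7, extra 0.5
  expect_equal(detachment_rate(-5, xb), 7.5)
  expect_equal(detachment_rate(0, xb), 7 + 0.3 * 125 + 0.5)
  # non-decreasing on strain >= breakpoint
  x <- seq(-5, 20, by = 0.25)
  expect_true(all(diff(detachment_rate(x, xb)) >= 0))
  # tuned part falls to zero under compression; the floor is the extra
  # offset
  expect_equal(detachment_rate(-50, xb), xb$detach_extra_offset)
  chain <- fibre_params("chain")$xb
  expect_equal(detachment_rate(-50, chain), 10)
  expect_true(all(detachment_rate(seq(-60, 30, 0.5), xb) >=
                    xb$detach_extra_offset))
})

test_that("actin derivative matches its closed-form limits", {
  thin0 <- thin_filament_params(k_coop = 0)
  grid <- strain_grid(-10, 10, 0.5)
  pars <- fibre_params("bag", k_coop = 0)

  # fully activated, nothing bound, no cooperativity: pure deactivation
  st <- fibre_state(pars, grid, actin_activated = 635 / 735)
  expect_equal(actin_derivative(st, thin0, Ca = 0),
               -thin0$k_off * st$n_overlap)

  # steady state of the linear balance: A* = n k_on Ca / (k_on Ca + k_off)
  Ca <- pca_to_molar(6.4)
  Astar <- st$n_overlap * thin0$k_on * Ca / (thin0$k_on * Ca + thin0$k_off)
  st2 <- fibre_state(pars, grid, actin_activated = Astar)
  expect_equal(actin_derivative(st2, thin0, Ca), 0, tolerance = 1e-12)
  expect_equal(Astar, 0.1187, tolerance = 1e-3)

  # bound cross-bridges block deactivation entirely
  nb <- length(grid$centres)
  bound <- rep(st$n_overlap / nb, nb)
  st3 <- fibre_state(pars, grid, actin_activated = st$n_overlap,
                     bound_myosin = bound)
  expect_equal(actin_derivative(st3, thin_filament_params(k_coop = 1),
                                Ca = 0), 0)

  # zero overlap: cooperativity ratios defined as zero, activation off
  st4 <- fibre_state(pars, grid, hs_length = 1940, actin_activated = 0.1)
  expect_equal(st4$n_overlap, 0)
  expect_equal(actin_derivative(st4, thin_filament_params(k_coop = 1), Ca),
               -200 * 0.1)
})

test_that("myosin derivatives conserve total myosin and respect ordering", {
  grid <- strain_grid(-10, 10, 0.5)
  pars <- fibre_params("bag")

  st0 <- fibre_state(pars, grid)
  d0 <- myosin_derivatives(st0, pars$xb, grid)
  expect_true(all(d0$bound == 0))
  expect_equal(d0$detached, 0)

  set.seed(42)
  for (i in 1:25) {
    bound <- runif(length(grid$centres), 0, 0.3 / length(grid$centres))
    A <- sum(bound) + runif(1, 0, 0.3)
    st <- fibre_state(pars, grid, actin_activated = A,
                      bound_myosin = bound)
    d <- myosin_derivatives(st, pars$xb, grid)
    expect_equal(sum(d$bound) + d$detached, 0, tolerance = 1e-15)
  }

  bad <- fibre_state(pars, grid, actin_activated = 0.2,
                     bound_myosin = rep(0.2 / 41, 41)[1:40])
  bad$actin_activated <- 0.05 # corrupt after construction
  expect_error(myosin_derivatives(bad, pars$xb, grid), "corruption")
})

test_that("stress sums the cross-bridge springs and the passive element", {
  grid <- strain_grid(-10, 10, 0.5)
  bag <- fibre_params("bag")
  chain <- fibre_params("chain")

  # no bound bridges: passive only
  st_slack <- fibre_state(bag, grid, hs_length = 1050)
  expect_equal(st_slack$stress, 0)
  expect_equal(fibre_state(bag, grid, hs_length = 1300)$stress,
               90 * (1300 - 1050))
  expect_equal(fibre_state(chain, grid, hs_length = 1300)$stress,
               250 * (1300 - 1200))
  # signed below slack, no clipping
  expect_equal(fibre_state(bag, grid, hs_length = 1000)$stress,
               90 * (1000 - 1050))

  # a bound cohort adds cb_density-scaled spring force, measured from the
  # post-power-stroke zero (strain + power_stroke)
  bound <- rep(0, 40)
  bound[grid$centres == 2.25] <- 0.1
  st <- fibre_state(bag, grid, hs_length = 1050, actin_activated = 0.2,
                    bound_myosin = bound)
  expect_equal(st$stress,
               1e-9 * 6.9e16 * 0.001 * (2.25 + 5) * 0.1)
})

test_that("advance conserves myosin and advects a frozen cohort exactly", {
  grid <- strain_grid(-10, 10, 0.5)
  pars <- frozen_params()
  bound <- rep(0, 40)
  bound[grid$centres == -0.25] <- 0.12
  bound[grid$centres == 0.25] <- 0.12
  st <- fibre_state(pars, grid, actin_activated = 0.5,
                    bound_myosin = bound)

  # rates are frozen: a +2 nm step shifts the cohort by exactly +2 nm and
  # raises stress by the cross-bridge term with dx = 2
  st2 <- advance(st, dt = 1e-4, next_length = 1302, Ca = 0, params = pars,
                 grid = grid)
  expect_equal(sum(st2$bound_myosin), 0.24, tolerance = 1e-14)
  expect_equal(st2$bound_myosin[grid$centres == 1.75], 0.12)
  expect_equal(st2$bound_myosin[grid$centres == 2.25], 0.12)
  expect_equal(st2$stress - st$stress,
               1e-9 * 6.9e16 * 0.001 * 2 * 0.24 + 90 * 2,
               tolerance = 1e-9)

  # non-integer shifts split mass between neighbouring bins, conserving it
  st3 <- advance(st, dt = 1e-4, next_length = 1300.3, Ca = 0,
                 params = pars, grid = grid)
  expect_equal(sum(st3$bound_myosin), 0.24, tolerance = 1e-14)
  expect_equal(sum(grid$centres * st3$bound_myosin) / 0.24, 0.3,
               tolerance = 1e-12) # first moment moves by the shift

  # conservation through a random walk of length steps with live kinetics
  live <- fibre_params("bag")
  wide <- strain_grid(-30, 25, 0.5) # room for the attachment tail
  bound <- rep(0, length(wide$centres))
  bound[40:51] <- 0.2 / 12
  st <- fibre_state(live, wide, actin_activated = 0.3,
                    bound_myosin = bound)
  set.seed(7)
  for (i in 1:100) {
    L <- st$hs_length + rnorm(1, 0, 0.02)
    st <- advance(st, 1e-4, L, pca_to_molar(6.4), live, wide)
    expect_true(st$cb_attached <= st$actin_activated + 1e-12)
    expect_true(all(st$bound_myosin >= 0))
  }
})

test_that("advance flags a strain-grid overflow", {
  grid <- strain_grid(-2, 2, 0.5)
  pars <- frozen_params()
  bound <- rep(0, length(grid$centres))
  bound[4] <- 0.3
  st <- fibre_state(pars, grid, actin_activated = 0.5,
                    bound_myosin = bound)
  expect_error(advance(st, 1e-4, st$hs_length + 2, Ca = 0, params = pars,
                       grid = grid, overflow_tol = 1e-9), "overflow")
})

test_that("isometric steady state is a fixed point of advance", {
  pars <- fibre_params("chain") # fast rates: equilibrated well within 4 s
  tr <- simulate_fibre(isometric_protocol(4), pars)
  st <- attr(tr, "final_state")
  st2 <- advance(st, 1e-4, st$hs_length, pca_to_molar(6.4), pars, st$grid)
  expect_equal(st2$actin_activated, st$actin_activated, tolerance = 1e-7)
  expect_equal(st2$bound_myosin, st$bound_myosin, tolerance = 1e-7)
  expect_equal(st2$stress, st$stress, tolerance = 1e-4)
})
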