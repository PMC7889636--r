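test_that("Womersley number follows r sqrt(w/nu)", {
  expect_equal(womersley_alpha(1, 3.33, 3.33), 1)
  expect_equal(womersley_alpha(0.2, 2 * pi / 0.137, 3.33),
               0.2 * sqrt((2 * pi / 0.137) / 3.33), tolerance = 1e-15)
  # linear in r
  expect_equal(womersley_alpha(0.4, 5, 3), 2 * womersley_alpha(0.2, 5, 3))
  expect_error(womersley_alpha(-1, 1, 1), "positive")
})

test_that("segment impedance has the right limits", {
  blood <- blood_properties()
  seg <- list(area = pi * 0.2^2, length = 10)
  R0 <- 1 / segment_conductance(seg, blood)
  # omega = 0 is exactly the Poiseuille resistance
  expect_equal(segment_impedance(seg, blood, 0), complex(real = R0))

  # low-frequency limit (alpha = 0.01)
  om <- (0.01 / 0.2)^2 * blood$nu_mm2_s
  Z <- segment_impedance(seg, blood, om)
  expect_lt(Mod(Z - R0) / R0, 1e-3)

  # high-frequency limit (alpha = 50): pure inertance i w rho L / (pi r^2)
  om <- (50 / 0.2)^2 * blood$nu_mm2_s
  Z <- segment_impedance(seg, blood, om)
  Zin <- 1i * om * blood$rho_g_mm3 * 10 / (pi * 0.2^2) / PA_PER_MMHG
  expect_lt(Mod(Z - Zin) / Mod(Zin), 0.05)
  expect_gt(Re(Z), 0)
})

test_that("impedance at alpha = 3 matches an integral-representation oracle", {
  blood <- blood_properties()
  r <- 0.2; L <- 10
  seg <- list(area = pi * r^2, length = L)
  om <- (3 / r)^2 * blood$nu_mm2_s
  Z <- segment_impedance(seg, blood, om)
  Fw <- oracle_womersley_factor(3)
  Z_exp <- 1i * om * blood$rho_g_mm3 * L / (pi * r^2) / Fw / PA_PER_MMHG
  expect_lt(Mod(Z - Z_exp) / Mod(Z_exp), 1e-9)
})

test_that("the default waveform is a positive pulse with ~1.6x systolic peak", {
  wf <- default_waveform()
  t <- seq(0, wf$period, length.out = 2001)
  s <- reconstruct_waveform(wf, t)
  expect_gt(min(s), 0)
  expect_equal(mean(s[-1]), 1, tolerance = 1e-6)   # unit cycle mean
  expect_equal(max(s), 1.6, tolerance = 0.05)
  # waveform with reversal triggers the guard
  expect_warning(arterial_waveform(0.137, data.frame(k = 1, amp = 1.5,
                                                     phase = 0)),
                 "not strictly positive")
})

test_that("a mean-only waveform reproduces the steady solve at every instant", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  st <- solve_steady(net, v)
  ts <- solve_transient(net, v, waveform = arterial_waveform(0.137, NULL))
  for (j in seq_along(ts$times))
    expect_equal(unname(ts$flows[, j]), unname(Re(st$flows)),
                 tolerance = 1e-12)
  # DC equivalence carries to the metrics
  expect_equal(max_velocity(ts, net, 1), max_velocity(st, net, 1),
               tolerance = 1e-9)
})

test_that("cycle-averaged transient flows equal the steady solution", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  st <- solve_steady(net, v)
  ts <- solve_transient(net, v)
  expect_equal(unname(rowMeans(ts$flows)), unname(Re(st$flows)),
               tolerance = 1e-9)
  expect_length(ts$times, 28)      # ceil(0.137/0.005) periodic grid
})

test_that("single-tube harmonic phase lag matches arg(Z) through reconstruction", {
  net <- tube_network(length = 10, area = pi * 0.25^2)
  blood <- blood_properties()
  wf <- arterial_waveform(0.137, data.frame(k = 1, amp = 0.3, phase = 0.4))
  ts <- solve_transient(net, c(`in` = 10), blood, wf,
                        transient_config(time_step = 0.137 / 64))
  dp <- ts$pressures["in", ] - ts$pressures["out", ]
  q <- ts$flows["T", ]
  # first-harmonic phasors via the discrete Fourier transform of the series
  n <- length(ts$times)
  ph <- exp(-1i * 2 * pi * (0:(n - 1)) / n)
  dp1 <- sum(dp * ph) * 2 / n
  q1 <- sum(q * ph) * 2 / n
  Z <- segment_impedance(net$segments[1, ], blood, 2 * pi / 0.137)
  expect_equal(Arg(dp1 / q1), Arg(Z), tolerance = 1e-6)
  expect_equal(Mod(dp1 / q1), Mod(Z), tolerance = 1e-6)
})

test_that("transient response is linear in the waveform amplitude", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  h <- data.frame(k = c(1, 2), amp = c(0.2, 0.1), phase = c(0, 1))
  t1 <- solve_transient(net, v, waveform = arterial_waveform(0.137, h))
  h2 <- h; h2$amp <- 2 * h2$amp
  t2 <- solve_transient(net, v, waveform = arterial_waveform(0.137, h2))
  dc <- Re(t1$steady$flows)
  expect_equal(t2$flows - dc, 2 * (t1$flows - dc), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("steady max velocity is twice the sectional mean", {
  net <- tube_network(length = 10, area = 0.2)
  st <- solve_steady(net, c(`in` = 2.5))   # Q = 25 mm/s * 0.2 = 5 mm^3/s
  # mean sectional velocity 25 mm/s = 2.5 cm/s -> peak 5 cm/s
  expect_equal(max_velocity(st, net, 1), 5, tolerance = 1e-12)
})

test_that("oscillatory max velocity matches a radial-quadrature oracle", {
  blood <- blood_properties()
  r <- 3 / sqrt((2 * pi / 0.137) / blood$nu_mm2_s) # alpha = 3 at k = 1
  net <- tube_network(length = 8, area = pi * r^2)
  wf <- arterial_waveform(0.137, data.frame(k = 1, amp = 0.4, phase = 0))
  ts <- solve_transient(net, c(`in` = 10), blood, wf,
                        transient_config(time_step = 0.137 / 64))
  got <- max_velocity(ts, net, 1, blood, n_radial = 301)

  # oracle: reconstruct the analytic profile on an independent 200-point
  # radial grid using the integral-representation Bessel functions
  A <- pi * r^2
  v0 <- Re(ts$steady$flows[["T"]]) / A
  v1 <- ts$harmonics[[1]]$flows[["T"]] / A
  L <- complex(modulus = 3, argument = 3 * pi / 4)
  y <- seq(0, 1, length.out = 200)
  phi <- vapply(y, function(yy)
    (1 - oracle_J0(L * yy) / oracle_J0(L)) / oracle_womersley_factor(3),
    complex(1))
  vmax_t <- vapply(ts$times, function(t) {
    prof <- 2 * v0 * (1 - y^2) + Re(v1 * phi * exp(1i * 2 * pi * t / 0.137))
    max(abs(prof))
  }, 0)
  expect_equal(got, mean(vmax_t) / 10, tolerance = 2e-3)
})
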