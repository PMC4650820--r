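test_that("the order parameter matches closed forms and is shift invariant", {
  expect_equal(order_parameter(rep(1.3, 7))[["r"]], 1)
  expect_equal(order_parameter(c(0, 2 * pi / 3, 4 * pi / 3))[["r"]], 0,
               tolerance = 1e-12)
  op <- order_parameter(c(0, pi / 2))
  expect_equal(op[["r"]], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(op[["psi"]], pi / 4, tolerance = 1e-12)
  expect_error(order_parameter(numeric(0)), "non-empty")

  withr::with_seed(1, {
    for (case in 1:10) {
      ph <- runif(20, -20, 20)
      shift <- runif(1, -10, 10)
      expect_equal(order_parameter(ph + shift)[["r"]],
                   order_parameter(ph)[["r"]], tolerance = 1e-12)
    }
  })
})

test_that("time-averaged order matches the drifting two-oscillator closed form", {
  # fully synchronized: r identically 1
  m <- two_osc_model(K = 1, beta = 0, omega = c(0, 0))
  tr <- integrate_mkm(m, phases0 = c(0.4, 0.4), n_steps = 1000,
                      record_stride = 10L, burn_in_steps = 0L)
  expect_equal(time_averaged_order(tr), 1, tolerance = 1e-12)

  # uncoupled drift: r(t) = |cos(delta_omega * t / 2)| averages to 2/pi
  # over whole periods
  m2 <- two_osc_model(K = 0, beta = 0, omega = c(pi / 4, -pi / 4))
  tr2 <- integrate_mkm(m2, phases0 = c(0, 0), dt = 0.01, n_steps = 8000,
                       record_stride = 4L, burn_in_steps = 0L)
  expect_equal(time_averaged_order(tr2), 2 / pi, tolerance = 0.01 / (2 / pi))

  expect_error(time_averaged_order(tr2, burn_in_steps = 8000), "burn-in")
})

test_that("decoupled oscillators have a vanishing Lyapunov exponent", {
  mx <- multiplex(ring_layer(10), ring_layer(10))
  m <- mkm(mx, K = 0, beta = 0, omega = sample_natural_frequencies(10, seed = 1))
  for (mode in c("renormalized", "direct")) {
    ly <- instantaneous_lyapunov(m, d0 = 1e-8, n_steps = 2000,
                                 record_stride = 20L, mode = mode, seed = 2)
    expect_lt(abs(ly$lambda_final), 1e-6)
  }
})

test_that("the twin stepper recovers the exponent of a linear flow in both modes", {
  rhs <- function(x) c(0.3, -1) * x
  for (mode in c("renormalized", "direct")) {
    ly <- twin_lyapunov(rhs, c(1, 1), d0 = 1e-8, dt = 0.01, n_steps = 5000,
                        mode = mode, seed = 3)
    expect_equal(ly$lambda_final, 0.3, tolerance = 0.01 / 0.3)
  }
  # the two estimators agree on a non-saturating run
  d <- twin_lyapunov(rhs, c(1, 1), d0 = 1e-8, dt = 0.01, n_steps = 5000,
                     mode = "direct", seed = 3)$lambda_final
  r <- twin_lyapunov(rhs, c(1, 1), d0 = 1e-8, dt = 0.01, n_steps = 5000,
                     mode = "renormalized", seed = 3)$lambda_final
  expect_lt(abs(d - r) / abs(r), 0.1)
})

test_that("the locked pair has a neutral mean-phase direction and the predicted transverse rate", {
  # two oscillators locked at sin(Delta*) = 1/4; linearization has
  # eigenvalues 0 (mean phase) and -4 cos(Delta*)
  m <- two_osc_model(K = 1, beta = 0, omega = c(0.5, -0.5))
  delta_star <- asin(0.25)
  locked <- c(delta_star / 2, -delta_star / 2)
  rhs <- function(x) mkm_velocity(x, m)

  neutral <- twin_lyapunov(rhs, locked, d0 = 1e-8, dt = 0.01, n_steps = 2000,
                           pert0 = c(1, 1), wrap = TRUE)
  expect_lt(abs(neutral$lambda_final), 1e-6)

  transverse <- twin_lyapunov(rhs, locked, d0 = 1e-8, dt = 0.01,
                              n_steps = 200, renorm_interval = 0.1,
                              pert0 = c(1, -1), wrap = TRUE)
  expect_equal(transverse$lambda_final, -4 * cos(delta_star),
               tolerance = 0.05)
})

test_that("compiled and pure-R twin estimators agree through the independent velocity oracle", {
  mx <- er_multiplex(8, 0.6, seed = 11)
  m <- mkm(mx, K = 2.5, beta = 0.2, omega = sample_natural_frequencies(8, seed = 12))
  phi0 <- sample_initial_phases(8, seed = 13)
  pert <- withr::with_seed(14, rnorm(8))
  cpp <- instantaneous_lyapunov(m, phases0 = phi0, d0 = 1e-8, dt = 0.01,
                                n_steps = 3000, record_stride = 30L,
                                seed = 14)
  pure <- twin_lyapunov(function(x) naive_mkm_velocity(x, m), phi0,
                        d0 = 1e-8, dt = 0.01, n_steps = 3000,
                        record_stride = 30L, wrap = TRUE, pert0 = pert)
  # the perturbation directions differ between the two routes; the
  # estimate itself must agree regardless of the direction
  expect_lt(abs(cpp$lambda_final - pure$lambda_final), 0.02)
})

test_that("stationary frequencies equal the natural frequencies when uncoupled", {
  mx <- multiplex(ring_layer(20), ring_layer(20))
  omega <- sample_natural_frequencies(20, seed = 5)
  m <- mkm(mx, K = 0, beta = 0, omega = omega)
  tr <- integrate_mkm(m, n_steps = 2000, record_stride = 20L,
                      burn_in_steps = 400L, seed = 6)
  fs <- mean_frequency_deviations(tr)
  expect_equal(fs$omega_i, omega, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(abs(fs$omega_bar), 1e-9)
})

test_that("the synchronized manifold on regular layers shows exact frequency suppression", {
  full <- er_layer(16, 1)
  m <- mkm(multiplex(full, full), K = 1, beta = pi / 4, omega = rep(0, 16))
  tr <- integrate_mkm(m, phases0 = rep(0.2, 16), n_steps = 2000,
                      record_stride = 20L, burn_in_steps = 400L)
  fs <- mean_frequency_deviations(tr)
  expect_equal(fs$omega_i, rep(-sin(pi / 4), 16), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("two locked detuned oscillators have zero mean frequency deviation", {
  m <- two_osc_model(K = 1, beta = 0, omega = c(0.5, -0.5))
  tr <- integrate_mkm(m, phases0 = c(0, 0), n_steps = 8000,
                      record_stride = 40L, burn_in_steps = 4000L)
  fs <- mean_frequency_deviations(tr)
  expect_lt(abs(fs$omega_bar), 1e-9)
})

test_that("frequency deviations are frame-covariant (exact bookkeeping)", {
  mx <- er_multiplex(25, 0.3, seed = 41)
  omega <- sample_natural_frequencies(25, seed = 42)
  phi0 <- sample_initial_phases(25, seed = 43)
  base <- integrate_mkm(mkm(mx, 1.4, 0.5, omega), phases0 = phi0,
                        n_steps = 4000, record_stride = 40L)
  shifted <- integrate_mkm(mkm(mx, 1.4, 0.5, omega + 1.5), phases0 = phi0,
                           n_steps = 4000, record_stride = 40L)
  expect_equal(mean_frequency_deviations(shifted)$omega_bar - 1.5,
               mean_frequency_deviations(base)$omega_bar, tolerance = 1e-9)
})

test_that("modulo-wrapped phase input is rejected by the frequency estimator", {
  m <- two_osc_model(K = 0, beta = 0, omega = c(5, -5))
  tr <- integrate_mkm(m, phases0 = c(0, 0), n_steps = 4000,
                      record_stride = 40L, burn_in_steps = 0L)
  tr$phases <- tr$phases %% (2 * pi)  # corrupt: wrap the state
  expect_error(mean_frequency_deviations(tr), "wrap")
})

test_that("frequency histograms normalize and quantify spread", {
  fs <- structure(list(omega_i = rep(0.3, 50), omega_bar = 0.3,
                       t_window = 1, n = 50L), class = "mkm_freqstats")
  h <- frequency_histogram(fs, bins = 10)
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(h$spread, 0)

  withr::with_seed(7, {
    fs2 <- structure(list(omega_i = rnorm(500), omega_bar = 0,
                          t_window = 1, n = 500L), class = "mkm_freqstats")
    h2 <- frequency_histogram(fs2, bins = 25)
    expect_equal(sum(h2$density * diff(h2$breaks)), 1, tolerance = 1e-12)
  })
  expect_error(frequency_histogram(fs, bins = 1), "bins")
})

test_that("uncoupled stationary spread matches the sampling distribution at large n", {
  n <- 1e4
  mx <- multiplex(ring_layer(n), ring_layer(n))
  omega <- sample_natural_frequencies(n, seed = 51, center = FALSE)
  m <- mkm(mx, K = 0, beta = 0, omega = omega)
  tr <- integrate_mkm(m, n_steps = 200, record_stride = 20L,
                      burn_in_steps = 20L, seed = 52)
  h <- frequency_histogram(mean_frequency_deviations(tr), bins = 40)
  expect_lt(abs(h$spread - 1), 3 / sqrt(2 * n))
})
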