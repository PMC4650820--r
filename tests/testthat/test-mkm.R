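test_that("natural-frequency sampling centers, reproduces, and matches its distribution", {
  w <- sample_natural_frequencies(5, seed = 7, center = TRUE)
  expect_lt(abs(mean(w)), 1e-15)
  expect_identical(sample_natural_frequencies(10, seed = 3),
                   sample_natural_frequencies(10, seed = 3))
  w2 <- sample_natural_frequencies(1e5, seed = 11, center = FALSE)
  # sd of the sample sd is ~ 1/sqrt(2n) for a normal sample
  expect_lt(abs(sd(w2) - 1), 3 / sqrt(2e5))
  expect_error(sample_natural_frequencies(10, "lognormal"))
  wu <- sample_natural_frequencies(1000, "uniform", seed = 1, half_width = 2)
  expect_true(all(abs(wu) < 4))  # centered draws from [-2, 2]
})

test_that("initial phases are uniform on the circle and reproducible", {
  ph <- sample_initial_phases(1000, seed = 5)
  expect_true(all(ph >= 0 & ph < 2 * pi))
  expect_identical(ph, sample_initial_phases(1000, seed = 5))
  big <- sample_initial_phases(1e5, seed = 6)
  expect_lt(Mod(mean(exp(1i * big))), 0.02)  # 3 sigma ~ 3/sqrt(n)
})

test_that("the velocity field matches hand evaluation and symmetry limits", {
  m <- two_osc_model(K = 1, beta = 0, omega = c(0, 0))
  expect_equal(mkm_velocity(c(0, pi / 2), m), c(2, -2))

  mx <- er_multiplex(30, 0.4, seed = 2)
  m2 <- mkm(mx, K = 1.3, beta = 0, omega = rep(0, 30))
  expect_equal(mkm_velocity(rep(0.7, 30), m2), rep(0, 30))

  # regular (complete) layers, equal phases: only the EI shift survives
  full <- er_layer(12, 1)
  m3 <- mkm(multiplex(full, full), K = 0.8, beta = 0.9, omega = rep(0, 12))
  expect_equal(mkm_velocity(rep(1.1, 12), m3), rep(-0.8 * sin(0.9), 12),
               tolerance = 1e-12)
})

test_that("the compiled velocity agrees with a naive double-loop oracle", {
  withr::with_seed(4, {
    for (case in 1:5) {
      mx <- er_multiplex(25, 0.3, seed = 100 + case)
      m <- mkm(mx, K = runif(1, 0, 3), beta = runif(1, -1.5, 1.5),
               omega = rnorm(25))
      ph <- runif(25, -10, 10)
      expect_equal(mkm_velocity(ph, m), naive_mkm_velocity(ph, m),
                   tolerance = 1e-12)
    }
  })
})

test_that("identical layers at zero shift reduce to the single-network Kuramoto model", {
  l <- er_layer(20, 0.4, seed = 8)
  m <- mkm(multiplex(l, l), K = 1.7, beta = 0,
           omega = sample_natural_frequencies(20, seed = 9))
  ph <- sample_initial_phases(20, seed = 10)
  A <- as_adjacency(l)
  expect_equal(mkm_velocity(ph, m),
               single_layer_kuramoto(ph, A, 2 * m$K, m$omega),
               tolerance = 1e-12)
})

test_that("uncoupled oscillators rotate freely and exactly under RK4", {
  m <- two_osc_model(K = 0, beta = 0, omega = c(1, -1))
  tr <- integrate_mkm(m, phases0 = c(0, 0), dt = 0.01, n_steps = 100,
                      record_stride = 100L, burn_in_steps = 0L)
  expect_equal(tr$phases[2, ], c(1, -1), tolerance = 1e-14)
})

test_that("two detuned oscillators lock at the Adler fixed point, matching an ODE-solver reference", {
  skip_if_not_installed("deSolve")
  m <- two_osc_model(K = 1, beta = 0, omega = c(0.5, -0.5))
  tr <- integrate_mkm(m, phases0 = c(0, 0), dt = 0.01, n_steps = 6000,
                      record_stride = 100L, burn_in_steps = 0L)
  delta_end <- tr$phases[nrow(tr$phases), 1] - tr$phases[nrow(tr$phases), 2]
  expect_equal(delta_end, asin(0.25), tolerance = 1e-6)

  ref <- deSolve::ode(
    y = c(0, 0), times = seq(0, 60, 1),
    func = function(t, y, p) list(c(
      0.5 + sin(y[2] - y[1]) + sin(y[2] - y[1]),
      -0.5 + sin(y[1] - y[2]) + sin(y[1] - y[2]))),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$phases[nrow(tr$phases), ],
               unname(ref[nrow(ref), 2:3]), tolerance = 1e-6)
})

test_that("negating the phase shift, frequencies and initial phases mirrors the trajectory", {
  mx <- er_multiplex(40, 0.25, seed = 21)
  omega <- sample_natural_frequencies(40, seed = 22)
  phi0 <- sample_initial_phases(40, seed = 23)
  fwd <- integrate_mkm(mkm(mx, 1.2, 0.7, omega), phases0 = phi0,
                       n_steps = 5000, record_stride = 100L)
  mir <- integrate_mkm(mkm(mx, 1.2, -0.7, -omega), phases0 = -phi0,
                       n_steps = 5000, record_stride = 100L)
  expect_equal(mir$phases, -fwd$phases, tolerance = 1e-9)
})

test_that("a rotating-frame shift of the frequencies leaves the order parameter invariant", {
  mx <- er_multiplex(40, 0.25, seed = 31)
  omega <- sample_natural_frequencies(40, seed = 32)
  phi0 <- sample_initial_phases(40, seed = 33)
  base <- integrate_mkm(mkm(mx, 1.1, 0.4, omega), phases0 = phi0,
                        n_steps = 5000, record_stride = 50L)
  shifted <- integrate_mkm(mkm(mx, 1.1, 0.4, omega + 2.5), phases0 = phi0,
                           n_steps = 5000, record_stride = 50L)
  # r is computed from phase differences, so subtracting the frame c*t is
  # immaterial to it; compare r(t) directly
  expect_equal(order_parameter_series(shifted)$r,
               order_parameter_series(base)$r, tolerance = 1e-9)
  # and the transformed phases themselves recover the original trajectory
  expect_equal(shifted$phases - outer(shifted$times, rep(2.5, 40)),
               base$phases, tolerance = 1e-9)
})

test_that("the integrator converges at 4th order on the two-oscillator system", {
  m <- two_osc_model(K = 1, beta = 0.3, omega = c(0.5, -0.5))
  final_at <- function(dt) {
    tr <- integrate_mkm(m, phases0 = c(0.2, -0.1), dt = dt,
                        n_steps = round(1 / dt), record_stride = round(1 / dt))
    tr$phases[2, ]
  }
  ref <- final_at(0.0005)
  dts <- c(0.04, 0.02, 0.01, 0.005)
  errs <- vapply(dts, function(dt) max(abs(final_at(dt) - ref)), numeric(1))
  slope <- coef(lm(log(errs) ~ log(dts)))[[2]]
  expect_equal(slope, 4, tolerance = 0.3 / 4)
})

test_that("integration inputs are validated", {
  m <- two_osc_model(1, 0, c(0, 0))
  expect_error(integrate_mkm(m, dt = -0.1), "positive")
  expect_error(integrate_mkm(m, n_steps = 100, record_stride = 7), "divisor")
  expect_error(integrate_mkm(m, phases0 = c(1, 2, 3), n_steps = 10,
                             record_stride = 1), "length")
})

test_that("trajectories serialize to TSV with a faithful manifest", {
  m <- mkm(er_multiplex(8, 0.5, seed = 1), K = 0.5, beta = 0.2, seed = 2)
  tr <- integrate_mkm(m, dt = 0.01, n_steps = 200, record_stride = 20L,
                      seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(dim(tab), c(11L, 9L))
  expect_equal(as.matrix(tab[, -1]), tr$phases, ignore_attr = TRUE,
               tolerance = 1e-12)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$K, 0.5)
  expect_equal(man$seed, 3)
  expect_equal(man$n_steps, 200)
})
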