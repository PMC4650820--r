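# the default oscillatory operating point is reused across blocks
wc_cycle_cache <- new.env()
default_cycle <- function() {
  if (is.null(wc_cycle_cache$cyc))
    wc_cycle_cache$cyc <- find_limit_cycle(wc_params())
  wc_cycle_cache$cyc
}

test_that("the sigmoid has the logistic midpoint, limits and slope", {
  expect_equal(wc_sigmoid(4, 1.3, 4), 0.5)
  expect_lt(wc_sigmoid(4 - 500 / 1.3, 1.3, 4), 1e-12)
  expect_gt(wc_sigmoid(4 + 500 / 1.3, 1.3, 4), 1 - 1e-12)
  h <- 1e-5
  slope <- (wc_sigmoid(3.7 + h, 2, 3.7) - wc_sigmoid(3.7 - h, 2, 3.7)) / (2 * h)
  expect_equal(slope, 2 / 4, tolerance = 1e-6)
  expect_error(wc_sigmoid(0, -1, 0), "positive")
})

test_that("the network velocity decouples at eps = 0 and respects symmetry", {
  net <- multiplex(er_layer(3, 1), er_layer(3, 1))
  p <- wc_params(network = net, eps = 0)
  s1 <- c(0.2, 0.3, 0.4, 0.1, 0.15, 0.2)
  s2 <- s1
  s2[2] <- 0.9  # perturb region 2 only
  v1 <- wc_velocity(s1, s1, p)
  v2 <- wc_velocity(s2, s2, p)
  expect_equal(v1[c(1, 3, 4, 6)], v2[c(1, 3, 4, 6)])

  # identical regions on a regular coupling graph stay identical
  p2 <- wc_params(network = net, eps = 0.05)
  sym <- rep(c(0.25, 0.12), each = 3)
  v <- wc_velocity(sym, sym, p2)
  expect_equal(v[1:3], rep(v[1], 3))
  expect_equal(v[4:6], rep(v[4], 3))
  expect_error(wc_velocity(c(0.1, 0.2), c(0.1, 0.2), p2), "length")
})

test_that("a fixed point of the uncoupled flow is stationary for the network", {
  p <- wc_params(P = 0.2)  # subthreshold drive: stable equilibrium
  rhs <- function(y) wc_velocity(y, y, p)
  # locate the equilibrium by damped fixed-point iteration, then polish
  y <- c(0.1, 0.05)
  for (i in 1:500) y <- y + 0.5 * rhs(y)
  expect_lt(sqrt(sum(rhs(y)^2)), 1e-10)

  tr <- wc_integrate(p, y, dt = 0.01, n_steps = 500L)
  expect_equal(unname(c(tr$E[nrow(tr$E), ], tr$I[nrow(tr$I), ])), y,
               tolerance = 1e-9)

  # with a genuine delay, a constant history at the fixed point stays put
  net2 <- multiplex(er_layer(2, 1), er_layer(2, 1))
  p2 <- wc_params(P = 0.2, network = net2, eps = 0.02, tau = 0.1)
  # fixed point of the coupled homogeneous system
  rhs2 <- function(z) wc_velocity(z, z, p2)
  z <- rep(y, each = 2)
  for (i in 1:800) z <- z + 0.5 * rhs2(z)
  tr2 <- wc_integrate(p2, z, dt = 0.01, n_steps = 300L)
  expect_equal(unname(c(tr2$E[nrow(tr2$E), ], tr2$I[nrow(tr2$I), ])), z,
               tolerance = 1e-9)
})

test_that("zero delay reduces the DDE integrator to plain RK4", {
  p <- wc_params()
  y0 <- c(0.15, 0.07)
  dde <- wc_integrate(p, y0, dt = 0.01, n_steps = 400L)
  ode <- rk4_ref <- local({
    rhs <- function(y) wc_velocity(y, y, p)
    mkmcortex:::rk4_integrate_r(rhs, y0, 0.01, 400L)
  })
  expect_equal(c(dde$E[nrow(dde$E), ], dde$I[nrow(dde$I), ]),
               ode$states[nrow(ode$states), ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the delay must sit on the step grid", {
  net <- multiplex(er_layer(2, 1), er_layer(2, 1))
  p <- wc_params(network = net, eps = 0.05, tau = 0.015)
  expect_error(wc_integrate(p, rep(c(0.2, 0.1), each = 2), dt = 0.01,
                            n_steps = 10L), "multiple")
})

test_that("the delayed integrator converges at 4th order", {
  net <- multiplex(er_layer(2, 1), er_layer(2, 1))
  p <- wc_params(network = net, eps = 0.08, tau = 0.2)
  hist_fn <- function(t) c(0.2 + 0.05 * sin(t), 0.25, 0.1, 0.12 + 0.02 * t)
  final_at <- function(dt) {
    tr <- wc_integrate(p, hist_fn, dt = dt, n_steps = round(5 / dt),
                       record_stride = round(5 / dt))
    c(tr$E[2, ], tr$I[2, ])
  }
  e1 <- max(abs(final_at(0.01) - final_at(0.00125)))
  e2 <- max(abs(final_at(0.005) - final_at(0.00125)))
  # O(dt^4): halving dt should shrink the error by ~16 (8..32 accepted,
  # the reference at dt/8 biases the ratio slightly)
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 40)
})

test_that("the uncoupled limit cycle is unique, stable and discretization independent", {
  cyc <- default_cycle()
  expect_gt(cyc$T, 0)
  expect_lt(sqrt(sum((cyc$orbit[1, ] - cyc$orbit[nrow(cyc$orbit), ])^2)),
            1e-6)

  # uniqueness: the same period from scattered initial conditions
  inits <- list(c(0.05, 0.02), c(0.4, 0.1), c(0.2, 0.3), c(0.6, 0.05),
                c(0.33, 0.21))
  for (y0 in inits) {
    ti <- find_limit_cycle(wc_params(), init = y0, transient_time = 150)
    expect_equal(ti$T, cyc$T, tolerance = 1e-4)
  }

  # period converged in dt
  fine <- find_limit_cycle(wc_params(), dt = 0.0025)
  expect_equal(fine$T, cyc$T, tolerance = 1e-6)
})

test_that("the fixed-point regime reports a no-cycle error", {
  expect_error(find_limit_cycle(wc_params(P = 0.2)), "no limit cycle")
})

test_that("the Floquet exponent is negative, linear in the perturbation, and neutral along the flow", {
  p <- wc_params()
  cyc <- default_cycle()
  fl <- estimate_floquet_exponent(p, cyc)
  expect_lt(as.numeric(fl), 0)

  fl2 <- estimate_floquet_exponent(p, cyc, perturbation = c(0, 2e-4))
  expect_lt(abs(fl2 - fl) / abs(fl), 0.05)

  rhs <- function(y) wc_velocity(y, y, mkmcortex:::wc_uncoupled(p))
  fdir <- rhs(cyc$anchor)
  fdir <- fdir / sqrt(sum(fdir^2))
  fl_flow <- estimate_floquet_exponent(p, cyc, perturbation = 1e-4 * fdir,
                                       n_periods = 20)
  expect_lt(abs(as.numeric(fl_flow)), 0.01 * abs(as.numeric(fl)))
})

test_that("asymptotic phase is anchored, additive along the orbit, and continuous", {
  p <- wc_params()
  cyc <- default_cycle()
  expect_lt(min(asymptotic_phase(cyc$anchor, cyc, p) %% (2 * pi),
                2 * pi - asymptotic_phase(cyc$anchor, cyc, p) %% (2 * pi)),
            0.01)
  quarter <- cyc$orbit[nrow(cyc$orbit) %/% 4 + 1, ]
  expect_equal(asymptotic_phase(quarter, cyc, p), pi / 2, tolerance = 0.02 / (pi / 2))
  # small radial offset: the isochron shear near the anchor is steep, so
  # continuity is probed with a perturbation well inside the linear range
  radial <- cyc$anchor + c(0.003, 0.003)
  th <- asymptotic_phase(radial, cyc, p)
  expect_lt(min(th, 2 * pi - th), 0.1)
  far <- c(0.9, 0.9)
  expect_error(asymptotic_phase(far, cyc, p, horizon = 2), "converge")
})
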