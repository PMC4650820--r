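#' Logistic sigmoid response
#'
#' The population response function of the Wilson-Cowan equations,
#' `S(x) = 1 / (1 + exp(-gain * (x - threshold)))`: strictly increasing,
#' `S(threshold) = 1/2`, slope `gain/4` at the midpoint, saturating at 0
#' and 1.
#'
#' @param x input (net synaptic drive).
#' @param gain slope parameter (> 0).
#' @param threshold half-activation point.
#' @return values in `(0, 1)`.
#' @export
wc_sigmoid <- function(x, gain, threshold) {
  if (gain <= 0) stop_param("`gain` must be positive")
  1 / (1 + exp(-gain * (x - threshold)))
}

#' Wilson-Cowan network parameters
#'
#' Each cortical region holds an excitatory and an inhibitory population
#' with activities `E_i, I_i` (fractions of firing neurons) obeying
#' \deqn{\dot E_i = -E_i + S_E(c_{ee} E_i - c_{ei} I_i + P
#'   + \varepsilon (W^{EE} E)_i - \varepsilon (W^{EI} I(t-\tau))_i),}
#' \deqn{\dot I_i = -I_i + S_I(c_{ie} E_i - c_{ii} I_i + Q),}
#' i.e. relaxation towards a sigmoid of the net drive. Inter-regional
#' inputs are weak (scale `eps`); the excitatory channel acts instantly
#' while the inhibitory channel is lagged by the synaptic delay `tau`
#' (a synaptic, not axonal, delay). Under weak coupling this network
#' reduces to the two-layer multiplex Kuramoto model with phase shift
#' `beta = omega_bar * tau`.
#'
#' The default single-region coefficients (`c_ee = 16`, `c_ei = 12`,
#' `c_ie = 15`, `c_ii = 3`, gains 1.3 / 2, thresholds 4 / 3.7,
#' `P = 1.25`, `Q = 0`) are the classical oscillatory operating point of
#' the Wilson-Cowan model: a unique, exponentially stable limit cycle
#' (period about 6.6 relaxation times). Lowering `P` below about 0.9
#' destroys the cycle, which is how the fixed-point regime is reached in
#' tests.
#'
#' @param c_ee,c_ei,c_ie,c_ii within-region synaptic coefficients (first
#'   index = target population), all `>= 0`.
#' @param gain_e,gain_i sigmoid gains of the two populations.
#' @param theta_e,theta_i sigmoid thresholds.
#' @param P,Q external inputs to E and I (scalar or per-region vector).
#' @param tau inter-regional inhibitory synaptic delay (`>= 0`, time in
#'   units of the relaxation time constant).
#' @param eps inter-regional coupling scale (`>= 0`; weak coupling means
#'   `eps` small).
#' @param network an `mkm_multiplex` supplying the EE and EI coupling
#'   graphs (may be `NULL` for a single region).
#' @param W_ee,W_ei optional explicit per-pair coefficient matrices
#'   (row = receiving region); default to the network layer adjacencies.
#'   Directed (asymmetric) matrices are allowed.
#' @return an object of class `wc_params`.
#' @export
wc_params <- function(c_ee = 16, c_ei = 12, c_ie = 15, c_ii = 3,
                      gain_e = 1.3, gain_i = 2, theta_e = 4, theta_i = 3.7,
                      P = 1.25, Q = 0, tau = 0, eps = 0, network = NULL,
                      W_ee = NULL, W_ei = NULL) {
  if (any(c(c_ee, c_ei, c_ie, c_ii) < 0))
    stop_param("synaptic coefficients must be non-negative")
  if (tau < 0) stop_param("`tau` must be >= 0")
  if (eps < 0) stop_param("`eps` must be >= 0")
  n <- if (!is.null(network)) network$n
  else if (!is.null(W_ee)) nrow(W_ee)
  else 1L
  if (is.null(W_ee))
    W_ee <- if (!is.null(network)) as_adjacency(network$layer_ee)
    else matrix(0, n, n)
  if (is.null(W_ei))
    W_ei <- if (!is.null(network)) as_adjacency(network$layer_ei)
    else matrix(0, n, n)
  stopifnot(nrow(W_ee) == n, ncol(W_ee) == n,
            nrow(W_ei) == n, ncol(W_ei) == n)
  structure(list(n = n, c_ee = c_ee, c_ei = c_ei, c_ie = c_ie, c_ii = c_ii,
                 gain_e = gain_e, gain_i = gain_i, theta_e = theta_e,
                 theta_i = theta_i, P = rep_len(P, n), Q = rep_len(Q, n),
                 tau = tau, eps = eps, network = network,
                 W_ee = W_ee, W_ei = W_ei),
            class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat(sprintf(
    "<wc_params> n = %d regions, c = (%g, %g; %g, %g), gains (%g, %g), P = %g, Q = %g, tau = %g, eps = %g\n",
    x$n, x$c_ee, x$c_ei, x$c_ie, x$c_ii, x$gain_e, x$gain_i,
    x$P[1], x$Q[1], x$tau, x$eps))
  invisible(x)
}

# single-region copy (eps = 0, no network)
wc_uncoupled <- function(params) {
  p <- params
  p$n <- 1L
  p$eps <- 0
  p$network <- NULL
  p$W_ee <- p$W_ei <- matrix(0, 1L, 1L)
  p$P <- p$P[1L]
  p$Q <- p$Q[1L]
  p
}

#' Wilson-Cowan network velocity field
#'
#' Right-hand side of the delay-coupled network equations (see
#' [wc_params()]): the current state supplies everything except the
#' inter-regional inhibitory input, which is read from `delayed_state`
#' (the state at `t - tau`). With `eps = 0` regions decouple exactly.
#'
#' @param state numeric vector `c(E_1..E_n, I_1..I_n)`.
#' @param delayed_state state vector at `t - tau` (same layout); only its
#'   I-part is used.
#' @param params a [wc_params()] object.
#' @return derivative vector, same layout as `state`.
#' @export
wc_velocity <- function(state, delayed_state, params) {
  stopifnot(inherits(params, "wc_params"))
  n <- params$n
  if (length(state) != 2L * n || length(delayed_state) != 2L * n)
    stop_param("state vectors must have length 2n = %d", 2L * n)
  E <- state[1:n]
  I <- state[(n + 1):(2L * n)]
  I_del <- delayed_state[(n + 1):(2L * n)]
  drive_e <- params$c_ee * E - params$c_ei * I + params$P
  if (params$eps > 0) {
    drive_e <- drive_e + params$eps * (as.vector(params$W_ee %*% E) -
                                         as.vector(params$W_ei %*% I_del))
  }
  dE <- -E + wc_sigmoid(drive_e, params$gain_e, params$theta_e)
  dI <- -I + wc_sigmoid(params$c_ie * E - params$c_ii * I + params$Q,
                        params$gain_i, params$theta_i)
  c(dE, dI)
}

# cubic Hermite value at the midpoint of [t_k, t_k + dt]
hermite_mid <- function(y0, y1, f0, f1, dt) {
  (y0 + y1) / 2 + dt * (f0 - f1) / 8
}

#' Integrate the delay-coupled Wilson-Cowan network
#'
#' Method of steps with a classical RK4 stepper. The delay must be an
#' exact multiple of `dt` (grid-aligned); delayed values at the RK4
#' half-step stage times are reconstructed from the stored grid by cubic
#' Hermite interpolation (values plus stored derivatives), which keeps the
#' scheme 4th-order. With `tau = 0` the integration is a plain RK4 on the
#' ODE.
#'
#' @param params a [wc_params()] object.
#' @param history initial data on `[-tau, 0]`: either a state vector
#'   (constant history, also the state at `t = 0`) or a function of time
#'   `t <= 0` returning the state vector.
#' @param dt step size; `tau/dt` must be integer to within `1e-8`.
#' @param n_steps number of steps.
#' @param record_stride store every `record_stride`-th step.
#' @return a `wc_trajectory`: `times`, activity matrices `E` and `I`
#'   (rows = records), `params`, `dt`. Activities escaping
#'   `[-0.01, 1.01]` abort with a model-sanity error.
#' @export
wc_integrate <- function(params, history, dt = 0.01, n_steps = 1000L,
                         record_stride = 1L) {
  stopifnot(inherits(params, "wc_params"))
  n <- params$n
  m_real <- params$tau / dt
  m <- as.integer(round(m_real))
  if (abs(m_real - m) > 1e-8)
    stop_param(paste0("`tau` (%g) is not a multiple of `dt` (%g); ",
                      "adjust dt so tau/dt is integer"), params$tau, dt)
  n_steps <- as.integer(n_steps)
  record_stride <- as.integer(record_stride)
  if (n_steps %% record_stride != 0L)
    stop_param("`record_stride` must divide `n_steps`")
  hfun <- if (is.function(history)) history else {
    h0 <- as.numeric(history)
    function(t) h0
  }
  y0 <- hfun(0)
  if (length(y0) != 2L * n) stop_param("history must have length 2n = %d", 2L * n)

  n_grid <- m + n_steps + 1L   # rows: t = -m*dt ... n_steps*dt
  G <- matrix(NA_real_, n_grid, 2L * n)
  Fd <- matrix(NA_real_, n_grid, 2L * n)
  f0_left <- NULL
  if (m > 0L) {
    h <- min(1e-5, dt / 4)  # step-size independent, keeps the FD error
                            # far below the integrator's
    for (k in seq_len(m)) {
      t_k <- (k - 1L - m) * dt
      G[k, ] <- hfun(t_k)
      Fd[k, ] <- (hfun(t_k + h) - hfun(t_k - h)) / (2 * h)
    }
    # left-side derivative of the history at t = 0: the history need not
    # satisfy the equations, so this differs from the RHS at t = 0 and
    # must be used when interpolating over [-dt, 0]
    f0_left <- (3 * hfun(0) - 4 * hfun(-h) + hfun(-2 * h)) / (2 * h)
  }
  G[m + 1L, ] <- y0

  y <- y0
  n_rec <- n_steps %/% record_stride + 1L
  rec <- matrix(NA_real_, n_rec, 2L * n)
  rec[1L, ] <- y
  row <- 2L
  for (s in seq_len(n_steps) - 1L) {
    b <- m + 1L + s
    if (m > 0L) {
      d0v <- G[b - m, ]
      d1v <- G[b - m + 1L, ]
      f1 <- if (b - m + 1L == m + 1L) f0_left else Fd[b - m + 1L, ]
      dmid <- hermite_mid(d0v, d1v, Fd[b - m, ], f1, dt)
      k1 <- wc_velocity(y, d0v, params)
      Fd[b, ] <- k1
      k2 <- wc_velocity(y + dt / 2 * k1, dmid, params)
      k3 <- wc_velocity(y + dt / 2 * k2, dmid, params)
      k4 <- wc_velocity(y + dt * k3, d1v, params)
    } else {
      y2 <- y + dt / 2 * (k1 <- wc_velocity(y, y, params))
      y3 <- y + dt / 2 * (k2 <- wc_velocity(y2, y2, params))
      y4 <- y + dt * (k3 <- wc_velocity(y3, y3, params))
      k4 <- wc_velocity(y4, y4, params)
    }
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    G[b + 1L, ] <- y
    if ((s + 1L) %% record_stride == 0L) {
      if (any(!is.finite(y)) || any(y < -0.01) || any(y > 1.01))
        stop("activity left [-0.01, 1.01] at step ", s + 1L,
             ": model-sanity failure", call. = FALSE)
      rec[row, ] <- y
      row <- row + 1L
    }
  }
  structure(list(times = seq(0, by = dt * record_stride, length.out = n_rec),
                 E = rec[, 1:n, drop = FALSE],
                 I = rec[, (n + 1):(2L * n), drop = FALSE],
                 params = params, dt = dt, record_stride = record_stride),
            class = "wc_trajectory")
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf("<wc_trajectory> n = %d regions, %d records, t in [0, %.4g]\n",
              ncol(x$E), nrow(x$E), max(x$times)))
  invisible(x)
}

#' Write a Wilson-Cowan trajectory as TSV
#'
#' Columns: `time`, `E_1..E_n`, `I_1..I_n`.
#'
#' @param x a `wc_trajectory`.
#' @param path output path.
#' @export
write_wc_tsv <- function(x, path) {
  stopifnot(inherits(x, "wc_trajectory"))
  n <- ncol(x$E)
  df <- data.frame(time = x$times, x$E, x$I)
  names(df) <- c("time", paste0("E_", 1:n), paste0("I_", 1:n))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# interpolate a recorded single-region trajectory (cubic Hermite using the
# ODE's own derivative at the records)
interp_state <- function(tq, times, states, params) {
  dt <- times[2] - times[1]
  k <- pmin(pmax(floor((tq - times[1]) / dt) + 1, 1), length(times) - 1)
  t0 <- times[k]
  u <- (tq - t0) / dt
  y0 <- states[k, , drop = FALSE]
  y1 <- states[k + 1, , drop = FALSE]
  f0 <- t(apply(y0, 1, function(y) wc_velocity(y, y, params)))
  f1 <- t(apply(y1, 1, function(y) wc_velocity(y, y, params)))
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  y0 * h00 + dt * f0 * h10 + y1 * h01 + dt * f1 * h11
}

upward_crossings <- function(times, x, level) {
  below <- x[-length(x)] < level
  above <- x[-1] >= level
  idx <- which(below & above)
  if (!length(idx)) return(numeric(0))
  # linear interpolation of the crossing time
  t0 <- times[idx]
  frac <- (level - x[idx]) / (x[idx + 1] - x[idx])
  t0 + frac * diff(times)[1]
}

#' Locate the uncoupled limit cycle
#'
#' Integrates a single uncoupled region past its transient and detects the
#' period from successive upward crossings of a Poincare section (E equal
#' to its time mean). Fails with a no-cycle error when the dynamics settles
#' to a fixed point, and with a not-converged error when crossing intervals
#' stay irregular.
#'
#' @param params a [wc_params()] object; only the single-region part is
#'   used (`eps` forced to 0).
#' @param transient_time time to discard before detection.
#' @param horizon detection window after the transient.
#' @param dt step size.
#' @param tol relative tolerance on the crossing-interval spread.
#' @param init initial `(E, I)` state.
#' @param n_orbit number of stored orbit samples over one period.
#' @return a `wc_cycle`: period `T`, `omega` (`2*pi/T`), `orbit`
#'   (`n_orbit + 1` rows of `(E, I)` at equispaced phases, first and last
#'   rows coinciding), `phase` grid, `anchor` state (on the section, going
#'   up), `section` level, `params`, `dt`.
#' @export
find_limit_cycle <- function(params, transient_time = 150, horizon = 120,
                             dt = 0.005, tol = 1e-4,
                             init = c(0.1, 0.05), n_orbit = 2000L) {
  p <- wc_uncoupled(params)
  rhs <- function(y) wc_velocity(y, y, p)
  y <- init
  for (s in seq_len(ceiling(transient_time / dt))) y <- rk4_step_r(rhs, y, dt)
  n_steps <- ceiling(horizon / dt)
  sim <- rk4_integrate_r(rhs, y, dt, n_steps)
  Es <- sim$states[, 1]
  amp <- max(Es) - min(Es)
  if (amp < 1e-3)
    stop("no limit cycle: amplitude ", format(amp),
         " (fixed-point regime)", call. = FALSE)
  # a damped spiral keeps crossing its mean; require sustained amplitude
  q <- length(Es) %/% 5
  amp_head <- max(Es[1:q]) - min(Es[1:q])
  amp_tail <- max(Es[(length(Es) - q):length(Es)]) -
    min(Es[(length(Es) - q):length(Es)])
  if (amp_tail < 0.9 * amp_head)
    stop("no limit cycle: oscillation decaying (fixed-point regime)",
         call. = FALSE)
  level <- mean(Es)
  tc <- upward_crossings(sim$times, Es, level)
  if (length(tc) < 3L)
    stop("no limit cycle: fewer than 3 section crossings", call. = FALSE)
  iv <- diff(tc)
  T_per <- mean(iv)
  if (sd(iv) / T_per > tol)
    stop("period not converged: crossing intervals vary by ",
         format(sd(iv) / T_per), " (tol ", tol, ")", call. = FALSE)
  t_a <- tc[length(tc)] - T_per  # anchor crossing with a full period after it
  phase <- seq(0, 2 * pi, length.out = n_orbit + 1L)
  orbit <- interp_state(t_a + phase / (2 * pi) * T_per, sim$times, sim$states, p)
  structure(list(T = T_per, omega = 2 * pi / T_per, orbit = orbit,
                 phase = phase, anchor = orbit[1L, ], section = level,
                 params = p, dt = dt),
            class = "wc_cycle")
}

#' @export
print.wc_cycle <- function(x, ...) {
  cat(sprintf("<wc_cycle> period T = %.5f (omega = %.5f), section E = %.4f\n",
              x$T, x$omega, x$section))
  invisible(x)
}

# minimum Euclidean distance from point(s) to the polyline through the
# orbit samples (point-to-segment, so the floor is O(spacing^2 * curvature))
orbit_distance <- function(pts, orbit) {
  a <- orbit[-nrow(orbit), , drop = FALSE]
  b <- orbit[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  apply(pts, 1L, function(pp) {
    ap1 <- pp[1] - a[, 1]
    ap2 <- pp[2] - a[, 2]
    tt <- pmin(pmax((ap1 * ab[, 1] + ap2 * ab[, 2]) / len2, 0), 1)
    dx <- ap1 - tt * ab[, 1]
    dy <- ap2 - tt * ab[, 2]
    sqrt(min(dx^2 + dy^2))
  })
}

#' Floquet exponent of the limit cycle
#'
#' Measures the orbital stability rate: a perturbed copy of the anchor and
#' an on-cycle reference are integrated in lockstep, their deviation is
#' split into the component along the flow (the neutral phase direction,
#' Floquet multiplier 1) and the component normal to it, and the log of
#' the normal distance to the orbit is fitted against time. The slope is
#' the transverse Floquet exponent (negative = exponentially stable). A
#' perturbation along the flow direction leaves only an O(|perturbation|^2)
#' periodic normal residue, so its fitted rate is close to zero — the
#' neutral direction.
#'
#' @param params a [wc_params()] object (single-region part used).
#' @param cycle a `wc_cycle` from [find_limit_cycle()].
#' @param perturbation offset vector `(dE, dI)` applied to the anchor.
#'   Small values widen the window between the linear transverse signal
#'   (proportional to the size) and the quadratic tangential floor
#'   (proportional to its square); the default is `1e-4` on the I
#'   component.
#' @param n_periods fit window in cycle periods.
#' @param r2_min minimum R-squared demanded of the log-linear fit when the
#'   normal distance actually decays over more than one decade.
#' @return the decay rate (1/time); attribute `"r_squared"` carries the
#'   fit quality.
#' @export
estimate_floquet_exponent <- function(params, cycle,
                                      perturbation = c(0, 1e-4),
                                      n_periods = 10, r2_min = 0.9) {
  stopifnot(inherits(cycle, "wc_cycle"))
  p <- wc_uncoupled(params)
  rhs <- function(y) wc_velocity(y, y, p)
  dt <- cycle$dt
  n_steps <- ceiling(n_periods * cycle$T / dt)
  stride <- max(1L, n_steps %/% 500L)
  ref <- rk4_integrate_r(rhs, cycle$anchor, dt, n_steps, record_stride = stride)
  per <- rk4_integrate_r(rhs, cycle$anchor + perturbation, dt, n_steps,
                         record_stride = stride)
  dev <- per$states - ref$states
  fdir <- t(apply(ref$states, 1L, function(y) { v <- rhs(y); v / sqrt(sum(v^2)) }))
  tang <- rowSums(dev * fdir)
  dperp <- sqrt(pmax(rowSums(dev^2) - tang^2, 0))
  # stroboscopic samples once per period (at the anchor phase, where the
  # tangent is well conditioned); their decay is a clean power of the
  # transverse Floquet multiplier, free of within-period modulation
  k_max <- floor(ref$times[length(ref$times)] / cycle$T)
  t_k <- (0:k_max) * cycle$T
  idx <- vapply(t_k, function(tk) which.min(abs(ref$times - tk)), integer(1))
  valid <- which(dperp[idx] > 1e-6 * max(dperp[idx]))
  d_k <- dperp[idx][valid]
  tt_k <- t_k[valid]
  floor_d <- median(tail(d_k, 3L))
  if (length(d_k) >= 3L && d_k[1L] > 50 * floor_d) {
    # measurable contraction: fit the initial head of the series that is
    # still clear of the quadratic tangential floor, removing the floor's
    # quadrature contribution from the kept points
    head_run <- cumprod(d_k > 7 * floor_d) == 1
    keep <- seq_len(max(sum(head_run), 2L))
    d_k <- sqrt(pmax(d_k^2 - floor_d^2, (0.1 * floor_d)^2))
  } else {
    # no decade-scale decay (e.g. a flow-direction perturbation): the
    # stroboscopic series is flat and the fitted rate is near zero;
    # the first couple of periods still carry a decaying second-order
    # transient, so they are dropped
    keep <- if (length(d_k) > 4L) seq_along(d_k)[-(1:2)] else seq_along(d_k)
  }
  fit <- lm(log(d_k[keep]) ~ tt_k[keep])
  decades <- diff(range(log10(d_k[keep])))
  r2 <- summary(fit)$r.squared
  if (decades > 1 && r2 < r2_min)
    stop("unreliable Floquet estimate: log-distance fit R^2 = ",
         format(r2), " < ", r2_min, call. = FALSE)
  structure(unname(coef(fit)[2]), r_squared = r2)
}

#' Asymptotic phase of a state
#'
#' The asymptotic (isochron) phase of a state in the basin of the limit
#' cycle: integrate the uncoupled flow from the state; once the orbit is
#' reached, phase advances as `omega * t`, so the last upward section
#' crossing at time `t_c` pins the initial phase to
#' `theta = (-omega * t_c) mod 2*pi` (the anchor has phase 0 at its
#' crossing).
#'
#' @param state `(E, I)` state vector, or a matrix of states (one per row)
#'   for batch extraction.
#' @param cycle a `wc_cycle`.
#' @param params a [wc_params()] object (single-region part used).
#' @param horizon integration horizon (defaults to 10 periods, enough for
#'   the exponential transient at the default operating point).
#' @param basin_tol maximal admissible final distance to the orbit.
#' @return phase(s) in `[0, 2*pi)`.
#' @export
asymptotic_phase <- function(state, cycle, params,
                             horizon = 10 * cycle$T, basin_tol = 1e-3) {
  stopifnot(inherits(cycle, "wc_cycle"))
  p <- wc_uncoupled(params)
  pts <- if (is.matrix(state)) state else matrix(state, 1L)
  m <- nrow(pts)
  dt <- cycle$dt
  n_steps <- ceiling(horizon / dt)
  # batch RK4: states as an m x 2 matrix, the uncoupled field applied rowwise
  rhs_mat <- function(X) {
    E <- X[, 1]
    I <- X[, 2]
    cbind(-E + wc_sigmoid(p$c_ee * E - p$c_ei * I + p$P[1], p$gain_e, p$theta_e),
          -I + wc_sigmoid(p$c_ie * E - p$c_ii * I + p$Q[1], p$gain_i, p$theta_i))
  }
  X <- pts
  Etrace <- matrix(NA_real_, n_steps + 1L, m)
  Etrace[1L, ] <- X[, 1]
  for (s in seq_len(n_steps)) {
    k1 <- rhs_mat(X)
    k2 <- rhs_mat(X + dt / 2 * k1)
    k3 <- rhs_mat(X + dt / 2 * k2)
    k4 <- rhs_mat(X + dt * k3)
    X <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    Etrace[s + 1L, ] <- X[, 1]
  }
  dfin <- orbit_distance(X, cycle$orbit)
  if (any(dfin > basin_tol))
    stop("state did not converge to the limit cycle (final orbit distance ",
         format(max(dfin)), "): outside the basin or horizon too short",
         call. = FALSE)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  theta <- vapply(seq_len(m), function(j) {
    tc <- upward_crossings(times, Etrace[, j], cycle$section)
    if (!length(tc))
      stop("no section crossing found while extracting the phase",
           call. = FALSE)
    (-cycle$omega * tc[length(tc)]) %% (2 * pi)
  }, numeric(1))
  if (is.matrix(state)) theta else theta[[1]]
}

# history function: two uncoupled regions moving on the cycle with given
# initial phases (phase 0 = anchor), used as pre-delay initial data
cycle_history <- function(cycle, phases0) {
  force(cycle)
  force(phases0)
  function(t) {
    ph <- (phases0 + cycle$omega * t) %% (2 * pi)
    idx <- ph / (2 * pi) * (nrow(cycle$orbit) - 1L)
    k <- pmin(floor(idx) + 1L, nrow(cycle$orbit) - 1L)
    u <- idx - (k - 1L)
    st <- cycle$orbit[k, , drop = FALSE] * (1 - u) +
      cycle$orbit[k + 1L, , drop = FALSE] * u
    c(st[, 1], st[, 2])
  }
}

# closed-form Adler relaxation: dDelta/dt = -C sin(Delta)
adler_delta <- function(t, delta0, C) {
  2 * atan(tan(delta0 / 2) * exp(-C * t))
}

#' Phase-reduction discrepancy of a coupled Wilson-Cowan pair
#'
#' The weak-coupling claim made quantitative: two delay-coupled
#' Wilson-Cowan regions (single EE and EI edge) started a quarter period
#' apart are simulated at each coupling scale `eps`; the phase difference
#' `Delta(t)`, extracted through the asymptotic phase of each region, is
#' compared with the matched two-oscillator multiplex Kuramoto
#' prediction. For the symmetric pair that prediction is the Adler
#' relaxation `dDelta/dt = -C sin(Delta)` with
#' `C = 2 eps (k_ee + k_ei cos(beta))`; the single effective constant `C`
#' is fitted by least squares at the largest `eps` and rescaled
#' proportionally to `eps` for the others. The discrepancy per `eps` is
#' the maximal absolute difference between the extracted and the predicted
#' phase difference over the horizon; phase reduction predicts it shrinks
#' with `eps`.
#'
#' @param eps_list coupling scales, largest first (the first entry anchors
#'   the fit).
#' @param beta target phase shift; the delay is set to
#'   `tau = beta / omega_bar` snapped to the `dt` grid (the realized
#'   `beta_eff = omega_bar * tau` is reported).
#' @param pair_params single-region [wc_params()] defaults used for both
#'   regions.
#' @param horizon fixed comparison horizon (time units).
#' @param dt step size.
#' @param n_samples number of phase-extraction samples over the horizon.
#' @return a data.frame with one row per `eps`: `eps`, `C` (effective
#'   Adler constant used), `max_discrepancy` (radians); attributes
#'   `beta_eff`, `T`, `fit_C_per_eps`.
#' @export
phase_reduction_error <- function(eps_list = c(0.02, 0.01, 0.005),
                                  beta = pi / 4, pair_params = wc_params(),
                                  horizon = 250, dt = 0.005,
                                  n_samples = 60L) {
  cycle <- find_limit_cycle(pair_params, dt = dt)
  omega_bar <- cycle$omega
  m <- as.integer(round(beta / omega_bar / dt))
  tau <- m * dt
  beta_eff <- omega_bar * tau
  delta0 <- -pi / 2  # region 1 at the anchor, region 2 a quarter ahead

  extract_delta <- function(eps) {
    p2 <- pair_params
    p2$n <- 2L
    p2$P <- rep_len(pair_params$P, 2L)
    p2$Q <- rep_len(pair_params$Q, 2L)
    p2$eps <- eps
    p2$tau <- tau
    p2$W_ee <- p2$W_ei <- matrix(c(0, 1, 1, 0), 2L)
    hist_fn <- cycle_history(cycle, c(0, pi / 2))
    n_steps <- ceiling(horizon / dt)
    stride <- max(1L, n_steps %/% (n_samples * 4L))
    n_steps <- (n_steps %/% stride) * stride
    tr <- wc_integrate(p2, hist_fn, dt = dt, n_steps = n_steps,
                       record_stride = stride)
    take <- unique(round(seq(1L, length(tr$times), length.out = n_samples)))
    st1 <- cbind(tr$E[take, 1], tr$I[take, 1])
    st2 <- cbind(tr$E[take, 2], tr$I[take, 2])
    th1 <- asymptotic_phase(st1, cycle, pair_params)
    th2 <- asymptotic_phase(st2, cycle, pair_params)
    d <- wrap_phase(th1 - th2)
    # unwrap the difference series
    d <- d[1] + c(0, cumsum(wrap_phase(diff(d))))
    list(times = tr$times[take], delta = d)
  }

  eps_list <- sort(eps_list, decreasing = TRUE)
  ref <- extract_delta(eps_list[1])
  fit <- stats::optimize(function(C) {
    sum((ref$delta - adler_delta(ref$times, delta0, C))^2)
  }, interval = c(1e-6, 10))
  C1 <- fit$minimum
  c_per_eps <- C1 / eps_list[1]

  rows <- lapply(eps_list, function(eps) {
    xd <- if (eps == eps_list[1]) ref else extract_delta(eps)
    C <- c_per_eps * eps
    pred <- adler_delta(xd$times, delta0, C)
    data.frame(eps = eps, C = C,
               max_discrepancy = max(abs(xd$delta - pred)))
  })
  out <- do.call(rbind, rows)
  attr(out, "beta_eff") <- beta_eff
  attr(out, "T") <- cycle$T
  attr(out, "fit_C_per_eps") <- c_per_eps
  out
}

#' Locked phase lag of a driven Wilson-Cowan region
#'
#' One region (the receiver) is coupled unidirectionally to a free-running
#' driver through the EE and delayed EI channels. The multiplex Kuramoto
#' reduction predicts the receiver locks at the root of
#' `k_ee sin(Delta) + k_ei sin(Delta + beta) = 0`, i.e. at lag
#' `Delta = -beta/2` for equal channel weights: a delay `tau > 0` pulls
#' the locked lag negative. This helper measures that lag directly from
#' the activity dynamics.
#'
#' @param tau inhibitory delay applied on the inter-regional EI channel
#'   (snapped to the `dt` grid).
#' @param pair_params single-region [wc_params()] defaults.
#' @param eps coupling scale.
#' @param horizon locking horizon.
#' @param dt step size.
#' @return locked phase difference `Delta = theta_receiver - theta_driver`
#'   in `(-pi, pi]`; attribute `"beta_eff"`.
#' @export
locked_phase_lag <- function(tau, pair_params = wc_params(), eps = 0.03,
                             horizon = 300, dt = 0.005) {
  cycle <- find_limit_cycle(pair_params, dt = dt)
  m <- as.integer(round(tau / dt))
  tau <- m * dt
  p2 <- pair_params
  p2$n <- 2L
  p2$P <- rep_len(pair_params$P, 2L)
  p2$Q <- rep_len(pair_params$Q, 2L)
  p2$eps <- eps
  p2$tau <- tau
  # row = receiver: region 1 receives from region 2; region 2 runs free
  p2$W_ee <- p2$W_ei <- matrix(c(0, 1, 0, 0), 2L, 2L, byrow = TRUE)
  hist_fn <- cycle_history(cycle, c(0.3, 0))
  n_steps <- ceiling(horizon / dt)
  tr <- wc_integrate(p2, hist_fn, dt = dt, n_steps = n_steps,
                     record_stride = n_steps)
  st <- rbind(c(tr$E[2, 1], tr$I[2, 1]), c(tr$E[2, 2], tr$I[2, 2]))
  th <- asymptotic_phase(st, cycle, pair_params)
  structure(wrap_phase(th[1] - th[2]), beta_eff = cycle$omega * tau)
}
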