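#' Kuramoto order parameter
#'
#' Modulus and argument of the population-mean unit phasor
#' \eqn{r e^{i\psi} = n^{-1}\sum_j e^{i\varphi_j}}: a value of 0 is
#' complete incoherence, 1 full synchronization.
#'
#' @param phases numeric phase vector (radians, wrapped or unwrapped).
#' @return named numeric vector `c(r = , psi = )` with `psi` in `[0, 2*pi)`.
#' @examples
#' order_parameter(c(0, pi / 2))  # r = 1/sqrt(2), psi = pi/4
#' @export
order_parameter <- function(phases) {
  if (length(phases) < 1L) stop_param("`phases` must be non-empty")
  z <- mean(exp(1i * phases))
  c(r = Mod(z), psi = Arg(z) %% (2 * pi))
}

#' Order-parameter time series of a trajectory
#'
#' @param trajectory an `mkm_trajectory`.
#' @return list with `times`, `r`, `psi` (each per record).
#' @export
order_parameter_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "mkm_trajectory"))
  zc <- rowMeans(cos(trajectory$phases))
  zs <- rowMeans(sin(trajectory$phases))
  list(times = trajectory$times, r = sqrt(zc^2 + zs^2),
       psi = atan2(zs, zc) %% (2 * pi))
}

# record index of the first retained sample after a burn-in given in steps
burn_index <- function(trajectory, burn_in_steps) {
  idx <- floor(burn_in_steps / trajectory$record_stride) + 1L
  if (idx >= nrow(trajectory$phases))
    stop_param("burn-in leaves no retained samples")
  idx
}

#' Time-averaged order parameter
#'
#' Arithmetic mean of `r(t)` over the records after the burn-in window.
#'
#' @param trajectory an `mkm_trajectory`.
#' @param burn_in_steps transient steps to discard (defaults to the value
#'   recorded on the trajectory).
#' @return scalar `r_bar` in `[0, 1]`.
#' @export
time_averaged_order <- function(trajectory,
                                burn_in_steps = trajectory$burn_in_steps) {
  i0 <- burn_index(trajectory, burn_in_steps)
  s <- order_parameter_series(trajectory)
  mean(s$r[i0:length(s$r)])
}

new_lyapunov <- function(times, lambda_t, lambda_final, d0, mode,
                         renorm_interval, saturated, sep = NULL,
                         reference = NULL) {
  structure(list(times = times, lambda_t = lambda_t,
                 lambda_final = lambda_final, d0 = d0, mode = mode,
                 renorm_interval = renorm_interval, saturated = saturated,
                 sep = sep, reference = reference),
            class = "mkm_lyapunov")
}

#' @export
print.mkm_lyapunov <- function(x, ...) {
  cat(sprintf("<mkm_lyapunov> mode = %s, d0 = %g, lambda_final = %.5g%s\n",
              x$mode, x$d0, x$lambda_final,
              if (isTRUE(x$saturated)) " (saturated)" else ""))
  invisible(x)
}

#' Largest Lyapunov exponent by the twin-trajectory method
#'
#' Integrates a reference trajectory and a perturbed twin (initial
#' separation `d0` along a random direction) with the identical stepper and
#' measures their separation `d(t)`, the Euclidean norm of component-wise
#' phase differences wrapped to `(-pi, pi]` (the natural metric on the
#' phase torus, insensitive to winding counts).
#'
#' * `mode = "direct"` reports the instantaneous exponent
#'   \eqn{\lambda(t) = t^{-1}\log(d(t)/d_0)} verbatim; on chaotic runs
#'   `d(t)` eventually saturates at the torus scale and a warning suggests
#'   the renormalized mode.
#' * `mode = "renormalized"` (Benettin) rescales the offset back to `d0`
#'   every `renorm_interval` time units and accumulates the log stretch
#'   factors; `lambda_t` is the running mean growth rate and
#'   `lambda_final` the mean growth rate after discarding the first
#'   `burn_frac` of the horizon.
#'
#' For `mode = "direct"`, `lambda_final` is the late-time value
#' `lambda(t_end)`.
#'
#' @param model an [mkm()] object.
#' @param phases0 reference initial phases; sampled uniformly if `NULL`.
#' @param d0 initial separation (small; default `1e-8`).
#' @param dt,n_steps,record_stride as in [integrate_mkm()].
#' @param mode `"renormalized"` (default) or `"direct"`.
#' @param renorm_interval rescaling interval in time units (renormalized
#'   mode); snapped to the step grid.
#' @param burn_frac fraction of the horizon discarded before averaging the
#'   renormalized growth rate.
#' @param seed seed for initial phases and perturbation direction.
#' @param keep_reference also return the reference trajectory (as an
#'   `mkm_trajectory`), so synchronization and frequency observables can be
#'   computed from the same run.
#' @return an `mkm_lyapunov` object: `times`, `lambda_t`, `lambda_final`,
#'   `d0`, `mode`, `renorm_interval`, `saturated`, and optionally
#'   `reference`.
#' @export
instantaneous_lyapunov <- function(model, phases0 = NULL, d0 = 1e-8,
                                   dt = 0.01, n_steps = 1e5,
                                   record_stride = 10L,
                                   mode = c("renormalized", "direct"),
                                   renorm_interval = 1, burn_frac = 0.2,
                                   seed = NULL, keep_reference = FALSE) {
  stopifnot(inherits(model, "mkm"))
  mode <- match.arg(mode)
  if (!is.numeric(d0) || d0 <= 0) stop_param("`d0` must be positive")
  n_steps <- as.integer(n_steps)
  record_stride <- as.integer(record_stride)
  if (record_stride < 1L || n_steps %% record_stride != 0L)
    stop_param("`record_stride` must be a positive divisor of `n_steps`")
  n <- model$network$n
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    as.list(derive_seeds(seed, 2L, offset = 100L))
  if (is.null(phases0)) phases0 <- sample_initial_phases(n, seeds[[1]])
  pert <- with_seed_if(seeds[[2]], rnorm(n))
  pert <- pert / sqrt(sum(pert^2)) * d0
  renorm_every <- if (mode == "renormalized") {
    re <- as.integer(round(renorm_interval / dt))
    if (re < 1L) stop_param("`renorm_interval` must be >= dt")
    re
  } else 0L
  ea <- edge_arrays(model)
  res <- mkm_twin_cpp(as.numeric(phases0), pert, d0, ea$ee_a, ea$ee_b,
                      ea$ei_a, ea$ei_b, n, model$network$mean_degree_ee,
                      model$network$mean_degree_ei, model$omega, model$K,
                      model$beta, dt, n_steps, record_stride, renorm_every,
                      keep_reference)
  times <- seq(0, by = dt * record_stride, length.out = length(res$cumlog))
  lambda_t <- c(NA_real_, res$cumlog[-1] / times[-1])
  i_burn <- max(2L, floor(burn_frac * (length(times) - 1L)) + 1L)
  lambda_final <- if (mode == "renormalized") {
    (res$cumlog[length(times)] - res$cumlog[i_burn]) /
      (times[length(times)] - times[i_burn])
  } else {
    lambda_t[length(times)]
  }
  if (mode == "direct" && isTRUE(res$saturated))
    warning("twin separation reached the wrapping scale; the direct ",
            "estimate is saturated -- use mode = \"renormalized\"",
            call. = FALSE)
  reference <- if (keep_reference) {
    new_trajectory(times, res$reference, model, dt, record_stride,
                   burn_in_steps = floor(n_steps / 5), seed = seed)
  }
  new_lyapunov(times, lambda_t, lambda_final, d0, mode, renorm_interval,
               isTRUE(res$saturated), sep = res$sep, reference = reference)
}

#' Twin-trajectory Lyapunov estimate for an arbitrary flow
#'
#' Pure-R counterpart of [instantaneous_lyapunov()] for any autonomous RHS
#' `rhs(x) -> dx/dt`, using the same classical RK4 stepper on reference and
#' twin. Serves small validation systems (e.g. linear flows with known
#' exponents) and as an independent cross-check of the compiled path.
#'
#' @param rhs function mapping a state vector to its time derivative.
#' @param x0 initial state.
#' @param wrap treat components as angles (wrap differences to
#'   `(-pi, pi]`) as on a phase torus.
#' @inheritParams instantaneous_lyapunov
#' @param pert0 optional explicit initial offset (length of `x0`; rescaled
#'   to norm `d0`); default is a random direction.
#' @return an `mkm_lyapunov` object.
#' @export
twin_lyapunov <- function(rhs, x0, d0 = 1e-8, dt = 0.01, n_steps = 1e4,
                          record_stride = 10L,
                          mode = c("renormalized", "direct"),
                          renorm_interval = 1, burn_frac = 0.2,
                          wrap = FALSE, pert0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n_steps <- as.integer(n_steps)
  record_stride <- as.integer(record_stride)
  if (is.null(pert0)) pert0 <- with_seed_if(seed, rnorm(length(x0)))
  pert0 <- pert0 / sqrt(sum(pert0^2)) * d0
  renorm_every <- if (mode == "renormalized")
    max(1L, as.integer(round(renorm_interval / dt))) else 0L
  diff_fn <- if (wrap) function(x, y) wrap_phase(y - x) else function(x, y) y - x

  x <- x0
  y <- x0 + pert0
  n_rec <- n_steps %/% record_stride + 1L
  cumlog <- sep <- numeric(n_rec)
  sep[1L] <- sqrt(sum(diff_fn(x, y)^2))
  acc <- 0
  row <- 2L
  saturated <- FALSE
  for (step in seq_len(n_steps)) {
    x <- rk4_step_r(rhs, x, dt)
    y <- rk4_step_r(rhs, y, dt)
    if (step %% record_stride == 0L) {
      d <- sqrt(sum(diff_fn(x, y)^2))
      sep[row] <- d
      cumlog[row] <- acc + log(d / d0)
      if (renorm_every == 0L && wrap && d > sqrt(length(x0)))
        saturated <- TRUE
      row <- row + 1L
    }
    if (renorm_every > 0L && step %% renorm_every == 0L) {
      w <- diff_fn(x, y)
      d <- sqrt(sum(w^2))
      acc <- acc + log(d / d0)
      y <- x + w * (d0 / d)
    }
  }
  times <- seq(0, by = dt * record_stride, length.out = n_rec)
  lambda_t <- c(NA_real_, cumlog[-1] / times[-1])
  i_burn <- max(2L, floor(burn_frac * (n_rec - 1L)) + 1L)
  lambda_final <- if (mode == "renormalized") {
    (cumlog[n_rec] - cumlog[i_burn]) / (times[n_rec] - times[i_burn])
  } else lambda_t[n_rec]
  new_lyapunov(times, lambda_t, lambda_final, d0, mode, renorm_interval,
               saturated, sep = sep)
}

#' Stationary mean frequency deviations
#'
#' Per-region stationary frequencies
#' \eqn{\Omega_i = (\varphi_i(t_{end}) - \varphi_i(t_{burn})) /
#' (t_{end} - t_{burn})} from the *unwrapped* phases — exact endpoint
#' bookkeeping, insensitive to oscillatory transients to order
#' `1/window`. Negative population mean `Omega` is frequency suppression:
#' the slow-wave shift accompanying the transition into the synchronized
#' (epileptiform) regime.
#'
#' @inheritParams time_averaged_order
#' @return an `mkm_freqstats` object: `omega_i` (per region), `omega_bar`
#'   (population mean), `t_window`, `n`.
#' @export
mean_frequency_deviations <- function(trajectory,
                                      burn_in_steps = trajectory$burn_in_steps) {
  i0 <- burn_index(trajectory, burn_in_steps)
  ph <- trajectory$phases
  if (nrow(ph) - i0 < 1L) stop_param("need >= 2 retained samples")
  # wrapped-phase input guard: consecutive records of an unwrapped
  # trajectory move by velocity * record interval; a jump of more than pi
  # alongside a much smaller overall drift betrays modulo-wrapped input
  dt_rec <- trajectory$dt * trajectory$record_stride
  steps <- diff(ph[i0:nrow(ph), , drop = FALSE])
  if (length(steps) && max(abs(steps)) > pi) {
    drift <- abs(ph[nrow(ph), ] - ph[i0, ]) /
      (trajectory$times[nrow(ph)] - trajectory$times[i0])
    if (max(abs(steps)) / dt_rec > 4 * max(drift, 1))
      stop_param(paste0("phase jumps exceed pi between records while the ",
                        "mean drift is moderate: input looks ",
                        "modulo-wrapped, but unwrapped phases are required"))
  }
  t_window <- trajectory$times[nrow(ph)] - trajectory$times[i0]
  omega_i <- (ph[nrow(ph), ] - ph[i0, ]) / t_window
  structure(list(omega_i = omega_i, omega_bar = mean(omega_i),
                 t_window = t_window, n = ncol(ph)),
            class = "mkm_freqstats")
}

#' @export
print.mkm_freqstats <- function(x, ...) {
  cat(sprintf(
    "<mkm_freqstats> n = %d, Omega = %.5g, spread (sd) = %.5g, window = %.4g\n",
    x$n, x$omega_bar, sd(x$omega_i), x$t_window))
  invisible(x)
}

#' Density histogram of stationary frequency deviations
#'
#' @param freq_stats an `mkm_freqstats` from
#'   [mean_frequency_deviations()].
#' @param bins number of equal-width bins (>= 2).
#' @return list with `breaks`, `density` (integrating to 1), `mids`, and
#'   `spread` (the standard deviation of the per-region deviations, the
#'   summary used to quantify distribution narrowing).
#' @export
frequency_histogram <- function(freq_stats, bins = 30L) {
  stopifnot(inherits(freq_stats, "mkm_freqstats"))
  if (bins < 2L) stop_param("`bins` must be >= 2")
  x <- freq_stats$omega_i
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, density = h$density, mids = h$mids,
       spread = sd(x))
}
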