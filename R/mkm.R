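#' Sample natural frequencies
#'
#' Natural frequencies are the constant part of each region's deviation
#' from the common carrier oscillation. The model's phenomenology only
#' requires a symmetric, unimodal distribution; the default is standard
#' normal. With `center = TRUE` the sample mean is subtracted, enforcing
#' the zero-mean convention exactly (a rotating-frame transformation makes
#' this a pure convention, not a restriction).
#'
#' @param n number of oscillators.
#' @param distribution one of `"standard_normal"`, `"cauchy"`, `"uniform"`.
#' @param seed optional integer seed.
#' @param center subtract the sample mean (default `TRUE`).
#' @param gamma Cauchy half-width at half-maximum (scale), used when
#'   `distribution = "cauchy"`.
#' @param half_width half-width of the symmetric uniform distribution on
#'   `[-half_width, half_width]`.
#' @return numeric vector of length `n`.
#' @export
sample_natural_frequencies <- function(n,
                                       distribution = c("standard_normal",
                                                        "cauchy", "uniform"),
                                       seed = NULL, center = TRUE,
                                       gamma = 0.5, half_width = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_param("`n` must be a positive integer")
  distribution <- match.arg(distribution)
  omega <- with_seed_if(seed, switch(
    distribution,
    standard_normal = rnorm(n),
    cauchy = rcauchy(n, scale = gamma),
    uniform = runif(n, -half_width, half_width)
  ))
  if (center) {
    omega <- omega - mean(omega)
    omega <- omega - mean(omega)  # second pass clears the rounding residue
  }
  omega
}

#' Sample initial phase deviations
#'
#' Uniform i.i.d. draws on `[0, 2*pi)`, the standard incoherent initial
#' condition.
#'
#' @inheritParams sample_natural_frequencies
#' @return numeric vector of length `n` in `[0, 2*pi)`.
#' @export
sample_initial_phases <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_param("`n` must be a positive integer")
  with_seed_if(seed, runif(n, 0, 2 * pi))
}

#' Two-layer multiplex Kuramoto model
#'
#' Builds the model object for the phase-deviation dynamics
#' \deqn{\dot\varphi_i = \omega_i
#'   + \frac{K}{\langle k^{EE}\rangle}\sum_j A^{EE}_{ij}
#'       \sin(\varphi_j - \varphi_i)
#'   + \frac{K}{\langle k^{EI}\rangle}\sum_j A^{EI}_{ij}
#'       \sin(\varphi_j - \varphi_i - \beta),}
#' where the EE layer couples excitatory populations directly and the EI
#' layer carries the inhibitory channel whose synaptic delay \eqn{\tau}
#' appears as the Sakaguchi phase shift \eqn{\beta = \bar\omega\tau}. The
#' global coupling `K` plays the role of an overall connection strength
#' (physiologically tied to cerebral blood flow); `beta` tracks the
#' synaptic GABA concentration. At `beta = 0` with identical layers the
#' model collapses onto the classical Kuramoto model.
#'
#' @param network an `mkm_multiplex` (see [multiplex()]).
#' @param K global coupling, `K >= 0`.
#' @param beta Sakaguchi phase shift (radians) on the EI layer.
#' @param omega natural-frequency vector of length `network$n`; defaults to
#'   centered standard-normal draws (seeded via `seed`).
#' @param seed seed used only when `omega` is sampled here.
#' @return an object of class `mkm`.
#' @examples
#' m <- mkm(er_multiplex(50, 0.2, seed = 1), K = 1, beta = 0.5, seed = 2)
#' m
#' @seealso [integrate_mkm()], [mkm_velocity()], [simulate.mkm()]
#' @export
mkm <- function(network, K, beta = 0, omega = NULL, seed = NULL) {
  stopifnot(inherits(network, "mkm_multiplex"))
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0)
    stop_param("`K` must be a single non-negative number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop_param("`beta` must be a single finite number")
  if (is.null(omega))
    omega <- sample_natural_frequencies(network$n, seed = seed)
  if (length(omega) != network$n)
    stop_param("`omega` must have length %d (one per region)", network$n)
  structure(list(network = network, K = K, beta = beta,
                 omega = as.numeric(omega)),
            class = "mkm")
}

#' @export
print.mkm <- function(x, ...) {
  cat(sprintf(
    "<mkm> n = %d regions, K = %g, beta = %g\n  EE <k> = %.3f, EI <k> = %.3f, omega: mean %.3g, sd %.3g\n",
    x$network$n, x$K, x$beta, x$network$mean_degree_ee,
    x$network$mean_degree_ei, mean(x$omega), sd(x$omega)))
  invisible(x)
}

# 0-based edge arrays for the compiled core
edge_arrays <- function(model) {
  if (model$network$mean_degree_ee == 0 || model$network$mean_degree_ei == 0)
    stop("cannot integrate: a layer has zero edges, so its mean-degree ",
         "normalization is undefined", call. = FALSE)
  ee <- model$network$layer_ee$edges - 1L
  ei <- model$network$layer_ei$edges - 1L
  list(ee_a = ee[, 1L], ee_b = ee[, 2L], ei_a = ei[, 1L], ei_b = ei[, 2L])
}

#' Instantaneous phase velocity of the multiplex Kuramoto model
#'
#' Evaluates the right-hand side of the model equation (see [mkm()]) at a
#' phase vector. This is the same compiled kernel the integrator uses.
#'
#' @param phases numeric vector of length `n` (phase deviations, radians).
#' @param model an [mkm()] object.
#' @return numeric vector of phase velocities.
#' @export
mkm_velocity <- function(phases, model) {
  stopifnot(inherits(model, "mkm"))
  if (length(phases) != model$network$n)
    stop_param("`phases` must have length %d", model$network$n)
  ea <- edge_arrays(model)
  mkm_velocity_cpp(as.numeric(phases), ea$ee_a, ea$ee_b, ea$ei_a, ea$ei_b,
                   model$network$n, model$network$mean_degree_ee,
                   model$network$mean_degree_ei, model$omega, model$K,
                   model$beta)
}

new_trajectory <- function(times, phases, model, dt, record_stride,
                           burn_in_steps, seed = NULL) {
  structure(list(times = times, phases = phases, model = model, dt = dt,
                 record_stride = record_stride,
                 burn_in_steps = burn_in_steps, seed = seed),
            class = "mkm_trajectory")
}

#' Integrate the multiplex Kuramoto model
#'
#' Fixed-step classical 4th-order Runge-Kutta. Phases are stored
#' *unwrapped* (no modulo is applied to the state), which makes stationary
#' frequency estimation an exact endpoint difference; wrapping happens only
#' inside observables that need it.
#'
#' @param model an [mkm()] object.
#' @param phases0 initial phase deviations (length `n`); defaults to
#'   uniform draws on `[0, 2*pi)` seeded by `seed`.
#' @param dt time step (rescaled time units).
#' @param n_steps number of RK4 steps.
#' @param record_stride store every `record_stride`-th step (step 0
#'   included); must divide `n_steps`.
#' @param burn_in_steps transient steps that downstream time averages
#'   discard (recorded on the trajectory; default `n_steps / 5`, i.e. 2e4
#'   of the default 1e5).
#' @param seed seed for a sampled `phases0`.
#' @return an `mkm_trajectory`: `times`, `phases` (rows = records, columns
#'   = regions), the model snapshot and the discretization metadata.
#' @examples
#' m <- mkm(er_multiplex(30, 0.3, seed = 1), K = 2, seed = 2)
#' tr <- integrate_mkm(m, dt = 0.01, n_steps = 2000, seed = 3)
#' tail(order_parameter_series(tr)$r, 1)
#' @export
integrate_mkm <- function(model, phases0 = NULL, dt = 0.01, n_steps = 1e5,
                          record_stride = 10L,
                          burn_in_steps = floor(n_steps / 5), seed = NULL) {
  stopifnot(inherits(model, "mkm"))
  if (!is.numeric(dt) || dt <= 0) stop_param("`dt` must be positive")
  n_steps <- as.integer(n_steps)
  record_stride <- as.integer(record_stride)
  if (n_steps < 1L) stop_param("`n_steps` must be >= 1")
  if (record_stride < 1L || n_steps %% record_stride != 0L)
    stop_param("`record_stride` must be a positive divisor of `n_steps`")
  n <- model$network$n
  if (is.null(phases0)) phases0 <- sample_initial_phases(n, seed = seed)
  if (length(phases0) != n) stop_param("`phases0` must have length %d", n)
  ea <- edge_arrays(model)
  ph <- mkm_rk4_cpp(as.numeric(phases0), ea$ee_a, ea$ee_b, ea$ei_a, ea$ei_b,
                    n, model$network$mean_degree_ee,
                    model$network$mean_degree_ei, model$omega, model$K,
                    model$beta, dt, n_steps, record_stride)
  times <- seq(0, by = dt * record_stride, length.out = nrow(ph))
  new_trajectory(times, ph, model, dt, record_stride,
                 as.integer(burn_in_steps), seed)
}

#' @export
print.mkm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mkm_trajectory> n = %d regions, %d records, t in [0, %.4g], dt = %g (stride %d)\n",
    ncol(x$phases), nrow(x$phases), max(x$times), x$dt, x$record_stride))
  invisible(x)
}

#' Simulate the model from random initial conditions
#'
#' `simulate()` draws fresh uniform initial phases for each replicate and
#' integrates; replicate `i` uses sub-seed `i` of `seed` via
#' [derive_seeds()].
#'
#' @param object an [mkm()] object.
#' @param nsim number of replicates.
#' @param seed master seed (optional).
#' @param ... passed to [integrate_mkm()] (`dt`, `n_steps`, ...).
#' @return a single `mkm_trajectory` when `nsim = 1`, else a list of them.
#' @export
simulate.mkm <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) vector("list", nsim) else
    as.list(derive_seeds(seed, nsim))
  out <- lapply(seeds, function(s) integrate_mkm(object, seed = s, ...))
  if (nsim == 1) out[[1]] else out
}

#' Write a trajectory as TSV plus a JSON run manifest
#'
#' The table has a `time` column and one `phi_<i>` column per region; the
#' manifest records every parameter and seed needed to reproduce the run.
#'
#' @param x an `mkm_trajectory`.
#' @param path output TSV path; the manifest lands at `<path>.manifest.json`.
#' @return invisibly, `path`.
#' @export
write_trajectory_tsv <- function(x, path) {
  stopifnot(inherits(x, "mkm_trajectory"))
  df <- data.frame(time = x$times, x$phases)
  names(df) <- c("time", paste0("phi_", seq_len(ncol(x$phases))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- x$model
  manifest <- list(
    kind = "mkm_trajectory", n = m$network$n, K = m$K, beta = m$beta,
    omega = m$omega, dt = x$dt, n_steps = (nrow(x$phases) - 1L) * x$record_stride,
    record_stride = x$record_stride, burn_in_steps = x$burn_in_steps,
    seed = x$seed,
    edges_ee = m$network$layer_ee$edges - 1L,
    edges_ei = m$network$layer_ei$edges - 1L,
    output = basename(path))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
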