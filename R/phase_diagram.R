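# internal counter of compiled twin integrations, used to verify that
# cached sweep cells are served without touching the integrator
.mkm_counters <- new.env(parent = emptyenv())
.mkm_counters$integrations <- 0L

integration_count <- function() .mkm_counters$integrations
bump_integrations <- function() {
  .mkm_counters$integrations <- .mkm_counters$integrations + 1L
}

#' Sweep configuration
#'
#' Bundles every knob of a `(K, beta)` phase-diagram sweep: the control
#' grids, the random-network and frequency settings, the integrator
#' protocol, the number of independent runs per cell, and the master seed
#' from which all per-run sub-seeds derive (see [derive_seeds()]).
#'
#' Defaults mirror the reference simulation protocol: `n = 100` regions,
#' two independent Erdős–Rényi layers with `p = 0.1` (mean degree about
#' 10, above percolation), centered standard-normal natural frequencies,
#' RK4 with `dt = 0.01` for `1e5` steps discarding the first `2e4`, and
#' averages over `n_runs = 10` independent realizations of network,
#' frequencies and initial phases per cell.
#'
#' @param K_grid,beta_grid numeric grids of the control plane.
#' @param n regions per run.
#' @param p_ee,p_ei layer edge probabilities; `complete = TRUE` overrides
#'   both with complete graphs.
#' @param complete use complete layers (mean-field setting).
#' @param omega_dist,gamma,half_width frequency distribution (see
#'   [sample_natural_frequencies()]).
#' @param dt,n_steps,burn_in,record_stride integrator protocol.
#' @param n_runs independent runs per cell.
#' @param master_seed integer master seed.
#' @param d0,renorm_interval twin-trajectory Lyapunov settings.
#' @return an object of class `mkm_sweep_config`.
#' @export
sweep_config <- function(K_grid = seq(0, 3, length.out = 6),
                         beta_grid = seq(0, 1.6, length.out = 6),
                         n = 100L, p_ee = 0.1, p_ei = 0.1, complete = FALSE,
                         omega_dist = "standard_normal", gamma = 0.5,
                         half_width = 1, dt = 0.01, n_steps = 1e5,
                         burn_in = 2e4, record_stride = 10L, n_runs = 10L,
                         master_seed = 1L, d0 = 1e-8, renorm_interval = 1) {
  if (!length(K_grid) || !length(beta_grid))
    stop_param("control grids must be non-empty")
  if (any(K_grid < 0)) stop_param("couplings must be >= 0")
  if (burn_in >= n_steps) stop_param("`burn_in` must be < `n_steps`")
  structure(list(K_grid = as.numeric(K_grid),
                 beta_grid = as.numeric(beta_grid), n = as.integer(n),
                 p_ee = p_ee, p_ei = p_ei, complete = isTRUE(complete),
                 omega_dist = omega_dist, gamma = gamma,
                 half_width = half_width, dt = dt,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 record_stride = as.integer(record_stride),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed), d0 = d0,
                 renorm_interval = renorm_interval),
            class = "mkm_sweep_config")
}

#' @export
print.mkm_sweep_config <- function(x, ...) {
  cat(sprintf(
    "<mkm_sweep_config> %d x %d grid, n = %d, %s layers, %d runs/cell, %g steps (burn %g), master seed %d\n",
    length(x$K_grid), length(x$beta_grid), x$n,
    if (x$complete) "complete" else sprintf("ER p = (%g, %g)", x$p_ee, x$p_ei),
    x$n_runs, x$n_steps, x$burn_in, x$master_seed))
  invisible(x)
}

# deterministic per-run seed block: four sub-seeds (network, omega, phi0,
# perturbation) per (cell, run) index
run_seeds <- function(config, K, beta, run) {
  iK <- which(abs(config$K_grid - K) < 1e-12)[1]
  ib <- which(abs(config$beta_grid - beta) < 1e-12)[1]
  if (is.na(iK)) iK <- 0L
  if (is.na(ib)) ib <- 0L
  cell_index <- (ib - 1L) * length(config$K_grid) + iK
  derive_seeds(config$master_seed, 4L,
               offset = 4L * (cell_index * config$n_runs + run))
}

# complete graphs are deterministic; cache the multiplex per node count
complete_multiplex <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      full <- er_layer(n, 1, seed = 1L)
      cache[[key]] <- multiplex(full, full)
    }
    cache[[key]]
  }
})

# one independent realization: network + frequencies + initial phases
# (+ twin Lyapunov integration unless lyapunov = FALSE); returns the
# scalar observables
single_run <- function(config, K, beta, run, lyapunov = TRUE) {
  seeds <- run_seeds(config, K, beta, run)
  net <- if (config$complete) complete_multiplex(config$n) else
    multiplex(er_layer(config$n, config$p_ee, seeds[1]),
              er_layer(config$n, config$p_ei, seeds[1] + 1L))
  omega <- sample_natural_frequencies(config$n, config$omega_dist,
                                      seed = seeds[2], center = TRUE,
                                      gamma = config$gamma,
                                      half_width = config$half_width)
  model <- mkm(net, K = K, beta = beta, omega = omega)
  phi0 <- sample_initial_phases(config$n, seeds[3])
  bump_integrations()
  if (lyapunov) {
    ly <- instantaneous_lyapunov(model, phases0 = phi0, d0 = config$d0,
                                 dt = config$dt, n_steps = config$n_steps,
                                 record_stride = config$record_stride,
                                 mode = "renormalized",
                                 renorm_interval = config$renorm_interval,
                                 seed = seeds[4], keep_reference = TRUE)
    traj <- ly$reference
    lambda <- ly$lambda_final
  } else {
    traj <- integrate_mkm(model, phases0 = phi0, dt = config$dt,
                          n_steps = config$n_steps,
                          record_stride = config$record_stride)
    lambda <- NA_real_
  }
  traj$burn_in_steps <- config$burn_in
  fs <- mean_frequency_deviations(traj)
  c(r_bar = time_averaged_order(traj), lambda = lambda,
    omega_bar = fs$omega_bar, spread = sd(fs$omega_i))
}

#' Evaluate one phase-diagram cell
#'
#' Runs `config$n_runs` independent realizations at fixed `(K, beta)` —
#' fresh layers, natural frequencies and initial phases per run, all
#' seeded from the master seed — and aggregates the time-averaged order
#' parameter, the renormalized twin-trajectory Lyapunov exponent, the mean
#' stationary frequency deviation and its per-region spread. Failed runs
#' are recorded and excluded; the cell is flagged when more than 20% fail.
#'
#' @param K,beta cell coordinates.
#' @param config an [sweep_config()].
#' @param thresholds classification thresholds, see [classify_cell()].
#' @return a one-row data.frame (class `mkm_cell`): `K`, `beta`, mean and
#'   sd of each observable, `n_runs`, `n_failed`, `flagged`, `label`.
#' @export
run_cell <- function(K, beta, config, thresholds = phase_thresholds()) {
  stopifnot(inherits(config, "mkm_sweep_config"))
  res <- vector("list", config$n_runs)
  failed <- 0L
  for (run in seq_len(config$n_runs)) {
    res[[run]] <- tryCatch(single_run(config, K, beta, run),
                           error = function(e) {
                             warning("run ", run, " at (K = ", K, ", beta = ",
                                     beta, ") failed: ", conditionMessage(e),
                                     call. = FALSE)
                             NULL
                           })
    if (is.null(res[[run]])) failed <- failed + 1L
  }
  ok <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(ok) || !nrow(ok))
    stop("all runs failed at (K = ", K, ", beta = ", beta, ")", call. = FALSE)
  cell <- data.frame(
    K = K, beta = beta,
    r_mean = mean(ok[, "r_bar"]), r_sd = sd(ok[, "r_bar"]),
    lambda_mean = mean(ok[, "lambda"]), lambda_sd = sd(ok[, "lambda"]),
    omega_mean = mean(ok[, "omega_bar"]), omega_sd = sd(ok[, "omega_bar"]),
    spread_mean = mean(ok[, "spread"]), spread_sd = sd(ok[, "spread"]),
    n_runs = nrow(ok), n_failed = failed,
    flagged = failed > 0.2 * config$n_runs)
  cell$label <- classify_cell(cell, thresholds)
  class(cell) <- c("mkm_cell", "data.frame")
  cell
}

#' Classification thresholds for the three regimes
#'
#' The incoherent floor of the order parameter at finite size is about
#' `1/sqrt(n)` (0.1 at n = 100), motivating `r_incoherent = 0.3`;
#' `r_sync = 0.8` marks strong synchronization; `lambda_chaos = 0.02`
#' sits above the noise scale of the finite-time Lyapunov estimate.
#'
#' @param r_sync,r_incoherent,lambda_chaos threshold values.
#' @return named list of thresholds.
#' @export
phase_thresholds <- function(r_sync = 0.8, r_incoherent = 0.3,
                             lambda_chaos = 0.02) {
  list(r_sync = r_sync, r_incoherent = r_incoherent,
       lambda_chaos = lambda_chaos)
}

#' Classify a phase-diagram cell
#'
#' Chaotic if the mean Lyapunov exponent exceeds `lambda_chaos`; otherwise
#' synchronized if the mean order parameter exceeds `r_sync`;
#' unsynchronized if it is below `r_incoherent`; `"boundary"` in between.
#' The three macroscopic regimes map onto cortical activity as:
#' unsynchronized = background, synchronized = epileptiform, chaotic (with
#' synchronized clusters) = resting-state.
#'
#' @param cell a one-row data.frame with `r_mean` and `lambda_mean` (or
#'   named scalars).
#' @param thresholds see [phase_thresholds()].
#' @return one of `"chaotic"`, `"synchronized"`, `"unsynchronized"`,
#'   `"boundary"`.
#' @export
classify_cell <- function(cell, thresholds = phase_thresholds()) {
  r <- if (is.data.frame(cell)) cell$r_mean else cell[["r_mean"]]
  l <- if (is.data.frame(cell)) cell$lambda_mean else cell[["lambda_mean"]]
  if (l > thresholds$lambda_chaos) "chaotic"
  else if (r > thresholds$r_sync) "synchronized"
  else if (r < thresholds$r_incoherent) "unsynchronized"
  else "boundary"
}

cell_cache_path <- function(cache_dir, K, beta, master_seed) {
  file.path(cache_dir, sprintf("cell_K%.8g_b%.8g_s%d.tsv", K, beta,
                               master_seed))
}

#' Sweep the (K, beta) control plane
#'
#' One [run_cell()] per grid point. With a `cache_dir`, finished cells are
#' written as one-row TSV files keyed by `(K, beta, master seed)` and
#' served from disk on re-runs without touching the integrator, making
#' long sweeps resumable.
#'
#' @param config an [sweep_config()].
#' @param thresholds see [phase_thresholds()].
#' @param cache_dir optional cell cache directory.
#' @param verbose print one line per finished cell.
#' @return a data.frame (class `mkm_sweep`) with one row per cell, columns
#'   as in [run_cell()], row order: K fastest, beta slowest.
#' @export
phase_sweep <- function(config, thresholds = phase_thresholds(),
                        cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "mkm_sweep_config"))
  if (!is.null(cache_dir))
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  i <- 0L
  for (beta in config$beta_grid) {
    for (K in config$K_grid) {
      i <- i + 1L
      cp <- if (!is.null(cache_dir))
        cell_cache_path(cache_dir, K, beta, config$master_seed)
      cell <- if (!is.null(cp) && file.exists(cp)) {
        read.table(cp, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
      } else {
        fresh <- run_cell(K, beta, config, thresholds)
        if (!is.null(cp))
          write.table(fresh, cp, sep = "\t", quote = FALSE,
                      row.names = FALSE)
        fresh
      }
      if (verbose)
        message(sprintf("cell %d/%d (K = %.3g, beta = %.3g): r = %.3f, lambda = %.4f -> %s",
                        i, length(config$K_grid) * length(config$beta_grid),
                        K, beta, cell$r_mean, cell$lambda_mean, cell$label))
      rows[[i]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "thresholds") <- thresholds
  class(out) <- c("mkm_sweep", "data.frame")
  out
}

#' Write sweep results as a TSV table
#'
#' Fixed column order (`K`, `beta`, `r_mean`, `r_sd`, `lambda_mean`,
#' `lambda_sd`, `omega_mean`, `omega_sd`, `spread_mean`, `spread_sd`,
#' `n_runs`, `n_failed`, `flagged`, `label`) for bit-exact diffing.
#'
#' @param x an `mkm_sweep`.
#' @param path output path.
#' @export
write_sweep_tsv <- function(x, path) {
  cols <- c("K", "beta", "r_mean", "r_sd", "lambda_mean", "lambda_sd",
            "omega_mean", "omega_sd", "spread_mean", "spread_sd",
            "n_runs", "n_failed", "flagged", "label")
  write.table(as.data.frame(x)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Heat-map view of a sweep
#'
#' Renders one observable of the sweep table over the `(K, beta)` grid.
#'
#' @param x an `mkm_sweep`.
#' @param what column to render (default `"r_mean"`).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.mkm_sweep <- function(x, what = "r_mean", ...) {
  config <- attr(x, "config")
  K <- sort(unique(x$K))
  b <- sort(unique(x$beta))
  z <- matrix(NA_real_, length(K), length(b))
  for (r in seq_len(nrow(x)))
    z[match(x$K[r], K), match(x$beta[r], b)] <- x[[what]][r]
  image(K, b, z, xlab = "K (coupling)", ylab = "beta (phase shift)",
        main = what, col = hcl.colors(64, "viridis"), ...)
  invisible(z)
}

#' Locate the critical coupling by bisection
#'
#' At `beta = 0` the model undergoes a classical Kuramoto transition at a
#' critical coupling `K_c`. For the mean-field (complete identical layers)
#' canonical form, the two layer sums add, so
#' `K_c = 1 / (pi * g(0))`: `gamma` for Cauchy(`gamma`) frequencies,
#' `sqrt(2*pi)/pi` for standard-normal ones.
#'
#' The estimator bisects `K` against the crossing of the run-averaged
#' order parameter through `level`. The default level is `r_incoherent`
#' (0.3), just above the incoherent finite-size band: on the supercritical
#' branch the order parameter rises steeply from the transition, so a low
#' crossing level lands near `K_c`, whereas levels well inside the
#' synchronized branch (say 0.55) sit far above it (for Cauchy frequencies
#' the mean-field branch reaches 0.55 only at `1.43 * K_c`).
#'
#' @param config an [sweep_config()]; its `beta_grid` is ignored
#'   (`beta = 0` is enforced) and its `K_grid` is unused.
#' @param K_range bracketing interval `c(lo, hi)`.
#' @param tol bracket width at which bisection stops.
#' @param level order-parameter crossing level.
#' @param thresholds supplies the default `level`.
#' @return the bracket midpoint; attributes `"bracket"`, `"r_lo"`,
#'   `"r_hi"`, `"level"`.
#' @export
locate_critical_coupling <- function(config, K_range, tol = 0.02,
                                     level = NULL,
                                     thresholds = phase_thresholds()) {
  stopifnot(inherits(config, "mkm_sweep_config"))
  level <- level %||% thresholds$r_incoherent
  r_at <- function(K) {
    vals <- vapply(seq_len(config$n_runs), function(run) {
      single_run(config, K, 0, run, lyapunov = FALSE)[["r_bar"]]
    }, numeric(1))
    mean(vals)
  }
  lo <- K_range[1]
  hi <- K_range[2]
  r_lo <- r_at(lo)
  r_hi <- r_at(hi)
  if (r_lo >= level || r_hi <= level)
    stop("crossing level ", level, " not bracketed by K_range (r = ",
         format(r_lo, digits = 3), " .. ", format(r_hi, digits = 3), ")",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (r_at(mid) < level) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), r_lo = r_lo, r_hi = r_hi,
            level = level)
}
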