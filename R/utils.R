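`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles (radians).
#' @return `x` reduced modulo `2*pi` into the interval `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * floor(x / (2 * pi) + 0.5)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic draws in a sweep (network realizations, natural
#' frequencies, initial phases, Lyapunov perturbation directions) take their
#' seeds from a single master seed through this fixed linear-congruential
#' counter scheme, so "identical, independent runs" are bit-reproducible:
#' `subseed(master, i) = (1103515245 * ((master + i) mod 65536)
#'                        + 12345 + 2654435 * i) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @param offset counter offset of the first sub-seed (distinct draws in one
#'   run use distinct offsets).
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n = 1L, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  i <- offset + seq_len(n) - 1
  s <- (1103515245 * ((master + i) %% 65536) + 12345 + 2654435 * i) %%
    2147483647
  as.integer(s + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed uses the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# Classical RK4 on a plain ODE given as an R function rhs(x) -> dx/dt.
# Kept in base R as the reference stepper for small systems and as the
# independent route against which the compiled integrator is checked.
rk4_step_r <- function(rhs, x, dt) {
  k1 <- rhs(x)
  k2 <- rhs(x + dt / 2 * k1)
  k3 <- rhs(x + dt / 2 * k2)
  k4 <- rhs(x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

rk4_integrate_r <- function(rhs, x0, dt, n_steps, record_stride = 1L) {
  n_rec <- n_steps %/% record_stride + 1L
  out <- matrix(NA_real_, n_rec, length(x0))
  out[1L, ] <- x0
  x <- x0
  row <- 2L
  for (step in seq_len(n_steps)) {
    x <- rk4_step_r(rhs, x, dt)
    if (step %% record_stride == 0L) {
      out[row, ] <- x
      row <- row + 1L
    }
  }
  list(times = seq(0, by = dt * record_stride, length.out = n_rec),
       states = out)
}
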