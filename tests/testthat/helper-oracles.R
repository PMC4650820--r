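# Independent oracles and small fixtures used across the suite.

# plain double-loop evaluation of the multiplex Kuramoto right-hand side
# from the adjacency matrices -- deliberately naive and independent of the
# compiled kernel
naive_mkm_velocity <- function(phases, model) {
  A <- as_adjacency(model$network$layer_ee)
  B <- as_adjacency(model$network$layer_ei)
  n <- model$network$n
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- model$omega[i]
    for (j in seq_len(n)) {
      if (A[i, j] == 1)
        acc <- acc + model$K / model$network$mean_degree_ee *
          sin(phases[j] - phases[i])
      if (B[i, j] == 1)
        acc <- acc + model$K / model$network$mean_degree_ei *
          sin(phases[j] - phases[i] - model$beta)
    }
    out[i] <- acc
  }
  out
}

# classical single-network Kuramoto right-hand side
single_layer_kuramoto <- function(phases, A, K, omega) {
  k_mean <- mean(rowSums(A))
  omega + K / k_mean * rowSums(A * sin(outer(phases, phases, function(a, b) b - a)))
}

ring_layer <- function(n) {
  layer(n, cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
}

# two oscillators, both layers a single edge, unit mean degrees
two_osc_model <- function(K, beta, omega) {
  l <- layer(2, matrix(c(1L, 2L), 1L))
  mkm(suppressWarnings(multiplex(l, l)), K = K, beta = beta, omega = omega)
}
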