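# shared fixtures, all built in code

path3_adjacency <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  A
}

# random connected graph: a spanning path plus extra random edges
random_connected_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ord <- sample(n)
  for (k in seq_len(n - 1)) {
    A[ord[k], ord[k + 1]] <- A[ord[k + 1], ord[k]] <- 1
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1
  }
  A
}

tiny_hierarchy <- function(n_super = 2, areas_per_super = 3, seed = 5) {
  make_nested_lattice(n_super, areas_per_super, seed = seed)
}

# smallest usable panel: given Y and E matrices over a hierarchy
panel_from_matrices <- function(Y, E, hierarchy, times = seq_len(ncol(Y))) {
  df <- data.frame(
    area = rep(hierarchy$area_ids, times = ncol(Y)),
    year = rep(times, each = nrow(Y)),
    births = as.vector(Y),
    expected = as.vector(E)
  )
  panel_counts(df, hierarchy)
}

# one-area one-time panel (alpha-only checks)
single_cell_panel <- function(y, e) {
  h <- nested_hierarchy("A1", "S1", c(A1 = "S1"),
                        matrix(0, 1, 1), matrix(0, 1, 1))
  panel_from_matrices(matrix(y, 1, 1), matrix(e, 1, 1), h)
}

quick_sampler <- function(iterations = 600, burn_in = 150, seed = 1) {
  sampler_config(iterations = iterations, burn_in = burn_in, seed = seed)
}

random_effect_state <- function(hierarchy, n_times, seed = 1) {
  set.seed(seed)
  n1 <- hierarchy$n1
  n2 <- hierarchy$n2
  effect_state(
    alpha = rnorm(1),
    mu = rnorm(n1, sd = 0.3), v = rnorm(n1, sd = 0.2),
    gamma = rnorm(n_times, sd = 0.2), phi = rnorm(n_times, sd = 0.1),
    delta = matrix(rnorm(n1 * n_times, sd = 0.1), n1, n_times),
    omega = rnorm(n2, sd = 0.3), xi = rnorm(n2, sd = 0.2),
    zeta = matrix(rnorm(n2 * n_times, sd = 0.1), n2, n_times),
    precisions = c(mu = 10, v = 25, gamma = 25, phi = 100, delta = 100,
                   omega = 10, xi = 25, zeta = 100)
  )
}
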