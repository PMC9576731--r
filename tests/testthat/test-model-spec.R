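test_that("expected counts apply one overall rate and conserve the total", {
  # two areas, one time, overall rate 0.1
  expect_equal(expected_counts(c(25, 15), c(100, 300)), c(10, 30))
  # constant-rate data give E proportional to N
  N <- matrix(c(100, 200, 400, 800), 2, 2)
  Y <- 0.05 * N
  E <- expected_counts(Y, N)
  expect_equal(E, Y)  # rho-hat is exactly 1
  # conservation on a random panel
  set.seed(8)
  Y <- matrix(rpois(12, 40), 3, 4)
  N <- matrix(runif(12, 500, 1500), 3, 4)
  expect_equal(sum(expected_counts(Y, N)), sum(Y))
  expect_error(expected_counts(c(1, 2), c(10, -1)), "positive")
})

test_that("panel construction validates shape and standardises populations", {
  h <- tiny_hierarchy()
  df <- data.frame(area = rep(h$area_ids, 2), year = rep(1:2, each = 6),
                   births = 5, population = 1000)
  p <- panel_counts(df, h)
  expect_equal(dim(p$Y), c(6, 2))
  expect_equal(sum(p$E), sum(p$Y))
  expect_error(panel_counts(df[-1, ], h), "rectangle")
  df$births[1] <- -1
  expect_error(panel_counts(df, h), "nonnegative")
})

test_that("panel CSV round-trips", {
  h <- tiny_hierarchy()
  set.seed(2)
  Y <- matrix(rpois(12, 100), 6, 2)
  E <- matrix(runif(12, 50, 150), 6, 2)
  p <- panel_from_matrices(Y, E, h)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, tmp)
  p2 <- read_panel(tmp, h)
  expect_equal(p2$Y, p$Y)
  expect_equal(p2$E, p$E)
})

test_that("linear predictor matches a naive per-cell loop", {
  h <- tiny_hierarchy()
  TT <- 4
  st <- random_effect_state(h, TT, seed = 11)
  eta <- linear_predictor(st, h, "model1", n_times = TT)
  for (i in seq_len(h$n1)) {
    for (t in seq_len(TT)) {
      j <- h$super_index[i]
      expect_equal(unname(eta[i, t]),
                   st$alpha + st$mu[i] + st$v[i] + st$gamma[t] + st$phi[t] +
                     st$delta[i, t] + st$omega[j] + st$xi[j] + st$zeta[j, t])
    }
  }
  # identity and constant cases
  z <- effect_state(alpha = 0)
  expect_equal(exp(linear_predictor(z, h, "model2", n_times = 2)),
               matrix(1, 6, 2), ignore_attr = TRUE)
  z5 <- effect_state(alpha = 0.5)
  expect_equal(linear_predictor(z5, h, "model1", n_times = 3),
               matrix(0.5, 6, 3), ignore_attr = TRUE)
  # model2 ignores the super-region terms
  eta2 <- linear_predictor(st, h, "model2", n_times = TT)
  expect_equal(unname(eta2[2, 3]),
               st$alpha + st$mu[2] + st$v[2] + st$gamma[3] + st$phi[3] +
                 st$delta[2, 3])
  bad <- st; bad$mu <- bad$mu[-1]
  expect_error(linear_predictor(bad, h, "model1", n_times = TT), "mismatch")
})

test_that("Poisson log likelihood is exact and invariant to E-rho rescaling", {
  p0 <- single_cell_panel(0, 1)
  ll <- log_likelihood(effect_state(alpha = 0), p0, "model2")
  expect_equal(ll$total, -1)  # Poisson(1) at 0
  # large-count cell against a direct Stirling-form evaluation
  y <- 48000; lam <- 47500
  p1 <- single_cell_panel(y, lam)
  ll1 <- log_likelihood(effect_state(alpha = 0), p1, "model2")
  direct <- y * log(lam) - lam - (0.5 * log(2 * pi * y) +
    y * log(y) - y + 1 / (12 * y))
  expect_equal(ll1$total, direct, tolerance = 1e-8)
  # doubling E while halving rho leaves lambda unchanged
  h <- tiny_hierarchy()
  set.seed(4)
  Y <- matrix(rpois(12, 80), 6, 2)
  E <- matrix(runif(12, 40, 120), 6, 2)
  st <- effect_state(alpha = 0.3)
  la <- log_likelihood(st, panel_from_matrices(Y, E, h), "model2")
  lb <- log_likelihood(effect_state(alpha = 0.3 - log(2)),
                       panel_from_matrices(Y, 2 * E, h), "model2")
  expect_equal(la$total, lb$total)
  expect_equal(la$pointwise, lb$pointwise)
})

test_that("log prior quadratic forms match brute-force sums", {
  h <- tiny_hierarchy()
  TT <- 4
  cfg <- model_config("model1", type1 = 4, type2 = 2)
  str <- model_structures(h, TT, cfg)
  st <- random_effect_state(h, TT, seed = 21)

  # RW1 part: gamma quadratic form is the sum of squared increments
  qf_gamma <- drop(crossprod(st$gamma, str$gamma$R$entries %*% st$gamma))
  expect_equal(qf_gamma, sum(diff(st$gamma)^2))
  # ICAR part: pairwise sum over edges
  A <- h$area_adjacency
  qf_mu <- drop(crossprod(st$mu, str$mu$R$entries %*% st$mu))
  brute <- 0
  for (i in seq_len(h$n1)) for (k in seq_len(h$n1)) {
    if (k > i && A[i, k] == 1) brute <- brute + (st$mu[i] - st$mu[k])^2
  }
  expect_equal(qf_mu, brute)
  # a constant gamma lies in the RW1 null space
  stc <- st; stc$gamma <- rep(0.7, TT)
  expect_equal(drop(crossprod(stc$gamma, str$gamma$R$entries %*% stc$gamma)),
               0, tolerance = 1e-12)
  # zeroing the GMRF components changes the prior only through the
  # quadratic forms
  st0 <- st
  st0$mu <- st0$mu * 0; st0$gamma <- st0$gamma * 0
  st0$delta <- st0$delta * 0; st0$omega <- st0$omega * 0
  st0$zeta <- st0$zeta * 0
  qf_all <- qf_mu + qf_gamma +
    drop(crossprod(vec_delta <- as.vector(t(st$delta)),
                   str$delta$R$entries %*% vec_delta)) +
    drop(crossprod(st$omega, str$omega$R$entries %*% st$omega)) +
    drop(crossprod(vec_zeta <- as.vector(t(st$zeta)),
                   str$zeta$R$entries %*% vec_zeta))
  tau <- st$precisions
  expect_equal(log_prior(st0, str, cfg) - log_prior(st, str, cfg),
               (tau[["mu"]] * qf_mu + tau[["gamma"]] * qf_gamma +
                  tau[["delta"]] * drop(crossprod(vec_delta,
                                                  str$delta$R$entries %*% vec_delta)) +
                  tau[["omega"]] * drop(crossprod(st$omega,
                                                  str$omega$R$entries %*% st$omega)) +
                  tau[["zeta"]] * drop(crossprod(vec_zeta,
                                                 str$zeta$R$entries %*% vec_zeta))) / 2)
  bad <- st; bad$precisions[["mu"]] <- -1
  expect_error(effect_state(precisions = bad$precisions), "positive")
})

test_that("log prior is invariant to null-space shifts, motivating constraints", {
  h <- tiny_hierarchy()
  cfg <- model_config("model1", type1 = 4, type2 = 4)
  str <- model_structures(h, 4, cfg)
  st <- random_effect_state(h, 4, seed = 31)
  sh <- st
  sh$gamma <- sh$gamma + 5       # constant: RW1 null space
  sh$mu <- sh$mu + 3             # constant: ICAR null space (connected)
  expect_equal(log_prior(sh, str, cfg), log_prior(st, str, cfg))
})

test_that("constraint centring is idempotent and preserves the predictor", {
  h <- tiny_hierarchy()
  TT <- 4
  for (types in list(c(1, 1), c(2, 3), c(4, 4))) {
    cfg <- model_config("model1", type1 = types[1], type2 = types[2])
    str <- model_structures(h, TT, cfg)
    st <- random_effect_state(h, TT, seed = 41 + types[1])
    cs <- apply_constraints(st, str, h, cfg)
    # linear predictor unchanged cell-by-cell
    expect_equal(linear_predictor(cs, h, "model1", n_times = TT),
                 linear_predictor(st, h, "model1", n_times = TT),
                 tolerance = 1e-12)
    # constraints hold
    expect_equal(sum(cs$mu), 0, tolerance = 1e-10)
    expect_equal(sum(cs$gamma), 0, tolerance = 1e-10)
    expect_equal(sum(cs$omega), 0, tolerance = 1e-10)
    if (types[1] %in% c(2, 4))
      expect_equal(rowSums(cs$delta), rep(0, h$n1), tolerance = 1e-10)
    if (types[1] %in% c(3, 4))
      expect_equal(colSums(cs$delta), rep(0, TT), tolerance = 1e-10)
    # idempotent
    cs2 <- apply_constraints(cs, str, h, cfg)
    expect_equal(cs2, cs, tolerance = 1e-12)
  }
})

test_that("a shift of c between alpha and mu is undone by constraining", {
  h <- tiny_hierarchy()
  cfg <- model_config("model1", type1 = 4, type2 = 4)
  str <- model_structures(h, 3, cfg)
  st <- apply_constraints(random_effect_state(h, 3, seed = 51), str, h, cfg)
  sh <- st
  sh$mu <- sh$mu + 0.9
  sh$alpha <- sh$alpha - 0.9
  back <- apply_constraints(sh, str, h, cfg)
  expect_equal(back$mu, st$mu, tolerance = 1e-12)
  expect_equal(back$alpha, st$alpha, tolerance = 1e-12)
})
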