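test_that("sampler configuration validates its invariants", {
  expect_error(sampler_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_config(thin = 0), "thin")
  s <- sampler_config(iterations = 500, burn_in = 100, thin = 2)
  expect_equal(s$iterations, 500L)
})

test_that("two chains with the same seed give identical results", {
  sim <- simulate_panel(simulation_design(n_super = 2, areas_per_super = 3,
                                          times = 1:4, seed = 6))
  cfg <- model_config("model1", 2, 3)
  f1 <- nestbym(sim$panel, cfg, quick_sampler(seed = 42))
  f2 <- nestbym(sim$panel, cfg, quick_sampler(seed = 42))
  expect_identical(f1$summaries, f2$summaries)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- nestbym(sim$panel, cfg, quick_sampler(seed = 43))
  expect_false(identical(f1$summaries$mean, f3$summaries$mean))
})

test_that("posterior summaries have ordered quantiles and full diagnostics", {
  sim <- simulate_panel(simulation_design(n_super = 2, areas_per_super = 3,
                                          times = 1:4, seed = 6))
  f <- nestbym(sim$panel, model_config("model1", 4, 4), quick_sampler())
  expect_true(all(f$summaries$q2.5 <= f$summaries$q50))
  expect_true(all(f$summaries$q50 <= f$summaries$q97.5))
  expect_equal(f$n_draws, 450)
  expect_named(f$diagnostics$acceptance,
               c("alpha", "mu", "v", "gamma", "phi", "delta",
                 "omega", "xi", "zeta"))
  expect_true(all(f$diagnostics$acceptance > 0.5))
  # every retained draw satisfies the sum-to-zero constraints
  expect_lt(max(abs(rowSums(f$draws$effects$mu))), 1e-8)
  expect_lt(max(abs(rowSums(f$draws$effects$gamma))), 1e-8)
  expect_lt(max(abs(rowSums(f$draws$effects$omega))), 1e-8)
})

test_that("the intercept-only posterior matches dense-grid integration", {
  p <- single_cell_panel(5, 1)
  oracle <- grid_oracle(p)
  f <- nestbym(p, model_config("model2", components = character(0)),
               sampler_config(iterations = 4500, burn_in = 500, seed = 3))
  mc <- posterior_summary(f, "alpha")
  expect_lt(abs(mc$mean - oracle$mean), 0.02)
  expect_lt(abs(mc$sd - oracle$sd), 0.05)
  expect_lt(abs(mc$q50 - oracle$q50), 0.03)
})

test_that("a weak-likelihood posterior collapses to the prior", {
  # E near zero and y = 0: the likelihood is flat, the oracle returns the
  # prior, centred at zero
  p <- single_cell_panel(0, 1e-9)
  o <- grid_oracle(p, components = "v", precisions = c(v = 4))
  expect_lt(abs(o$mean[o$param == "v[1]"]), 0.05)
  expect_equal(o$sd[o$param == "v[1]"], 0.5, tolerance = 0.05)
})

test_that("symmetric two-area models give symmetric posteriors", {
  h <- nested_hierarchy(c("a", "b"), "s", c(a = "s", b = "s"),
                        matrix(c(0, 1, 1, 0), 2, 2), matrix(0, 1, 1))
  p <- panel_from_matrices(matrix(c(20, 20), 2, 1),
                           matrix(c(10, 10), 2, 1), h)
  o <- grid_oracle(p, components = "v", precisions = c(v = 10), n_grid = 101)
  vs <- o[o$param %in% c("v[1]", "v[2]"), ]
  expect_equal(vs$mean[1], vs$mean[2], tolerance = 1e-6)
  expect_equal(vs$sd[1], vs$sd[2], tolerance = 1e-6)
})

test_that("MCMC agrees with the grid oracle on small sub-models", {
  # alpha plus two iid area effects with fixed precision: 3 latent scalars
  h <- nested_hierarchy(c("a", "b"), "s", c(a = "s", b = "s"),
                        matrix(c(0, 1, 1, 0), 2, 2), matrix(0, 1, 1))
  p <- panel_from_matrices(matrix(c(24, 11), 2, 1),
                           matrix(c(15, 15), 2, 1), h)
  o <- grid_oracle(p, components = "v", precisions = c(v = 6))
  f <- nestbym(p, model_config("model2", components = "v",
                               fixed_precisions = c(v = 6)),
               sampler_config(iterations = 5500, burn_in = 500, seed = 8))
  for (pa in c("alpha", "v[a]", "v[b]")) {
    op <- sub("\\[a\\]", "[1]", sub("\\[b\\]", "[2]", pa))
    mc <- posterior_summary(f, pa)
    expect_lt(abs(mc$mean - o$mean[o$param == op]), 0.02)
    expect_lt(abs(mc$sd - o$sd[o$param == op]), 0.05)
  }
})

test_that("the oracle rejects what it cannot integrate", {
  h <- tiny_hierarchy()
  p <- panel_from_matrices(matrix(10, 6, 1), matrix(10, 6, 1), h)
  expect_error(grid_oracle(p, components = "v", precisions = c(v = 1)),
               "exceeds")
  expect_error(grid_oracle(p, components = "mu", precisions = c(mu = 1)),
               "iid components only")
})

test_that("with the likelihood switched off the precisions sample their prior", {
  # y = 0 with E ~ 0 leaves the posterior equal to the prior; the marginal
  # moments of log tau must match log Gamma(0.5, 0.0005)
  h <- tiny_hierarchy(seed = 9)
  p <- panel_from_matrices(matrix(0, 6, 3), matrix(1e-9, 6, 3), h)
  # the flat likelihood legitimately triggers the low-acceptance diagnostic
  f <- suppressWarnings(
    nestbym(p, model_config("model2", 1),
            sampler_config(iterations = 2500, burn_in = 500, seed = 5)))
  lt <- log(f$draws$tau[, "delta"])
  expect_lt(abs(mean(lt) - (digamma(0.5) - log(0.0005))), 0.35)
  expect_lt(abs(sd(lt) - sqrt(trigamma(0.5))), 0.35)
})

test_that("alpha recovery on a strongly informative simulated panel", {
  sim <- simulate_panel(simulation_design(alpha = 0.3, seed = 17))
  f <- nestbym(sim$panel, model_config("model1", 4, 4),
               sampler_config(iterations = 700, burn_in = 250, seed = 1))
  a <- posterior_summary(f, "alpha")
  expect_gt(a$q97.5, 0.3 - 0.4)
  expect_lt(a$q2.5, 0.3 + 0.4)
})
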