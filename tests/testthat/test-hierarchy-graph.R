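test_that("ICAR structure matches the neighbour-count / minus-adjacency form", {
  sm <- icar_structure(path3_adjacency())
  expect_equal(sm$entries,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(sm$rank, 2L)
  expect_equal(sm$null_space_dim, 1L)
  expect_equal(rowSums(sm$entries), rep(0, 3), ignore_attr = TRUE)
})

test_that("ICAR flags islands and counts them as their own components", {
  expect_warning(sm <- icar_structure(matrix(0, 4, 4)), "island")
  expect_equal(sm$islands, 1:4, ignore_attr = TRUE)
  expect_equal(sm$rank, 0L)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1  # one edge, two islands
  expect_warning(sm2 <- icar_structure(A), "3, 4")
  expect_equal(sm2$rank, 1L)  # 4 nodes - 3 components
})

test_that("ICAR implies the neighbour-average full conditional on random graphs", {
  for (seed in 1:3) {
    A <- random_connected_graph(10, seed = seed)
    sm <- icar_structure(A)
    R <- sm$entries
    set.seed(seed + 100)
    m <- rnorm(10)
    tau <- runif(1, 0.5, 4)
    for (cc in 1:10) {
      nc <- sum(A[cc, ])
      # brute force from the joint density: condition the quadratic form
      cond_prec <- tau * R[cc, cc]
      cond_mean <- -sum(R[cc, -cc] * m[-cc]) / R[cc, cc]
      expect_equal(cond_prec, nc * tau)
      expect_equal(cond_mean, sum(A[cc, ] * m) / nc)
    }
  }
})

test_that("RW1 structure is the second-difference penalty with rank T-1", {
  sm <- rw1_structure(3)
  expect_equal(sm$entries,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  sm9 <- rw1_structure(9)
  expect_equal(sm9$rank, 8L)
  expect_equal(rowSums(sm9$entries), rep(0, 9), ignore_attr = TRUE)
  # quadratic form equals the sum of squared increments
  set.seed(42)
  for (TT in c(2, 5, 9)) {
    x <- rnorm(TT)
    smT <- rw1_structure(TT)
    expect_equal(drop(crossprod(x, smT$entries %*% x)),
                 sum(diff(x)^2))
  }
  expect_error(rw1_structure(1), "at least 2")
})

test_that("interaction structures follow the four types with multiplicative rank", {
  A31 <- random_connected_graph(31, seed = 9)
  icar31 <- icar_structure(A31)
  A7 <- random_connected_graph(7, seed = 10)
  icar7 <- icar_structure(A7)
  rw9 <- rw1_structure(9)
  id31 <- identity_structure(31)
  id7 <- identity_structure(7)
  id9 <- identity_structure(9)

  cases <- list(
    list(1, 1, id31, id9, 31 * 9),
    list(1, 2, id31, rw9, 31 * 8),
    list(1, 3, icar31, id9, 30 * 9),
    list(1, 4, icar31, rw9, 30 * 8),
    list(2, 1, id7, id9, 7 * 9),
    list(2, 2, id7, rw9, 7 * 8),
    list(2, 3, icar7, id9, 6 * 9),
    list(2, 4, icar7, rw9, 6 * 8)
  )
  for (cs in cases) {
    sp <- interaction_spec(cs[[1]], cs[[2]])
    sm <- interaction_structure(sp, cs[[3]], cs[[4]])
    expect_equal(sm$rank, cs[[5]])
    expect_equal(sm$dim, cs[[3]]$dim * cs[[4]]$dim)
    # numerical rank agrees
    ev <- eigen(sm$entries, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > 1e-8 * max(1, max(ev))), cs[[5]])
    expect_gt(min(ev), -1e-8)
  }
  # type 1 at level 1 is the identity of dimension n1*T
  sm1 <- interaction_structure(interaction_spec(1, 1), id31, id9)
  expect_equal(sm1$entries, diag(31 * 9), ignore_attr = TRUE)
})

test_that("interaction factor kinds are validated against the type", {
  icar4 <- icar_structure(random_connected_graph(4, seed = 1))
  rw5 <- rw1_structure(5)
  id4 <- identity_structure(4)
  id5 <- identity_structure(5)
  expect_error(interaction_structure(interaction_spec(1, 4), id4, rw5),
               "icar")
  expect_error(interaction_structure(interaction_spec(1, 1), icar4, id5),
               "identity")
  expect_error(interaction_structure(interaction_spec(1, 2), id4, id5),
               "rw1")
})

test_that("structure matrices are symmetric PSD with consistent null spaces", {
  for (seed in 1:3) {
    A <- random_connected_graph(8, seed = seed)
    sm <- icar_structure(A)
    expect_equal(sm$entries, t(sm$entries))
    ev <- eigen(sm$entries, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    N <- structure_nullspace(sm)
    expect_equal(ncol(N), sm$null_space_dim)
    expect_equal(max(abs(sm$entries %*% N)), 0, tolerance = 1e-10)
    # the constant vector lies in the null space
    expect_equal(drop(crossprod(rep(1, 8), sm$entries %*% rep(1, 8))), 0,
                 tolerance = 1e-12)
  }
})

test_that("adjacency files round-trip and asymmetry is rejected by name", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  set.seed(3)
  A <- random_connected_graph(12, seed = 3)
  write_adjacency(A, tmp)
  expect_equal(read_adjacency(tmp), A, ignore_attr = TRUE)

  writeLines(c("3", "1 1 2", "2 2 1 3"), tmp)  # 3 -> 2 missing
  expect_error(read_adjacency(tmp), "2 -> 3|3 -> 2")

  writeLines(c("3", "1 1 2", "2 1 1"), tmp)
  expect_equal(sum(read_adjacency(tmp)) / 2, 1)
})

test_that("hierarchy files round-trip and duplicate nesting is rejected", {
  h <- tiny_hierarchy()
  d <- withr::local_tempdir()
  paths <- file.path(d, c("h.csv", "a.txt", "s.txt"))
  write_hierarchy(h, paths[1], paths[2], paths[3])
  h2 <- read_hierarchy(paths[1], paths[2], paths[3])
  expect_equal(h2$area_adjacency, h$area_adjacency)
  expect_equal(h2$super_adjacency, h$super_adjacency)
  expect_equal(h2$nesting, h$nesting)

  writeLines(c("area,super_region", "A1,S1", "A2,S1", "A1,S2"), paths[1])
  expect_error(read_hierarchy(paths[1], paths[2], paths[3]),
               "two super-regions")
})

test_that("nested hierarchy validates its invariants", {
  A2 <- matrix(0, 2, 2)
  expect_error(nested_hierarchy(c("a", "b"), "s", c(a = "s"),
                                A2, matrix(0, 1, 1)),
               "exactly one super-region")
  Abad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(nested_hierarchy(c("a", "b"), "s", c(a = "s", b = "s"),
                                Abad, matrix(0, 1, 1)), "symmetric")
  expect_error(nested_hierarchy("a", c("s1", "s2"), c(a = "s1"),
                                matrix(0, 1, 1), A2), "n1 >= n2")
})
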