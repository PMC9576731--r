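#' Dense-grid posterior oracle for tiny sub-models
#'
#' Brute-force numerical integration of the unnormalised posterior for
#' sub-models whose latent field, after constraint reduction, is at most
#' three free scalars: the intercept plus any of the iid-Gaussian
#' components (`v`, `phi`, `xi`) with their precisions held fixed. Used as
#' an independent check on the MCMC engine; it shares no code path with it.
#'
#' @param data a [panel_counts()].
#' @param components character vector of iid components to include besides
#'   the intercept (each element of each component is one free scalar).
#' @param precisions named numeric vector of fixed precisions for those
#'   components.
#' @param alpha_prior_variance intercept prior variance.
#' @param n_grid grid points per dimension (reduced automatically in three
#'   dimensions to keep the evaluation dense but bounded).
#' @param half_width half-width of each grid in posterior sds around the
#'   mode.
#' @return data frame with `param`, `mean`, `sd`, `q2.5`, `q50`, `q97.5`.
#' @export
grid_oracle <- function(data, components = character(),
                        precisions = numeric(),
                        alpha_prior_variance = 1e6,
                        n_grid = 161, half_width = 8) {
  hierarchy <- data$hierarchy
  n1 <- hierarchy$n1
  TT <- ncol(data$Y)
  y <- vec_sm(data$Y)
  E <- vec_sm(data$E)
  ncells <- n1 * TT

  ok <- c("v", "phi", "xi")
  bad <- setdiff(components, ok)
  if (length(bad))
    stop("grid_oracle supports iid components only (v, phi, xi), not: ",
         paste(bad, collapse = ", "))
  if (!all(components %in% names(precisions)))
    stop("fixed precisions needed for: ",
         paste(setdiff(components, names(precisions)), collapse = ", "))

  # design: one column per free scalar, 0/1 incidence onto cells
  cols <- list(alpha = rep(1, ncells))
  prior_sd <- c(alpha = sqrt(alpha_prior_variance))
  ind <- list(v = rep(seq_len(n1), each = TT),
              phi = rep(seq_len(TT), times = n1),
              xi = rep(hierarchy$super_index, each = TT))
  sizes <- c(v = n1, phi = TT, xi = hierarchy$n2)
  for (nm in components) {
    for (k in seq_len(sizes[[nm]])) {
      cols[[paste0(nm, "[", k, "]")]] <- as.numeric(ind[[nm]] == k)
      prior_sd[[paste0(nm, "[", k, "]")]] <- 1 / sqrt(precisions[[nm]])
    }
  }
  p <- length(cols)
  if (p > 3)
    stop("latent dimension ", p, " exceeds the oracle limit of 3")
  C <- do.call(cbind, cols)

  logpost <- function(theta) {
    eta <- drop(C %*% theta)
    sum(y * eta - E * exp(eta) - lgamma(y + 1)) +
      sum(dnorm(theta, 0, prior_sd, log = TRUE))
  }
  opt <- optim(numeric(p), function(th) -logpost(th), method = "BFGS",
               hessian = TRUE)
  mode <- opt$par
  sds <- sqrt(diag(solve(opt$hessian)))

  ng <- if (p == 3) min(n_grid, 81L) else n_grid
  grids <- lapply(seq_len(p), function(d)
    seq(mode[[d]] - half_width * sds[[d]],
        mode[[d]] + half_width * sds[[d]], length.out = ng))
  G <- as.matrix(expand.grid(grids))
  lp <- numeric(nrow(G))
  for (cc in seq_len(ncells)) {
    eta <- drop(G %*% C[cc, ])
    lp <- lp + y[[cc]] * eta - E[[cc]] * exp(eta) - lgamma(y[[cc]] + 1)
  }
  for (d in seq_len(p))
    lp <- lp + dnorm(G[, d], 0, prior_sd[[d]], log = TRUE)
  w <- exp(lp - max(lp))
  arr <- array(w, dim = rep(ng, p))

  out <- lapply(seq_len(p), function(d) {
    marg <- if (p == 1) arr else apply(arr, d, sum)
    marg <- marg / sum(marg)
    g <- grids[[d]]
    mval <- sum(g * marg)
    sval <- sqrt(sum((g - mval)^2 * marg))
    cdf <- cumsum(marg)
    qs <- vapply(c(0.025, 0.5, 0.975), function(q) {
      i <- which(cdf >= q)[[1L]]
      g[[i]]
    }, numeric(1))
    data.frame(param = names(cols)[[d]], mean = mval, sd = sval,
               q2.5 = qs[[1]], q50 = qs[[2]], q97.5 = qs[[3]])
  })
  do.call(rbind, out)
}
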