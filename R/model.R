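#' Model configuration
#'
#' Describes which variant of the nested spatio-temporal model to fit:
#' the two-level model (`"model1"`, with super-region effects) or the
#' area-level-only model (`"model2"`), the space-time interaction type at
#' each level, the Gamma hyperprior shared by all precision parameters, and
#' the diffuse Normal prior variance of the intercept.
#'
#' @param variant `"model1"` (two-level) or `"model2"` (level 1 only).
#' @param type1 interaction type (1..4) at the area level.
#' @param type2 interaction type (1..4) at the super-region level
#'   (ignored for `"model2"`).
#' @param components optional character subset of
#'   `c("mu","v","gamma","phi","delta","omega","xi","zeta")` to restrict the
#'   latent field (used for sub-models and oracle checks); defaults to all
#'   components allowed by the variant.
#' @param hyperprior length-2 numeric `c(shape, rate)` of the Gamma prior on
#'   every precision; default `c(0.5, 0.0005)`.
#' @param alpha_prior_variance variance of the Normal prior on the
#'   intercept; default `1e6`.
#' @param fixed_precisions optional named numeric vector of precisions to
#'   hold fixed (not sampled), e.g. `c(v = 4)`.
#' @return object of class `model_config`.
#' @export
model_config <- function(variant = c("model1", "model2"),
                         type1 = 4, type2 = 4,
                         components = NULL,
                         hyperprior = c(shape = 0.5, rate = 0.0005),
                         alpha_prior_variance = 1e6,
                         fixed_precisions = NULL) {
  variant <- match.arg(variant)
  if (any(hyperprior <= 0)) stop("hyperprior shape and rate must be positive")
  if (alpha_prior_variance <= 0) stop("alpha_prior_variance must be positive")
  allowed <- c("mu", "v", "gamma", "phi", "delta")
  if (variant == "model1") allowed <- c(allowed, "omega", "xi", "zeta")
  if (is.null(components)) {
    components <- allowed
  } else {
    bad <- setdiff(components, allowed)
    if (length(bad))
      stop("components not allowed for ", variant, ": ",
           paste(bad, collapse = ", "))
  }
  structure(list(
    variant = variant,
    interaction_spec_level1 = interaction_spec(1, type1),
    interaction_spec_level2 = if (variant == "model1")
      interaction_spec(2, type2) else NULL,
    components = components,
    hyperprior = c(shape = unname(hyperprior[[1]]),
                   rate = unname(hyperprior[[2]])),
    alpha_prior_variance = alpha_prior_variance,
    fixed_precisions = fixed_precisions
  ), class = "model_config")
}

#' One realisation of the latent field
#'
#' Holds the intercept `alpha`, the effect vectors of the linear predictor
#' (`mu`, `v` over areas; `gamma`, `phi` over times; `delta` over area x
#' time; `omega`, `xi` over super-regions; `zeta` over super-region x time)
#' and the precision parameters. Components may be `NULL` (treated as zero
#' in the predictor) to represent sub-models.
#'
#' @param alpha scalar log baseline relative risk.
#' @param mu,v numeric vectors, length `n1` (structured / unstructured
#'   area effects).
#' @param gamma,phi numeric vectors, length `T` (structured / unstructured
#'   time effects).
#' @param delta `n1 x T` matrix (area-level interaction).
#' @param omega,xi numeric vectors, length `n2`.
#' @param zeta `n2 x T` matrix (super-region-level interaction).
#' @param precisions named numeric vector of positive precisions (names
#'   among `mu, v, gamma, phi, delta, omega, xi, zeta`).
#' @return object of class `effect_state`.
#' @export
effect_state <- function(alpha = 0, mu = NULL, v = NULL, gamma = NULL,
                         phi = NULL, delta = NULL, omega = NULL, xi = NULL,
                         zeta = NULL, precisions = numeric()) {
  if (length(precisions) && any(precisions <= 0))
    stop("all precisions must be strictly positive")
  structure(list(alpha = alpha, mu = mu, v = v, gamma = gamma, phi = phi,
                 delta = delta, omega = omega, xi = xi, zeta = zeta,
                 precisions = precisions),
            class = "effect_state")
}

#' Build all structure matrices and constraint bases for a model
#'
#' Constructs the ICAR structures at both levels, the RW1 temporal
#' structure, identities for the unstructured components, and the Kronecker
#' interaction structures for the configured types, together with the
#' orthonormal sum-to-zero constraint basis of each rank-deficient
#' component (the basis spans the structure matrix's null space; interaction
#' bases are built exactly from the factor null spaces).
#'
#' @param hierarchy a [nested_hierarchy()].
#' @param n_times number of time points.
#' @param config a [model_config()].
#' @return list with one element per active component, each a list
#'   `list(R = structure_matrix, N = constraint basis matrix)`.
#' @export
model_structures <- function(hierarchy, n_times, config) {
  n1 <- hierarchy$n1
  n2 <- hierarchy$n2
  # built lazily so sub-models never construct structures they do not use
  icar1_cache <- NULL
  icar1 <- function() {
    if (is.null(icar1_cache))
      icar1_cache <<- icar_structure(hierarchy$area_adjacency)
    icar1_cache
  }
  rw1_cache <- NULL
  rw1 <- function() {
    if (is.null(rw1_cache)) rw1_cache <<- rw1_structure(n_times)
    rw1_cache
  }
  id_n1 <- identity_structure(n1)
  id_T <- identity_structure(n_times)

  comp_basis <- function(components) {
    # per-component indicator vectors, normalised; exact ICAR null space
    sapply(seq_len(max(components)), function(g) {
      u <- as.numeric(components == g)
      u / sqrt(sum(u))
    })
  }

  out <- list()
  add <- function(name, R, N) out[[name]] <<- list(R = R, N = N)

  if ("mu" %in% config$components)
    add("mu", icar1(), comp_basis(icar1()$components))
  if ("v" %in% config$components)
    add("v", id_n1, matrix(0, n1, 0))
  if ("gamma" %in% config$components)
    add("gamma", rw1(), matrix(rep(1 / sqrt(n_times), n_times), ncol = 1))
  if ("phi" %in% config$components)
    add("phi", id_T, matrix(0, n_times, 0))
  if ("delta" %in% config$components) {
    sp1 <- config$interaction_spec_level1
    Rs <- if (sp1$spatial_component == "structured") icar1() else id_n1
    Rt <- if (sp1$temporal_component == "structured") rw1() else id_T
    Rint <- interaction_structure(sp1, Rs, Rt)
    comps <- if (sp1$spatial_component == "structured")
      icar1()$components else rep(1L, n1)
    add("delta", Rint, kron_nullspace(sp1, comps, n1, n_times))
  }
  if (config$variant == "model1") {
    icar2_cache <- NULL
    icar2 <- function() {
      if (is.null(icar2_cache))
        icar2_cache <<- icar_structure(hierarchy$super_adjacency)
      icar2_cache
    }
    id_n2 <- identity_structure(n2)
    if ("omega" %in% config$components)
      add("omega", icar2(), comp_basis(icar2()$components))
    if ("xi" %in% config$components)
      add("xi", id_n2, matrix(0, n2, 0))
    if ("zeta" %in% config$components) {
      sp2 <- config$interaction_spec_level2
      Rs <- if (sp2$spatial_component == "structured") icar2() else id_n2
      Rt <- if (sp2$temporal_component == "structured") rw1() else id_T
      Rint <- interaction_structure(sp2, Rs, Rt)
      comps <- if (sp2$spatial_component == "structured")
        icar2()$components else rep(1L, n2)
      add("zeta", Rint, kron_nullspace(sp2, comps, n2, n_times))
    }
  }
  out
}

# Orthonormal basis of null(R_space %x% R_time) for an interaction type,
# built exactly from the factor null spaces (space-major layout):
# spatial structured contributes {comp indicator (x) unit time vector},
# temporal structured contributes {unit space vector (x) constant}.
kron_nullspace <- function(spec, components, n_space, n_time) {
  cols <- list()
  if (spec$spatial_component == "structured") {
    for (g in seq_len(max(components))) {
      u <- as.numeric(components == g) / sqrt(sum(components == g))
      for (t in seq_len(n_time)) {
        e <- numeric(n_time); e[t] <- 1
        cols[[length(cols) + 1L]] <- u %x% e
      }
    }
  }
  if (spec$temporal_component == "structured") {
    one <- rep(1 / sqrt(n_time), n_time)
    for (i in seq_len(n_space)) {
      e <- numeric(n_space); e[i] <- 1
      cols[[length(cols) + 1L]] <- e %x% one
    }
  }
  if (!length(cols)) return(matrix(0, n_space * n_time, 0))
  B <- do.call(cbind, cols)
  q <- qr(B)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

# space-major vectorisation: all time points of unit 1, then unit 2, ...
vec_sm <- function(M) as.vector(t(M))

#' Linear predictor of the nested model
#'
#' Evaluates `log rho_it = alpha + mu_i + v_i + gamma_t + phi_t + delta_it`
#' plus, for the two-level variant, `omega_j(i) + xi_j(i) + zeta_j(i),t`
#' looked up through the nesting map. `NULL` components contribute zero.
#'
#' @param state an [effect_state()].
#' @param hierarchy a [nested_hierarchy()].
#' @param variant `"model1"` or `"model2"`.
#' @param n_times number of time points (inferred from the state when
#'   possible).
#' @return `n1 x T` matrix of log relative risks.
#' @export
linear_predictor <- function(state, hierarchy, variant = "model1",
                             n_times = NULL) {
  n1 <- hierarchy$n1
  if (is.null(n_times)) {
    n_times <- if (!is.null(state$gamma)) length(state$gamma)
      else if (!is.null(state$phi)) length(state$phi)
      else if (!is.null(state$delta)) ncol(state$delta)
      else stop("cannot infer the number of time points from the state")
  }
  chk <- function(x, len, name) {
    if (!is.null(x) && length(x) != len)
      stop("dimension mismatch for ", name, ": ", length(x), " vs ", len)
    x
  }
  eta <- matrix(state$alpha, n1, n_times)
  sp <- numeric(n1)
  if (!is.null(state$mu)) sp <- sp + chk(state$mu, n1, "mu")
  if (!is.null(state$v)) sp <- sp + chk(state$v, n1, "v")
  tm <- numeric(n_times)
  if (!is.null(state$gamma)) tm <- tm + chk(state$gamma, n_times, "gamma")
  if (!is.null(state$phi)) tm <- tm + chk(state$phi, n_times, "phi")
  eta <- eta + sp + rep(tm, each = n1)
  if (!is.null(state$delta)) {
    if (!all(dim(state$delta) == c(n1, n_times)))
      stop("dimension mismatch for delta")
    eta <- eta + state$delta
  }
  if (variant == "model1") {
    j <- hierarchy$super_index
    sp2 <- numeric(hierarchy$n2)
    if (!is.null(state$omega)) sp2 <- sp2 + chk(state$omega, hierarchy$n2, "omega")
    if (!is.null(state$xi)) sp2 <- sp2 + chk(state$xi, hierarchy$n2, "xi")
    eta <- eta + sp2[j]
    if (!is.null(state$zeta)) {
      if (!all(dim(state$zeta) == c(hierarchy$n2, n_times)))
        stop("dimension mismatch for zeta")
      eta <- eta + state$zeta[j, , drop = FALSE]
    }
  }
  dimnames(eta) <- list(hierarchy$area_ids, NULL)
  eta
}

#' Poisson log likelihood of a panel under a latent state
#'
#' `Y_it ~ Poisson(E_it * exp(log rho_it))`, evaluated in log space.
#'
#' @param state an [effect_state()].
#' @param data a [panel_counts()].
#' @param variant model variant (see [linear_predictor()]).
#' @return list with `total` (scalar) and `pointwise` (`n1 x T` matrix of
#'   per-cell log likelihoods, retained for WAIC).
#' @export
log_likelihood <- function(state, data, variant = "model1") {
  eta <- linear_predictor(state, data$hierarchy, variant,
                          n_times = ncol(data$Y))
  lambda <- data$E * exp(eta)
  pw <- dpois(data$Y, lambda, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Joint log prior of the latent field and hyperparameters
#'
#' Sums the diffuse Normal prior on the intercept, iid Normal priors on the
#' unstructured effects, improper GMRF priors
#' `(rank/2) log tau - (tau/2) x' R x` on the structured and interaction
#' effects, and the Gamma hyperprior on each active precision. Constant
#' terms that cancel within a fixed model are dropped for the GMRF parts.
#'
#' @param state an [effect_state()] whose precisions cover the active
#'   components.
#' @param structures output of [model_structures()].
#' @param config a [model_config()].
#' @return scalar log prior; `-Inf` (with a `reason` attribute) if any
#'   precision is nonpositive.
#' @export
log_prior <- function(state, structures, config) {
  tau <- state$precisions
  active <- names(structures)
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    out <- -Inf
    attr(out, "reason") <- "nonpositive precision"
    return(out)
  }
  missing_tau <- setdiff(active, names(tau))
  if (length(missing_tau))
    stop("state has no precision for: ", paste(missing_tau, collapse = ", "))

  lp <- dnorm(state$alpha, 0, sqrt(config$alpha_prior_variance), log = TRUE)
  for (nm in active) {
    x <- state[[nm]]
    if (is.null(x)) stop("state is missing component ", nm)
    if (is.matrix(x)) x <- vec_sm(x)
    R <- structures[[nm]]$R
    tt <- tau[[nm]]
    if (R$kind == "identity") {
      lp <- lp + sum(dnorm(x, 0, 1 / sqrt(tt), log = TRUE))
    } else {
      qf <- drop(crossprod(x, R$entries %*% x))
      lp <- lp + (R$rank / 2) * log(tt) - (tt / 2) * qf
    }
    lp <- lp + dgamma(tt, shape = config$hyperprior[["shape"]],
                      rate = config$hyperprior[["rate"]], log = TRUE)
  }
  lp
}

#' Centre a latent state onto its identifiability constraints
#'
#' Projects the structured components onto their sum-to-zero constraints and
#' reallocates the removed pieces so the linear predictor is unchanged:
#' overall means move into `alpha`, area-specific constants from `mu` or the
#' interaction into `v`, super-region constants into `xi`, and time
#' profiles removed from interactions into `phi`. The interaction centring
#' follows the null space of its type (row centring when the temporal
#' factor is structured, column centring when the spatial factor is
#' structured, double centring for both). Idempotent.
#'
#' @param state an [effect_state()] with all components of `config` present.
#' @param structures output of [model_structures()].
#' @param hierarchy a [nested_hierarchy()].
#' @param config a [model_config()].
#' @return the constrained [effect_state()].
#' @export
apply_constraints <- function(state, structures, hierarchy, config) {
  s <- state
  ensure <- function(x, len) if (is.null(x)) numeric(len) else x

  centre_icar <- function(x, components) {
    removed <- numeric(length(x))
    for (g in seq_len(max(components))) {
      idx <- components == g
      m <- mean(x[idx])
      x[idx] <- x[idx] - m
      removed[idx] <- m
    }
    list(x = x, removed = removed)
  }

  if (!is.null(s$gamma) && "gamma" %in% names(structures)) {
    m <- mean(s$gamma)
    s$gamma <- s$gamma - m
    s$alpha <- s$alpha + m
  }
  if (!is.null(s$mu) && "mu" %in% names(structures)) {
    cc <- centre_icar(s$mu, structures$mu$R$components)
    s$mu <- cc$x
    m0 <- mean(cc$removed)
    s$alpha <- s$alpha + m0
    if (any(cc$removed != m0)) {
      s$v <- ensure(s$v, hierarchy$n1) + (cc$removed - m0)
    }
  }
  if (!is.null(s$omega) && "omega" %in% names(structures)) {
    cc <- centre_icar(s$omega, structures$omega$R$components)
    s$omega <- cc$x
    m0 <- mean(cc$removed)
    s$alpha <- s$alpha + m0
    if (any(cc$removed != m0)) {
      s$xi <- ensure(s$xi, hierarchy$n2) + (cc$removed - m0)
    }
  }

  centre_interaction <- function(M, spec) {
    # returns list(M, row (into v/xi), col (into phi), grand (into alpha))
    row_c <- spec$temporal_component == "structured"
    col_c <- spec$spatial_component == "structured"
    out <- list(M = M, row = numeric(nrow(M)), col = numeric(ncol(M)),
                grand = 0)
    if (row_c && col_c) {
      g <- mean(M)
      a <- rowMeans(M) - g
      b <- colMeans(M) - g
      out$M <- M - outer(a, rep(1, ncol(M))) -
        outer(rep(1, nrow(M)), b) - g
      out$row <- a; out$col <- b; out$grand <- g
    } else if (row_c) {
      a <- rowMeans(M)
      out$M <- M - a
      out$row <- a
    } else if (col_c) {
      b <- colMeans(M)
      out$M <- M - rep(b, each = nrow(M))
      out$col <- b
    }
    out
  }

  if (!is.null(s$delta) && "delta" %in% names(structures)) {
    cc <- centre_interaction(s$delta, config$interaction_spec_level1)
    s$delta <- cc$M
    s$alpha <- s$alpha + cc$grand
    if (any(cc$row != 0)) s$v <- ensure(s$v, hierarchy$n1) + cc$row
    if (any(cc$col != 0)) s$phi <- ensure(s$phi, ncol(s$delta)) + cc$col
  }
  if (!is.null(s$zeta) && "zeta" %in% names(structures)) {
    cc <- centre_interaction(s$zeta, config$interaction_spec_level2)
    s$zeta <- cc$M
    s$alpha <- s$alpha + cc$grand
    if (any(cc$row != 0)) s$xi <- ensure(s$xi, hierarchy$n2) + cc$row
    if (any(cc$col != 0)) s$phi <- ensure(s$phi, ncol(s$zeta)) + cc$col
  }
  s
}
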