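#' Precision-structure matrices for Gaussian Markov random field priors
#'
#' A `structure_matrix` is the symmetric positive-semidefinite matrix `R`
#' in an (possibly improper) GMRF prior with density proportional to
#' `tau^(rank/2) * exp(-tau/2 * x' R x)`. The intrinsic CAR and first-order
#' random-walk structures are rank deficient (their null spaces hold the
#' directions the prior leaves flat); identity structures give iid effects.
#'
#' @param entries symmetric numeric matrix.
#' @param kind one of `"icar"`, `"rw1"`, `"identity"`, `"kronecker"`.
#' @param rank integer rank of `entries`.
#' @return an object of class `structure_matrix` with fields `dim`,
#'   `entries`, `rank`, `null_space_dim`, `kind`.
#' @keywords internal
structure_matrix <- function(entries, kind, rank) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  stopifnot(ncol(entries) == n, rank >= 0, rank <= n)
  structure(list(
    dim = n,
    entries = entries,
    rank = as.integer(rank),
    null_space_dim = as.integer(n - rank),
    kind = match.arg(kind, c("icar", "rw1", "identity", "kronecker"))
  ), class = "structure_matrix")
}

#' Intrinsic CAR (ICAR) structure matrix
#'
#' Builds `R = D - A` from a symmetric 0/1 adjacency: diagonal entries are
#' the neighbour counts `n_c`, off-diagonal entries are `-a_cd`. The implied
#' full conditional of node `c` given the rest is Normal with mean the
#' neighbour average and precision `n_c * tau`. Rank is `n` minus the number
#' of connected components; isolated nodes ("islands") each count as their
#' own component, are flagged in the `islands` field, and have their
#' structured effect fixed to 0 by the centring constraints (their risk is
#' carried by the unstructured effect).
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @return a `structure_matrix` of kind `"icar"`, with extra fields
#'   `components` (per-node component labels) and `islands` (indices of
#'   degree-0 nodes).
#' @export
icar_structure <- function(adjacency) {
  A <- check_adjacency(adjacency, seq_len(nrow(as.matrix(adjacency))), "input")
  deg <- rowSums(A)
  comp <- graph_components(A)
  islands <- which(deg == 0)
  R <- diag(deg, nrow(A)) - A
  out <- structure_matrix(R, "icar", rank = nrow(A) - max(comp))
  out$components <- comp
  out$islands <- islands
  if (length(islands))
    warning(length(islands), " island node(s) with no neighbours: ",
            paste(islands, collapse = ", "),
            "; their structured effect is pinned at 0", call. = FALSE)
  out
}

#' First-order random-walk (RW1) structure matrix
#'
#' Second-difference penalty on an ordered index: the quadratic form
#' `x' R x` equals the sum of squared first differences, so `R` is
#' tridiagonal with rank `T - 1` and the constant vector in its null space.
#'
#' @param n_times number of time points, at least 2.
#' @return a `structure_matrix` of kind `"rw1"`.
#' @export
rw1_structure <- function(n_times) {
  n_times <- as.integer(n_times)
  if (is.na(n_times) || n_times < 2L) stop("RW1 needs at least 2 time points")
  D <- diff(diag(n_times))        # (T-1) x T first-difference operator
  structure_matrix(crossprod(D), "rw1", rank = n_times - 1L)
}

#' Identity structure matrix (iid effects)
#'
#' @param n dimension.
#' @return a full-rank `structure_matrix` of kind `"identity"`.
#' @export
identity_structure <- function(n) {
  structure_matrix(diag(n), "identity", rank = n)
}

#' Space-time interaction type specification
#'
#' The four interaction types pair an unstructured or structured spatial
#' factor with an unstructured or structured temporal factor:
#' type 1 = iid x iid, type 2 = iid x RW1, type 3 = ICAR x iid,
#' type 4 = ICAR x RW1. Unstructured factors contribute identity structure
#' matrices.
#'
#' @param level 1 (area level) or 2 (super-region level).
#' @param type_id integer 1..4.
#' @return an object of class `interaction_spec` with fields `level`,
#'   `type_id`, `spatial_component`, `temporal_component`.
#' @export
interaction_spec <- function(level, type_id) {
  level <- as.integer(level)
  type_id <- as.integer(type_id)
  if (!level %in% 1:2) stop("level must be 1 or 2")
  if (!type_id %in% 1:4) stop("type_id must be in 1..4")
  comp <- switch(type_id,
    list(spatial = "unstructured", temporal = "unstructured"),
    list(spatial = "unstructured", temporal = "structured"),
    list(spatial = "structured",  temporal = "unstructured"),
    list(spatial = "structured",  temporal = "structured"))
  structure(list(level = level, type_id = type_id,
                 spatial_component = comp$spatial,
                 temporal_component = comp$temporal),
            class = "interaction_spec")
}

#' Kronecker interaction structure matrix
#'
#' Builds the structure matrix of a space-time interaction effect as the
#' Kronecker product of its spatial and temporal factors, laid out
#' space-major (all time points of unit 1, then unit 2, ...), i.e.
#' `R_space %x% R_time`. Rank multiplies: `rank_s * rank_t`. The factor
#' kinds must match the type: an unstructured factor must be an identity,
#' a structured spatial factor an ICAR, a structured temporal factor an RW1.
#'
#' @param spec an [interaction_spec()].
#' @param spatial `structure_matrix` for the spatial factor.
#' @param temporal `structure_matrix` for the temporal factor.
#' @return a `structure_matrix` of kind `"kronecker"` with extra fields
#'   `spec`, `n_space`, `n_time`, and the spatial factor's `components`.
#' @export
interaction_structure <- function(spec, spatial, temporal) {
  stopifnot(inherits(spec, "interaction_spec"),
            inherits(spatial, "structure_matrix"),
            inherits(temporal, "structure_matrix"))
  want_s <- if (spec$spatial_component == "structured") "icar" else "identity"
  want_t <- if (spec$temporal_component == "structured") "rw1" else "identity"
  if (spatial$kind != want_s)
    stop("type ", spec$type_id, " needs a ", want_s,
         " spatial factor, got ", spatial$kind)
  if (temporal$kind != want_t)
    stop("type ", spec$type_id, " needs a ", want_t,
         " temporal factor, got ", temporal$kind)
  out <- structure_matrix(spatial$entries %x% temporal$entries, "kronecker",
                          rank = spatial$rank * temporal$rank)
  out$spec <- spec
  out$n_space <- spatial$dim
  out$n_time <- temporal$dim
  out$components <- spatial$components %||% rep(1L, spatial$dim)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orthonormal null-space basis of a structure matrix
#'
#' Eigenvectors whose eigenvalues are numerically zero; these span the
#' directions an improper GMRF prior leaves flat and define the sum-to-zero
#' constraints used for identifiability.
#'
#' @param sm a `structure_matrix`.
#' @param tol eigenvalue threshold for "zero".
#' @return matrix with `null_space_dim` orthonormal columns (possibly 0).
#' @export
structure_nullspace <- function(sm, tol = 1e-8) {
  if (sm$null_space_dim == 0L)
    return(matrix(0, sm$dim, 0L))
  e <- eigen(sm$entries, symmetric = TRUE)
  idx <- which(e$values < tol * max(1, max(e$values)))
  if (length(idx) != sm$null_space_dim)
    stop("numerical null space dimension ", length(idx),
         " disagrees with declared ", sm$null_space_dim)
  e$vectors[, idx, drop = FALSE]
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat("structure_matrix [", x$kind, "] dim ", x$dim,
      ", rank ", x$rank, " (null space ", x$null_space_dim, ")\n", sep = "")
  invisible(x)
}
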