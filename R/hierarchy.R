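#' Nested two-level areal hierarchy
#'
#' Bundles the bookkeeping for a fine spatial level (areas, e.g. provinces)
#' nested inside a coarse level (super-regions, e.g. natural geographic
#' regions): the ordered unit labels, the area-to-super-region nesting map,
#' and a symmetric 0/1 adjacency relation at each level.
#'
#' @param area_ids character vector of area labels (length `n1`), in the
#'   order that fixes all vector/matrix layouts downstream.
#' @param super_ids character vector of super-region labels (length `n2`).
#' @param nesting named character vector mapping each area label to the
#'   super-region label that contains it.
#' @param area_adjacency symmetric 0/1 matrix (`n1 x n1`, zero diagonal).
#' @param super_adjacency symmetric 0/1 matrix (`n2 x n2`, zero diagonal).
#'
#' @return An object of class `nested_hierarchy`: a list with fields
#'   `area_ids`, `super_ids`, `nesting`, `area_adjacency`, `super_adjacency`,
#'   plus `n1`, `n2` and `super_index` (integer index of each area's
#'   super-region).
#' @export
nested_hierarchy <- function(area_ids, super_ids, nesting,
                             area_adjacency, super_adjacency) {
  area_ids <- as.character(area_ids)
  super_ids <- as.character(super_ids)
  if (anyDuplicated(area_ids)) stop("duplicated area labels")
  if (anyDuplicated(super_ids)) stop("duplicated super-region labels")
  n1 <- length(area_ids)
  n2 <- length(super_ids)
  if (n1 < n2 || n2 < 1L) stop("need n1 >= n2 >= 1")

  nesting <- nesting[area_ids]
  if (any(is.na(nesting)) || length(nesting) != n1)
    stop("every area must map to exactly one super-region")
  if (!all(nesting %in% super_ids))
    stop("nesting refers to unknown super-region(s): ",
         paste(setdiff(nesting, super_ids), collapse = ", "))

  area_adjacency <- check_adjacency(area_adjacency, area_ids, "area")
  super_adjacency <- check_adjacency(super_adjacency, super_ids, "super-region")

  structure(list(
    area_ids = area_ids,
    super_ids = super_ids,
    nesting = nesting,
    area_adjacency = area_adjacency,
    super_adjacency = super_adjacency,
    n1 = n1,
    n2 = n2,
    super_index = match(unname(nesting), super_ids)
  ), class = "nested_hierarchy")
}

check_adjacency <- function(A, ids, what) {
  A <- as.matrix(A)
  n <- length(ids)
  if (nrow(A) != n || ncol(A) != n)
    stop(what, " adjacency must be ", n, "x", n)
  if (!all(A %in% c(0, 1))) stop(what, " adjacency must be 0/1")
  if (any(diag(A) != 0)) stop(what, " adjacency must have zero diagonal")
  if (!isTRUE(all.equal(A, t(A))))
    stop(what, " adjacency must be symmetric")
  dimnames(A) <- list(ids, ids)
  A
}

#' Connected components of an adjacency relation
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @return integer vector of component labels (1-based); isolated nodes are
#'   singleton components.
#' @export
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Read an adjacency graph file
#'
#' Plain-text adjacency-list dialect: first line is the number of nodes `n`;
#' each following line is `node degree neighbour...` with 1-based node ids.
#' The listed relation must already be symmetric: an edge `a -> b` without
#' the matching `b -> a` is rejected naming both nodes.
#'
#' @param path path to the graph file.
#' @return symmetric 0/1 adjacency matrix.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[[1L]]))
  if (is.na(n) || n < 1L) stop("bad node count on line 1: ", lines[[1L]])
  A <- matrix(0, n, n)
  for (ln in lines[-1L]) {
    tok <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    if (any(is.na(tok)) || length(tok) < 2L)
      stop("malformed graph line: ", ln)
    node <- tok[[1L]]; deg <- tok[[2L]]; nb <- tok[-(1:2)]
    if (node < 1L || node > n) stop("unknown node id on line: ", ln)
    if (length(nb) != deg) stop("degree mismatch on line: ", ln)
    if (any(nb < 1L | nb > n)) stop("unknown neighbour id on line: ", ln)
    if (node %in% nb) stop("self-edge on line: ", ln)
    A[node, nb] <- 1
  }
  bad <- which(A != t(A), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop("asymmetric adjacency: edge ", max(b), " -> ", min(b),
         " listed without ", min(b), " -> ", max(b))
  }
  A
}

#' Write an adjacency graph file
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  n <- nrow(A)
  lines <- character(n + 1L)
  lines[[1L]] <- as.character(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    lines[[i + 1L]] <- paste(c(i, length(nb), nb), collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a nested hierarchy from disk
#'
#' The nesting map is a two-column CSV with header `area,super_region`
#' (areas in the order that fixes the layout); the two graphs use the
#' adjacency-list format of [read_adjacency()], with node ids matching the
#' row order of the CSV (areas) and the order of first appearance of the
#' super-region labels.
#'
#' @param nesting_path path to the `area,super_region` CSV.
#' @param area_graph_path path to the area-level graph file.
#' @param super_graph_path path to the super-region-level graph file.
#' @return a [nested_hierarchy()] object.
#' @export
read_hierarchy <- function(nesting_path, area_graph_path, super_graph_path) {
  df <- read.csv(nesting_path, stringsAsFactors = FALSE)
  if (!all(c("area", "super_region") %in% names(df)))
    stop("hierarchy CSV must have header area,super_region")
  dup <- df$area[duplicated(df$area)]
  if (length(dup)) {
    ln <- which(df$area == dup[[1L]])[2L] + 1L  # +1 for the header line
    stop("area '", dup[[1L]], "' mapped to two super-regions (line ", ln, ")")
  }
  area_ids <- as.character(df$area)
  super_ids <- unique(as.character(df$super_region))
  nesting <- setNames(as.character(df$super_region), area_ids)
  nested_hierarchy(area_ids, super_ids, nesting,
                   read_adjacency(area_graph_path),
                   read_adjacency(super_graph_path))
}

#' Write a nested hierarchy to disk
#'
#' Counterpart of [read_hierarchy()]; writes the nesting CSV and the two
#' graph files.
#'
#' @param hierarchy a [nested_hierarchy()] object.
#' @param nesting_path,area_graph_path,super_graph_path output paths.
#' @return `nesting_path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, nesting_path, area_graph_path,
                            super_graph_path) {
  write.csv(data.frame(area = hierarchy$area_ids,
                       super_region = unname(hierarchy$nesting)),
            nesting_path, row.names = FALSE, quote = FALSE)
  write_adjacency(hierarchy$area_adjacency, area_graph_path)
  write_adjacency(hierarchy$super_adjacency, super_graph_path)
  invisible(nesting_path)
}

#' @export
print.nested_hierarchy <- function(x, ...) {
  cat("Nested areal hierarchy:", x$n1, "areas in", x$n2, "super-regions\n")
  cat("  area edges:", sum(x$area_adjacency) / 2,
      " super-region edges:", sum(x$super_adjacency) / 2, "\n")
  invisible(x)
}
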