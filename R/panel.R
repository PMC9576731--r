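#' Areal count panel
#'
#' Rectangular panel of observed counts `Y` and expected counts `E` over
#' areas x times, tied to a [nested_hierarchy()]. `E` can be supplied
#' directly or internally standardised from a population column via
#' [expected_counts()].
#'
#' @param data data frame with columns `area`, `year`, `births`, and either
#'   `expected` or `population` (if both are present, `expected` wins).
#' @param hierarchy a [nested_hierarchy()]; its area order fixes the row
#'   order of the panel matrices.
#' @return object of class `panel_counts`: list with `Y` and `E`
#'   (`n1 x T` matrices, rows = areas, columns = times), `hierarchy`,
#'   and `times` (ordered time labels).
#' @export
panel_counts <- function(data, hierarchy) {
  stopifnot(inherits(hierarchy, "nested_hierarchy"))
  need <- c("area", "year", "births")
  if (!all(need %in% names(data)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (!all(as.character(data$area) %in% hierarchy$area_ids))
    stop("panel contains areas not in the hierarchy: ",
         paste(setdiff(unique(data$area), hierarchy$area_ids), collapse = ", "))
  times <- sort(unique(data$year))
  n1 <- hierarchy$n1
  TT <- length(times)
  key <- paste(data$area, data$year)
  if (anyDuplicated(key)) stop("duplicated (area, year) cells")
  if (nrow(data) != n1 * TT)
    stop("panel is not a complete rectangle: have ", nrow(data),
         " cells, expected ", n1 * TT)

  shape <- function(v) {
    m <- matrix(NA_real_, n1, TT, dimnames = list(hierarchy$area_ids, times))
    m[cbind(match(as.character(data$area), hierarchy$area_ids),
            match(data$year, times))] <- v
    m
  }
  Y <- shape(data$births)
  if (any(is.na(Y))) stop("missing cells in the panel")
  if (any(Y < 0) || any(Y != round(Y)))
    stop("births must be nonnegative integers")

  if ("expected" %in% names(data)) {
    E <- shape(data$expected)
    if (any(is.na(E)) || any(E <= 0)) stop("expected counts must be positive")
  } else if ("population" %in% names(data)) {
    E <- expected_counts(Y, shape(data$population))
  } else {
    stop("panel needs an 'expected' or 'population' column")
  }

  structure(list(Y = Y, E = E, hierarchy = hierarchy, times = times),
            class = "panel_counts")
}

#' Internally standardised expected counts
#'
#' Applies a single overall rate to each cell's population:
#' `E_it = N_it * (sum(Y) / sum(N))`, so the panel total of `E` equals the
#' total of `Y` and the relative risks average to about 1.
#'
#' @param Y matrix (or vector) of observed counts.
#' @param N matrix (or vector) of positive populations, same shape as `Y`.
#' @return expected counts, same shape as `Y`.
#' @export
expected_counts <- function(Y, N) {
  if (length(Y) != length(N)) stop("Y and N must share the same index set")
  if (any(is.na(Y)) || any(is.na(N))) stop("missing cells")
  if (any(N <= 0)) stop("populations must be positive")
  N * (sum(Y) / sum(N))
}

#' Read a count panel from CSV
#'
#' Expects header `area,year,births` plus `population` and/or `expected`.
#'
#' @param path CSV path.
#' @param hierarchy a [nested_hierarchy()].
#' @return a [panel_counts()] object.
#' @export
read_panel <- function(path, hierarchy) {
  panel_counts(read.csv(path, stringsAsFactors = FALSE), hierarchy)
}

#' Write a count panel to CSV
#'
#' @param panel a [panel_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(
    area = rep(rownames(panel$Y), times = ncol(panel$Y)),
    year = rep(panel$times, each = nrow(panel$Y)),
    births = as.vector(panel$Y),
    expected = as.vector(panel$E)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.panel_counts <- function(x, ...) {
  cat("panel_counts:", nrow(x$Y), "areas x", ncol(x$Y), "times;",
      "total births", sum(x$Y), "\n")
  invisible(x)
}
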