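#' Risk-band classification scheme
#'
#' Ordered half-open intervals `(lo, hi]` covering the positive axis. The
#' default bands are `(0, 0.5]` Low, `(0.5, 1.0]` Middle, `(1.0, 1.5]`
#' High, and `(1.5, Inf)` Very-high; a boundary value belongs to the lower
#' band (a relative risk of exactly 1.0 is Middle). Labels are
#' configurable.
#'
#' @param breaks increasing numeric vector of band edges starting at 0 and
#'   ending at `Inf`.
#' @param labels character labels, one per interval.
#' @return object of class `risk_band_scheme`.
#' @export
risk_band_scheme <- function(breaks = c(0, 0.5, 1, 1.5, Inf),
                             labels = c("Low", "Middle", "High",
                                        "Very-high")) {
  if (breaks[[1]] != 0 || !is.infinite(breaks[[length(breaks)]]))
    stop("breaks must start at 0 and end at Inf")
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must increase")
  if (length(labels) != length(breaks) - 1L)
    stop("need one label per interval")
  structure(list(breaks = breaks, labels = labels),
            class = "risk_band_scheme")
}

#' Classify a relative risk into a band
#'
#' @param rr positive relative risk value(s).
#' @param scheme a [risk_band_scheme()].
#' @return character band label(s).
#' @export
classify_risk <- function(rr, scheme = risk_band_scheme()) {
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("relative risks must be positive")
  idx <- findInterval(rr, scheme$breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  scheme$labels[idx]
}

# posterior mean + interval of exp(sum of draw matrices), computed
# draw-wise (mean of exp, never exp of the mean)
rr_summary <- function(draw_sum, labels, unit_col) {
  rr <- exp(draw_sum)
  df <- data.frame(
    unit = labels,
    rr = colMeans(rr),
    lower = apply(rr, 2, quantile, 0.025, names = FALSE),
    upper = apply(rr, 2, quantile, 0.975, names = FALSE)
  )
  names(df)[[1]] <- unit_col
  df
}

#' Relative-risk decomposition of a fitted two-level model
#'
#' Posterior summaries of the spatial relative-risk surfaces: the area
#' level `exp(mu_i + v_i)`, the super-region level `exp(omega_j + xi_j)`,
#' and the combined surface `exp(mu_i + v_i + omega_j(i) + xi_j(i))`. All
#' summaries are computed draw-wise (exponentiate each draw, then average)
#' with 95 percent intervals, and the posterior-mean surface is classified
#' into risk bands.
#'
#' @param fit a `nestbym_fit`.
#' @param scheme a [risk_band_scheme()] for the `band` column.
#' @return list of data frames `level1`, `level2`, `combined` (the last two
#'   `NULL`, with a `level2_missing` attribute set, for a level-1-only
#'   fit).
#' @export
risk_decomposition <- function(fit, scheme = risk_band_scheme()) {
  h <- fit$hierarchy
  d <- fit$draws$effects
  l1 <- rr_summary(d$mu + d$v, h$area_ids, "area")
  l1$band <- classify_risk(l1$rr, scheme)
  if (fit$model$variant != "model1" || is.null(d$omega)) {
    out <- list(level1 = l1, level2 = NULL, combined = NULL)
    attr(out, "level2_missing") <- TRUE
    message("level-1-only fit: super-region risk surfaces are absent")
    return(out)
  }
  l2 <- rr_summary(d$omega + d$xi, h$super_ids, "super_region")
  l2$band <- classify_risk(l2$rr, scheme)
  jm <- h$super_index
  comb <- rr_summary(d$mu + d$v +
                       d$omega[, jm, drop = FALSE] +
                       d$xi[, jm, drop = FALSE],
                     h$area_ids, "area")
  comb$band <- classify_risk(comb$rr, scheme)
  list(level1 = l1, level2 = l2, combined = comb)
}

#' Per-year temporal relative-risk table
#'
#' Posterior summaries of `exp(gamma_t)` (trend), `exp(phi_t)`
#' (exchangeable), and `exp(gamma_t + phi_t)` (combined), draw-wise with 95
#' percent intervals.
#'
#' @param fit a `nestbym_fit`.
#' @return data frame with one row per year.
#' @export
temporal_trend_table <- function(fit) {
  d <- fit$draws$effects
  g <- rr_summary(d$gamma, fit$times, "year")
  p <- rr_summary(d$phi, fit$times, "year")
  gp <- rr_summary(d$gamma + d$phi, fit$times, "year")
  data.frame(year = g$year,
             rr_trend = g$rr, trend_lower = g$lower, trend_upper = g$upper,
             rr_iid = p$rr, iid_lower = p$lower, iid_upper = p$upper,
             rr_total = gp$rr, total_lower = gp$lower,
             total_upper = gp$upper)
}

#' Per-area-per-year space-time interaction relative risks
#'
#' Posterior summaries of the combined interaction surface
#' `exp(delta_it + zeta_j(i),t)` (draw-wise, 95 percent intervals). For a
#' level-1-only fit the super-region interaction is absent and the surface
#' is `exp(delta_it)` alone, flagged via the `level2_missing` attribute.
#'
#' @param fit a `nestbym_fit`.
#' @return data frame with columns `area`, `year`, `rr`, `lower`, `upper`.
#' @export
interaction_trend_table <- function(fit) {
  h <- fit$hierarchy
  TT <- length(fit$times)
  d <- fit$draws$effects
  sum_draws <- d$delta
  missing2 <- fit$model$variant != "model1" || is.null(d$zeta)
  if (!missing2) {
    # zeta draws are space-major over (super, time); expand to (area, time)
    cellcols <- rep((h$super_index - 1L) * TT, each = TT) +
      rep(seq_len(TT), times = h$n1)
    sum_draws <- sum_draws + d$zeta[, cellcols, drop = FALSE]
  } else {
    message("level-1-only fit: interaction surface uses delta only")
  }
  labs <- paste(rep(h$area_ids, each = TT), rep(fit$times, times = h$n1))
  s <- rr_summary(sum_draws, labs, "cell")
  out <- data.frame(area = rep(h$area_ids, each = TT),
                    year = rep(fit$times, times = h$n1),
                    rr = s$rr, lower = s$lower, upper = s$upper)
  if (missing2) attr(out, "level2_missing") <- TRUE
  out
}

#' Write the relative-risk report tables to CSV
#'
#' Produces `spatial_rr_level1.csv`, `spatial_rr_level2.csv`,
#' `spatial_rr_combined.csv`, `temporal_rr.csv` and `interaction_rr.csv`.
#'
#' @param fit a `nestbym_fit`.
#' @param dir output directory.
#' @param scheme a [risk_band_scheme()].
#' @return `dir`, invisibly.
#' @export
write_risk_report <- function(fit, dir, scheme = risk_band_scheme()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rd <- risk_decomposition(fit, scheme)
  write.csv(rd$level1, file.path(dir, "spatial_rr_level1.csv"),
            row.names = FALSE)
  if (!is.null(rd$level2)) {
    write.csv(rd$level2, file.path(dir, "spatial_rr_level2.csv"),
              row.names = FALSE)
    write.csv(rd$combined, file.path(dir, "spatial_rr_combined.csv"),
              row.names = FALSE)
  }
  write.csv(temporal_trend_table(fit), file.path(dir, "temporal_rr.csv"),
            row.names = FALSE)
  write.csv(interaction_trend_table(fit),
            file.path(dir, "interaction_rr.csv"), row.names = FALSE)
  invisible(dir)
}
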