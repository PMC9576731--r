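#' Deviance information criterion from pointwise log-likelihood draws
#'
#' `Dbar` is the posterior mean of the deviance `-2 * sum(loglik)`;
#' `Dhat` is the deviance at the posterior-mean parameters (the plug-in,
#' supplied as the pointwise log likelihood evaluated at the posterior-mean
#' linear predictor); `pD = Dbar - Dhat` and `DIC = Dbar + pD`.
#'
#' @param loglik matrix of pointwise log-likelihood draws
#'   (draws x cells), at least 100 draws.
#' @param loglik_at_mean numeric vector of pointwise log likelihood at the
#'   posterior-mean parameters (length = cells).
#' @return list with `DIC`, `pD`, `Dbar`, `Dhat`. A slightly negative `pD`
#'   (Monte-Carlo noise) triggers a warning, not an error.
#' @export
compute_dic <- function(loglik, loglik_at_mean) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 100) stop("need at least 100 draws for DIC")
  if (length(loglik_at_mean) != ncol(loglik))
    stop("loglik_at_mean length must match the number of cells")
  Dbar <- mean(-2 * rowSums(loglik))
  Dhat <- -2 * sum(loglik_at_mean)
  pD <- Dbar - Dhat
  if (pD < 0)
    warning("negative pD (", format(pD), "); Monte-Carlo noise or misfit",
            call. = FALSE)
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Widely applicable information criterion from pointwise draws
#'
#' `lppd` sums the log of the posterior-mean pointwise likelihood (computed
#' stably in log space); `p_waic` sums the posterior variances of the
#' pointwise log likelihood; `WAIC = -2 (lppd - p_waic)`.
#'
#' @param loglik matrix of pointwise log-likelihood draws
#'   (draws x cells), at least 100 draws.
#' @return list with `WAIC`, `p_waic`, `lppd`.
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 100) stop("need at least 100 draws for WAIC")
  # column-wise log-mean-exp without leaving log space
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, var))
  list(WAIC = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Two-stage selection of the space-time interaction types
#'
#' Stage 1 drops the super-region effects (the level-1-only model variant)
#' and fits all four interaction types at the area level, recording DIC and
#' WAIC for each; the DIC argmin is chosen (WAIC is reported alongside and
#' a disagreement between the two criteria is flagged, not silently
#' resolved). Stage 2 fixes that type and fits the two-level model under
#' the four super-region-level types, choosing again by DIC argmin. When
#' the two best DIC values are closer than `tie_tol` the choice is flagged
#' as a near-tie.
#'
#' @param data a [panel_counts()].
#' @param sampler a [sampler_config()] reused for every candidate fit.
#' @param stages 1 (area level only) or 2 (both levels).
#' @param tie_tol DIC gap under which the choice is flagged as within
#'   Monte-Carlo noise.
#' @param hyperprior,alpha_prior_variance passed to [model_config()].
#' @return object of class `criteria_report`: candidate tables
#'   (`level1`, `level2`: type, DIC, pD, WAIC, p_waic), `chosen_type_level1`,
#'   `chosen_type_level2`, flags, and the selection rule record.
#' @export
select_interaction_types <- function(data, sampler = sampler_config(),
                                     stages = 2, tie_tol = 2,
                                     hyperprior = c(shape = 0.5, rate = 0.0005),
                                     alpha_prior_variance = 1e6) {
  stopifnot(stages %in% 1:2)
  run <- function(variant, type1, type2) {
    cfg <- model_config(variant, type1 = type1, type2 = type2,
                        hyperprior = hyperprior,
                        alpha_prior_variance = alpha_prior_variance)
    fit <- nestbym(data, cfg, sampler)
    d <- compute_dic(fit$loglik, fit$loglik_at_mean)
    w <- compute_waic(fit$loglik)
    c(DIC = d$DIC, pD = d$pD, WAIC = w$WAIC, p_waic = w$p_waic)
  }
  stage_table <- function(variant, type2 = NULL) {
    rows <- lapply(1:4, function(ty) {
      res <- tryCatch(
        if (is.null(type2)) run(variant, ty, 1) else run(variant, type2, ty),
        error = function(e) e)
      if (inherits(res, "error"))
        stop("fit failed for type ", ty, ": ", conditionMessage(res),
             call. = FALSE)
      data.frame(type = ty, DIC = res[["DIC"]], pD = res[["pD"]],
                 WAIC = res[["WAIC"]], p_waic = res[["p_waic"]])
    })
    do.call(rbind, rows)
  }
  pick <- function(tab) {
    ord <- order(tab$DIC)
    list(type = tab$type[[ord[[1]]]],
         near_tie = diff(tab$DIC[ord][1:2]) < tie_tol,
         waic_disagrees = tab$type[[which.min(tab$WAIC)]] !=
           tab$type[[ord[[1]]]])
  }

  t1 <- stage_table("model2")
  p1 <- pick(t1)
  out <- list(level1 = t1, chosen_type_level1 = p1$type,
              level1_near_tie = p1$near_tie,
              level1_waic_disagrees = p1$waic_disagrees,
              level2 = NULL, chosen_type_level2 = NULL,
              selection_rule = paste("argmin DIC; WAIC reported;",
                                     "ties within", tie_tol, "flagged"))
  if (stages == 2) {
    t2 <- stage_table("model1", type2 = p1$type)
    p2 <- pick(t2)
    out$level2 <- t2
    out$chosen_type_level2 <- p2$type
    out$level2_near_tie <- p2$near_tie
    out$level2_waic_disagrees <- p2$waic_disagrees
  }
  structure(out, class = "criteria_report")
}

#' Write the candidate tables of a selection report to CSV
#'
#' @param report a `criteria_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_criteria_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$level1, file.path(dir, "selection_level1.csv"),
            row.names = FALSE)
  if (!is.null(report$level2))
    write.csv(report$level2, file.path(dir, "selection_level2.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @export
print.criteria_report <- function(x, ...) {
  cat("Interaction-type selection (", x$selection_rule, ")\n", sep = "")
  cat("Level 1 candidates:\n"); print(x$level1)
  cat("chosen level-1 type:", x$chosen_type_level1,
      if (isTRUE(x$level1_near_tie)) "(near tie)" else "",
      if (isTRUE(x$level1_waic_disagrees)) "(WAIC disagrees)" else "", "\n")
  if (!is.null(x$level2)) {
    cat("Level 2 candidates:\n"); print(x$level2)
    cat("chosen level-2 type:", x$chosen_type_level2,
        if (isTRUE(x$level2_near_tie)) "(near tie)" else "",
        if (isTRUE(x$level2_waic_disagrees)) "(WAIC disagrees)" else "", "\n")
  }
  invisible(x)
}
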