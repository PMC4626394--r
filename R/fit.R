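#' Fit RDS prevalence estimators for one trait
#'
#' The main entry point: given a recruitment forest and a binary trait (or an
#' explicit group factor), computes the crude, equilibrium and RDS-adjusted
#' proportions, the recruitment transition matrix, group harmonic-mean
#' degrees, dependent-bootstrap standard errors with 95 percent percentile
#' intervals, and the cumulative per-wave equilibrium trace.
#'
#' @param forest a `recruitment_forest` from [build_recruitment_forest()].
#' @param trait name of a binary trait column in `forest$nodes`, or a group
#'   factor aligned with the nodes.
#' @param B bootstrap replicates (default 1000); `B = 0` skips the bootstrap.
#' @param seed optional integer seed for the bootstrap stream.
#' @param smoothing reciprocity-smooth the transition counts (off by default).
#' @param mean_type degree mean, `"harmonic"` (default) or `"arithmetic"`.
#' @param zero_row_policy transition-row policy for non-recruiting groups.
#' @param tolerance adjacent-wave tolerance for the equilibrium diagnostics.
#' @return an object of class `rds_estimate` with components `estimates`
#'   (long data frame: group, kind, proportion, se, ci), `transition`,
#'   `degrees`, `bootstrap` (per kind), `trace`, `waves_to_equilibrium`,
#'   `n`, `call`.
#' @examples
#' cfg <- scenario_default(population_size = 2000, target_n = 300,
#'                         seeds_community = 8, seeds_hospital = 3)
#' sim <- simulate_study(cfg, seed = 1)
#' fit <- rds_estimate(sim$forest, "trait:ketamine:lifetime", B = 50, seed = 1)
#' coef(fit)
#' @export
rds_estimate <- function(forest, trait, B = 1000L, seed = NULL,
                         smoothing = FALSE,
                         mean_type = c("harmonic", "arithmetic"),
                         zero_row_policy = c("uniform", "self"),
                         tolerance = 0.02) {
  mean_type <- match.arg(mean_type)
  zero_row_policy <- match.arg(zero_row_policy)
  part <- trait_partition(forest$nodes, trait)
  trait_name <- if (is.character(trait) && length(trait) == 1L) trait else "partition"

  tm <- estimate_transition_matrix(forest, part,
                                   zero_row_policy = zero_row_policy,
                                   smoothing = smoothing)
  degs <- harmonic_mean_degrees(forest, part, mean_type = mean_type)
  crude <- crude_proportion(forest, part)
  eq <- equilibrium_proportion(tm)
  adj <- rds_adjusted_proportion(tm, degs)

  boots <- list()
  if (B >= 2L) {
    for (kind in c("crude", "equilibrium", "rds_adjusted")) {
      boots[[kind]] <- bootstrap_se(forest, part, kind = kind, B = B,
                                    seed = seed, mean_type = mean_type,
                                    zero_row_policy = zero_row_policy)
    }
  }
  attach_se <- function(df) {
    b <- boots[[df$kind[1L]]]
    if (is.null(b)) {
      df$se <- NA_real_; df$ci_lo <- NA_real_; df$ci_hi <- NA_real_
    } else {
      m <- match(df$group, colnames(b$replicates))
      df$se <- b$se[m]
      df$ci_lo <- b$ci95[1L, m]
      df$ci_hi <- b$ci95[2L, m]
    }
    df
  }
  crude$n_contributing <- as.integer(table(part)[crude$group])
  eq$n_contributing <- crude$n_contributing[match(eq$group, crude$group)]
  adj$n_contributing <- crude$n_contributing[match(adj$group, crude$group)]
  est <- rbind(attach_se(crude[c("group", "kind", "proportion", "n_contributing")]),
               attach_se(eq), attach_se(adj))
  est <- cbind(trait = trait_name, est)
  rownames(est) <- NULL

  first_group <- levels(part)[1L]
  trace <- cumulative_wave_proportions(forest, part, first_group,
                                       tolerance = tolerance)
  seed_comp <- as.numeric(table(part[match(forest$roots, names(part))]))
  w2e <- tryCatch(
    waves_to_equilibrium(tm, seed_comp, tolerance = tolerance),
    error = function(e) NA_integer_)

  structure(list(trait = trait_name, estimates = est, transition = tm,
                 degrees = degs, bootstrap = boots, trace = trace,
                 waves_to_equilibrium = w2e, n = nrow(forest$nodes),
                 B = B, seed = seed, call = match.call()),
            class = "rds_estimate")
}

#' @export
print.rds_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("RDS prevalence fit for '%s' (n = %d, %d referral pairs)\n\n",
              x$trait, x$n, sum(x$transition$counts)))
  est <- x$estimates
  est$proportion <- round(est$proportion, digits)
  if (!all(is.na(est$se))) {
    est$se <- round(est$se, digits)
    est$ci_lo <- round(est$ci_lo, digits); est$ci_hi <- round(est$ci_hi, digits)
  }
  print(est, row.names = FALSE)
  if (!is.na(x$waves_to_equilibrium))
    cat(sprintf("\nWaves to equilibrium from seed composition: %d\n",
                x$waves_to_equilibrium))
  invisible(x)
}

#' @export
summary.rds_estimate <- function(object, ...) {
  structure(list(fit = object), class = "summary.rds_estimate")
}

#' @export
print.summary.rds_estimate <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$fit$transition, digits = 3)
  cat("\nHarmonic-mean degrees:\n")
  print(x$fit$degrees, row.names = FALSE)
  conv <- attr(x$fit$trace, "converged_at")
  cat(sprintf("\nCumulative-trace convergence (tol %.3g): %s\n",
              attr(x$fit$trace, "tolerance"),
              if (is.na(conv)) "not attained" else sprintf("wave %d", conv)))
  invisible(x)
}

#' @export
coef.rds_estimate <- function(object, kind = "rds_adjusted", ...) {
  e <- object$estimates[object$estimates$kind == kind, ]
  stats::setNames(e$proportion, e$group)
}

#' @export
confint.rds_estimate <- function(object, parm, level = 0.95,
                                 kind = "rds_adjusted", ...) {
  if (level != 0.95)
    rds_stop("rds_value_error", "only 95 percent percentile intervals are stored")
  e <- object$estimates[object$estimates$kind == kind, ]
  out <- cbind(`2.5 %` = e$ci_lo, `97.5 %` = e$ci_hi)
  rownames(out) <- e$group
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.rds_estimate <- function(x, ...) {
  plot(x$trace, main = sprintf("Cumulative wave proportions: %s", x$trait), ...)
  invisible(x)
}
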