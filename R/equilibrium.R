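#' Cumulative per-wave sample proportions
#'
#' The classic convergence diagnostic for chain-referral surveys: for each
#' recruitment wave `w`, the proportion of participants carrying the trait
#' among everyone recruited at waves `<= w` (seeds are wave 0). If the
#' accumulated proportion stabilizes well before the last wave, the sample
#' composition no longer depends on the seeds. Waves with no participants
#' carry the previous cumulative value forward.
#'
#' @param forest a `recruitment_forest`.
#' @param partition group factor from [trait_partition()].
#' @param trait_group the group whose proportion is traced (default the first
#'   level, `"user"` for binary traits).
#' @param tolerance adjacent-wave tolerance used to annotate convergence.
#' @return an `equilibrium_trace`: data frame with columns `wave`, `n_cum`,
#'   `proportion`, and attributes `group`, `tolerance`, `converged_at`.
#' @export
cumulative_wave_proportions <- function(forest, partition,
                                        trait_group = levels(partition)[1L],
                                        tolerance = 0.02) {
  if (nrow(forest$nodes) == 0L)
    rds_stop("rds_insufficient_data", "empty forest")
  waves <- forest$nodes$wave
  g <- partition[match(forest$nodes$pid, names(partition))]
  W <- max(waves)
  n_cum <- integer(W + 1L)
  pos_cum <- integer(W + 1L)
  for (w in 0:W) {
    n_cum[w + 1L] <- sum(waves <= w)
    pos_cum[w + 1L] <- sum(waves <= w & g == trait_group)
  }
  tr <- data.frame(wave = 0:W, n_cum = n_cum,
                   proportion = ifelse(n_cum > 0, pos_cum / n_cum, NA_real_))
  class(tr) <- c("equilibrium_trace", "data.frame")
  attr(tr, "group") <- trait_group
  attr(tr, "tolerance") <- tolerance
  attr(tr, "converged_at") <- detect_equilibrium(tr, tolerance)
  tr
}

#' Detect the equilibrium wave of a cumulative trace
#'
#' Returns the smallest wave `w` such that every adjacent-wave difference
#' from `w` onward is below `tolerance` — i.e. the proportion is
#' *consistently* within tolerance, not merely at its first crossing. `NA`
#' if the trace never settles.
#'
#' @param trace an `equilibrium_trace` or a plain numeric vector of
#'   cumulative proportions (wave 0 first).
#' @param tolerance adjacent-wave difference threshold; the working rule is
#'   0.02 (2 percent), with 0.05 the classic RDSAT default.
#' @return integer wave index, or `NA_integer_`.
#' @examples
#' detect_equilibrium(c(0.5, 0.3, 0.31, 0.315, 0.316))  # 1
#' @export
detect_equilibrium <- function(trace, tolerance = 0.02) {
  p <- if (is.data.frame(trace)) trace$proportion else as.numeric(trace)
  if (length(p) < 2L) return(0L)
  d <- abs(diff(p))
  bad <- which(d >= tolerance)
  if (length(bad) == 0L) return(0L)
  w <- max(bad)                      # first wave after the last violation
  if (w >= length(d)) return(NA_integer_)
  as.integer(w)
}

#' @export
plot.equilibrium_trace <- function(x, main = "Cumulative wave proportions", ...) {
  graphics::plot(x$wave, x$proportion, type = "b", pch = 16,
                 xlab = "recruitment wave",
                 ylab = sprintf("cumulative proportion (%s)", attr(x, "group")),
                 ylim = c(0, max(x$proportion, na.rm = TRUE) * 1.2 + 0.02),
                 main = main, ...)
  conv <- attr(x, "converged_at")
  if (!is.na(conv)) graphics::abline(v = conv, lty = 2)
  invisible(x)
}

#' Export an equilibrium trace as a plain table
#'
#' @param trace an `equilibrium_trace`.
#' @param trait optional trait label for the output.
#' @return data frame `trait`, `wave`, `n_cum`, `proportion`, `converged_at`.
#' @export
trace_table <- function(trace, trait = attr(trace, "group")) {
  data.frame(trait = trait, wave = trace$wave, n_cum = trace$n_cum,
             proportion = trace$proportion,
             converged_at = attr(trace, "converged_at"))
}
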