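#' Crude (raw sample) proportions
#'
#' The unweighted sample composition: group count over total. Seeds are
#' included in the denominator.
#'
#' @param records participant data frame (or `recruitment_forest`).
#' @param partition group factor from [trait_partition()].
#' @return data frame with columns `group`, `kind = "crude"`, `proportion`,
#'   `n_contributing`.
#' @export
crude_proportion <- function(records, partition) {
  if (inherits(records, "recruitment_forest")) records <- records$nodes
  n <- length(partition)
  if (n == 0L)
    rds_stop("rds_insufficient_data", "no records to estimate from")
  tab <- table(partition)
  data.frame(group = names(tab), kind = "crude",
             proportion = as.numeric(tab) / n,
             n_contributing = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Harmonic-mean degree per group
#'
#' The degree weighting component of the RDS-adjusted estimator: for group
#' \eqn{g}, \eqn{\hat D_g = n_g / \sum_{i \in g} 1/d_i}, the harmonic
#' ("multiplicity") mean of reported network degrees. Larger average degree
#' means larger inclusion probability, so prevalence of high-degree groups is
#' weighted down. Records with degree < 1 or missing are excluded from the
#' mean and counted in `n_excluded`; the arithmetic mean is available for
#' sensitivity analysis.
#'
#' @param records participant data frame with `degree`, or a forest.
#' @param partition group factor.
#' @param mean_type `"harmonic"` (default) or `"arithmetic"`.
#' @return data frame `group`, `D` (mean degree), `n`, `n_excluded`.
#' @examples
#' # degrees 1 and 4 in one group: 2 / (1 + 1/4) = 1.6
#' @export
harmonic_mean_degrees <- function(records, partition,
                                  mean_type = c("harmonic", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  if (inherits(records, "recruitment_forest")) records <- records$nodes
  deg <- as.numeric(records$degree)
  ok <- !is.na(deg) & deg >= 1
  out <- do.call(rbind, lapply(levels(partition), function(g) {
    in_g <- partition == g
    d <- deg[in_g & ok]
    if (length(d) == 0L)
      rds_stop("rds_insufficient_data",
               "group '%s' has no valid degrees (>= 1)", g)
    D <- if (mean_type == "harmonic") length(d) / sum(1 / d) else mean(d)
    data.frame(group = g, D = D, n = length(d),
               n_excluded = sum(in_g & !ok), stringsAsFactors = FALSE)
  }))
  if (sum(out$n_excluded) > 0)
    message(sprintf("%d record(s) with invalid degree excluded from degree weighting",
                    sum(out$n_excluded)))
  out
}

#' RDS-adjusted population proportions
#'
#' Combines the equilibrium composition of the recruitment Markov chain with
#' the group harmonic-mean degrees (the reciprocity / RDS-I estimator):
#' \deqn{\hat P_g = \frac{\pi_g / \hat D_g}{\sum_h \pi_h / \hat D_h}.}
#' For two groups this reduces to the closed form
#' \eqn{\hat P_A = S_{BA} \hat D_B / (S_{AB} \hat D_A + S_{BA} \hat D_B)},
#' and with equal degrees it equals the equilibrium proportions.
#'
#' @param transition an `rds_transition`.
#' @param degrees output of [harmonic_mean_degrees()].
#' @return data frame `group`, `kind = "rds_adjusted"`, `proportion`.
#' @export
rds_adjusted_proportion <- function(transition, degrees) {
  pi <- equilibrium_distribution(transition)
  D <- degrees$D[match(names(pi), degrees$group)]
  if (anyNA(D))
    rds_stop("rds_insufficient_data", "degree summary missing group(s): %s",
             paste(names(pi)[is.na(D)], collapse = ", "))
  w <- pi / D
  data.frame(group = names(pi), kind = "rds_adjusted",
             proportion = as.numeric(w / sum(w)),
             stringsAsFactors = FALSE)
}

#' Equilibrium-based proportions
#'
#' The stationary composition of the recruitment chain as a prevalence
#' estimate (no degree correction).
#'
#' @inheritParams rds_adjusted_proportion
#' @return data frame `group`, `kind = "equilibrium"`, `proportion`.
#' @export
equilibrium_proportion <- function(transition) {
  pi <- equilibrium_distribution(transition)
  data.frame(group = names(pi), kind = "equilibrium",
             proportion = as.numeric(pi), stringsAsFactors = FALSE)
}

#' Wald test for a difference of two proportions
#'
#' \eqn{z = (p_1 - p_2) / \sqrt{se_1^2 + se_2^2}}, two-sided normal p-value.
#' Used to contrast prevalence between strata (e.g. early- vs late-onset
#' smokers); p-values are reported unadjusted, one test per contrast.
#'
#' @param p1,p2 proportions. @param se1,se2 their standard errors (> 0).
#' @return list `z`, `p_value`.
#' @export
wald_test <- function(p1, se1, p2, se2) {
  if (!isTRUE(se1 > 0) || !isTRUE(se2 > 0))
    rds_stop("rds_undefined_test", "Wald test undefined: standard errors must be > 0")
  z <- (p1 - p2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

## round half away from zero (printed epidemiological tables round 2.45 -> 2.5,
## unlike R's round-half-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Prevalence ratio between two strata
#'
#' Ratio of two prevalence estimates (e.g. early- over late-onset), rounded
#' half away from zero to match printed tables.
#'
#' @param p_early,p_late prevalences on the same scale; `p_late` must be > 0.
#' @param decimals decimals to round to (default 1).
#' @return the rounded ratio.
#' @examples
#' prevalence_ratio(16.3, 5.7)  # 2.9
#' @export
prevalence_ratio <- function(p_early, p_late, decimals = 1) {
  if (!isTRUE(p_late > 0))
    rds_stop("rds_undefined_ratio", "prevalence ratio undefined: denominator must be > 0")
  round_half_away(p_early / p_late, decimals)
}
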