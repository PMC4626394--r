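#' Estimate the recruitment transition matrix
#'
#' The core RDS assumption is that referral probabilities depend only on the
#' recruiter's group, so recruiter-to-recruit pairs form a Markov chain over
#' the trait groups. `S[a, b]` is the probability that a recruiter in group
#' `a` recruits into group `b`, estimated by row-normalizing the raw pair
#' counts. Seeds enter as recruiters only, never as recruits.
#'
#' `smoothing = TRUE` applies reciprocity smoothing before normalizing:
#' `counts*[a,b] = counts*[b,a] = (counts[a,b] + counts[b,a]) / 2`, the "data
#' smoothing" option of the classic RDS analysis tool. Off by default.
#'
#' @param forest a `recruitment_forest`.
#' @param partition group factor from [trait_partition()] (names = pids).
#' @param zero_row_policy what to do with a group that never recruited:
#'   `"uniform"` spreads its row evenly, `"self"` makes it a self-loop. The
#'   affected groups are reported via the `zero_rows` element, never patched
#'   silently.
#' @param smoothing logical; reciprocity-smooth the counts first.
#' @return an object of class `rds_transition`: list with `groups`, `S`
#'   (row-stochastic matrix), `counts` (raw), `zero_rows`.
#' @examples
#' # edges A->B, A->B, A->A, B->A give S = [[1/3, 2/3], [1, 0]]
#' @export
estimate_transition_matrix <- function(forest, partition,
                                       zero_row_policy = c("uniform", "self"),
                                       smoothing = FALSE) {
  zero_row_policy <- match.arg(zero_row_policy)
  if (nrow(forest$edges) == 0L)
    rds_stop("rds_insufficient_data", "forest has no referral edges")
  groups <- levels(partition)
  k <- length(groups)
  g_from <- partition[match(forest$edges$recruiter, names(partition))]
  g_to   <- partition[match(forest$edges$recruit,  names(partition))]
  counts <- table(factor(g_from, levels = groups),
                  factor(g_to,   levels = groups))
  counts <- matrix(as.numeric(counts), k, k, dimnames = list(groups, groups))
  work <- if (smoothing) (counts + t(counts)) / 2 else counts
  rs <- rowSums(work)
  zero_rows <- groups[rs == 0]
  S <- work
  for (i in seq_len(k)) {
    if (rs[i] > 0) {
      S[i, ] <- work[i, ] / rs[i]
    } else if (zero_row_policy == "uniform") {
      S[i, ] <- 1 / k
    } else {
      S[i, ] <- 0; S[i, i] <- 1
    }
  }
  structure(list(groups = groups, S = S, counts = counts,
                 zero_rows = zero_rows, smoothing = smoothing),
            class = "rds_transition")
}

#' @export
print.rds_transition <- function(x, digits = 3, ...) {
  cat(sprintf("Recruitment transition matrix (%d groups, %d referral pairs%s)\n",
              length(x$groups), sum(x$counts),
              if (x$smoothing) ", reciprocity-smoothed" else ""))
  print(round(x$S, digits))
  if (length(x$zero_rows))
    cat("Note: no recruitments observed from group(s):",
        paste(x$zero_rows, collapse = ", "), "\n")
  invisible(x)
}

## Communicating-class analysis of the support of S: returns the list of
## closed (recurrent) classes. Uses Warshall transitive closure; k is small.
closed_classes <- function(S) {
  k <- nrow(S)
  R <- (S > 0) | diag(k) > 0
  for (m in seq_len(k)) R <- R | outer(R[, m], R[m, ])
  comm <- R & t(R)
  classes <- unique(apply(comm, 1L, function(r) which(r), simplify = FALSE))
  Filter(function(cl) {
    ## closed: no arc leaving the class
    !any(R[cl, -cl, drop = FALSE]) || length(cl) == k
  }, classes)
}

#' Stationary (equilibrium) distribution of a recruitment chain
#'
#' Solves \eqn{\pi S = \pi}, \eqn{\sum \pi = 1} directly. This is the
#' trait composition the recruitment process converges to after enough
#' waves, independent of the seed composition — the "equilibrium-based"
#' prevalence before degree correction.
#'
#' @param x an `rds_transition`, or a plain row-stochastic matrix.
#' @return named numeric vector `pi` summing to 1.
#' @section Degenerate chains: if the support of `S` has more than one closed
#'   communicating class (e.g. the identity matrix), the stationary vector is
#'   not unique and a degeneracy error naming the absorbing classes is
#'   raised.
#' @examples
#' S <- matrix(c(2/3, 1/3, 1, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("A","B"), c("A","B")))
#' equilibrium_distribution(S)  # (0.75, 0.25)
#' @export
equilibrium_distribution <- function(x) {
  S <- if (inherits(x, "rds_transition")) x$S else as.matrix(x)
  k <- nrow(S)
  if (is.null(rownames(S))) dimnames(S) <- list(seq_len(k), seq_len(k))
  if (any(S < -1e-12) || any(abs(rowSums(S) - 1) > 1e-8))
    rds_stop("rds_value_error", "matrix is not row-stochastic")
  cc <- closed_classes(S)
  if (length(cc) > 1L) {
    lab <- vapply(cc, function(cl) paste0("{", paste(rownames(S)[cl], collapse = ","), "}"), "")
    rds_stop("rds_degenerate_chain",
             "no unique stationary distribution: absorbing classes %s",
             paste(lab, collapse = ", "))
  }
  ## solve pi (S - I) = 0 with sum constraint: append ones column
  A <- rbind(t(S) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  names(pi) <- rownames(S)
  pi
}

#' Waves needed to reach equilibrium from a seed composition
#'
#' Iterates the seed group composition through the transition matrix and
#' returns the smallest wave `t` at which every group of `v S^t` is within
#' `tolerance` of the stationary distribution. This is the recursion-based
#' diagnostic for whether a chain-referral survey ran long enough.
#'
#' @param x `rds_transition` or row-stochastic matrix.
#' @param seed_composition probability vector over groups (the composition of
#'   wave 0); normalized if it does not sum to 1.
#' @param tolerance max absolute deviation from the stationary vector
#'   (default 0.02, the working 2 percent rule; 0.05 is the classic RDSAT
#'   default).
#' @param max_iter iteration cap.
#' @return integer number of waves (0 when the seeds already match).
#' @export
waves_to_equilibrium <- function(x, seed_composition, tolerance = 0.02,
                                 max_iter = 1000L) {
  S <- if (inherits(x, "rds_transition")) x$S else as.matrix(x)
  pi <- equilibrium_distribution(S)
  v <- as.numeric(seed_composition)
  if (length(v) != nrow(S))
    rds_stop("rds_value_error", "seed composition length != number of groups")
  v <- v / sum(v)
  for (t in 0:max_iter) {
    if (max(abs(v - pi)) < tolerance) return(t)
    v <- as.numeric(v %*% S)
  }
  rds_stop("rds_nonconvergence",
           "no convergence to the stationary distribution within %d iterations",
           max_iter)
}
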