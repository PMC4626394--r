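## run expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Dependent (chain) bootstrap standard errors for RDS estimators
#'
#' Resamples whole pseudo-recruitment-chains to respect the dependence of a
#' chain-referral sample. Each replicate rebuilds a pseudo-sample of the
#' original size by Markov draws: starting from a uniformly chosen observed
#' recruit, the next individual is drawn uniformly (with replacement) from
#' the pool of observed recruits whose recruiter belonged to the current
#' individual's group. The chosen estimator is then re-run on the replicate
#' (its own transition counts and degree sums), and the standard error and
#' percentile interval are taken over replicates.
#'
#' If the chain enters a group whose recruit pool is empty, the draw restarts
#' from a uniformly chosen observed recruit; restarts are counted in the
#' result (`n_restarts`) and such non-conditional draws are excluded from the
#' replicate's transition counts. Replicates whose transition matrix is
#' degenerate fall back to the replicate's raw composition (`n_fallbacks`).
#'
#' @param forest a `recruitment_forest`.
#' @param partition group factor from [trait_partition()].
#' @param kind which estimator to bootstrap.
#' @param B number of replicates (>= 2); 1000 by default.
#' @param seed optional integer; with a seed the result is reproducible and
#'   the caller's RNG state is untouched.
#' @param mean_type degree mean passed to the adjusted estimator.
#' @param zero_row_policy policy for non-recruiting groups in replicates.
#' @return object of class `rds_bootstrap`: list with `se` (named vector),
#'   `ci95` (2 x k matrix, 2.5/97.5 percentiles), `replicates` (B x k),
#'   `kind`, `B`, `n_restarts`, `n_fallbacks`.
#' @export
bootstrap_se <- function(forest, partition,
                         kind = c("rds_adjusted", "equilibrium", "crude"),
                         B = 1000L, seed = NULL,
                         mean_type = c("harmonic", "arithmetic"),
                         zero_row_policy = c("uniform", "self")) {
  kind <- match.arg(kind)
  mean_type <- match.arg(mean_type)
  zero_row_policy <- match.arg(zero_row_policy)
  if (B < 2L) rds_stop("rds_value_error", "B must be >= 2")
  if (nrow(forest$edges) == 0L)
    rds_stop("rds_insufficient_data", "forest has no referral edges to resample")
  with_seed(seed, boot_chain_impl(forest, partition, kind, as.integer(B),
                                  mean_type, zero_row_policy))
}

boot_chain_impl <- function(forest, partition, kind, B, mean_type, zero_row_policy) {
  nodes <- forest$nodes
  groups <- levels(partition)
  k <- length(groups)
  grp <- as.integer(partition)[match(nodes$pid, names(partition))]
  deg <- suppressWarnings(as.numeric(nodes$degree))
  valid <- !is.na(deg) & deg >= 1
  inv <- ifelse(valid, 1 / deg, 0)
  use_harmonic <- mean_type == "harmonic"

  rec_idx <- match(forest$edges$recruit, nodes$pid)     # observed recruits
  rtr_grp <- grp[match(forest$edges$recruiter, nodes$pid)]
  pools <- split(rec_idx, factor(rtr_grp, levels = seq_len(k)))
  pool_len <- lengths(pools)
  n <- nrow(nodes)

  ngrp <- matrix(0L, B, k)
  nval <- matrix(0L, B, k)
  invd <- matrix(0, B, k)
  trans <- matrix(0L, B, k * k)
  n_restarts <- 0L

  tally <- function(idx_drawn) {
    g <- grp[idx_drawn]
    ij <- cbind(seq_len(B), g)
    ngrp[ij] <<- ngrp[ij] + 1L
    v <- valid[idx_drawn]
    if (any(v)) {
      ijv <- ij[v, , drop = FALSE]
      nval[ijv] <<- nval[ijv] + 1L
      if (use_harmonic) invd[ijv] <<- invd[ijv] + inv[idx_drawn][v]
      else invd[ijv] <<- invd[ijv] + deg[idx_drawn][v]  # arithmetic: sum then /n
    }
    g
  }

  cur_idx <- rec_idx[sample.int(length(rec_idx), B, replace = TRUE)]
  cur_g <- tally(cur_idx)
  if (n > 1L) for (t in 2:n) {
    nxt <- integer(B)
    restart <- logical(B)
    for (gi in unique(cur_g)) {
      at <- which(cur_g == gi)
      if (pool_len[gi] == 0L) {
        nxt[at] <- rec_idx[sample.int(length(rec_idx), length(at), replace = TRUE)]
        restart[at] <- TRUE
      } else {
        nxt[at] <- pools[[gi]][sample.int(pool_len[gi], length(at), replace = TRUE)]
      }
    }
    n_restarts <- n_restarts + sum(restart)
    g_nxt <- grp[nxt]
    keep <- which(!restart)
    if (length(keep)) {
      tcol <- (cur_g[keep] - 1L) * k + g_nxt[keep]
      ij <- cbind(keep, tcol)
      trans[ij] <- trans[ij] + 1L
    }
    cur_g <- tally(nxt)
    cur_idx <- nxt
  }

  reps <- replicate_estimates(kind, k, B, ngrp, nval, invd, trans,
                              zero_row_policy, use_harmonic, n, groups)
  est <- reps$est
  colnames(est) <- groups
  structure(list(
    se = apply(est, 2L, stats::sd),
    ci95 = apply(est, 2L, stats::quantile, probs = c(0.025, 0.975)),
    replicates = est, kind = kind, B = B,
    n_restarts = n_restarts, n_fallbacks = reps$n_fallbacks
  ), class = "rds_bootstrap")
}

replicate_estimates <- function(kind, k, B, ngrp, nval, invd, trans,
                                zero_row_policy, use_harmonic, n, groups) {
  n_fallbacks <- 0L
  if (kind == "crude") return(list(est = ngrp / n, n_fallbacks = 0L))
  ## group mean degrees per replicate (NA where a group has no valid degree)
  D <- if (use_harmonic) ifelse(nval > 0, nval / invd, NA_real_)
       else ifelse(nval > 0, invd / nval, NA_real_)
  if (k == 2L) {
    r1 <- trans[, 1L] + trans[, 2L]
    r2 <- trans[, 3L] + trans[, 4L]
    zr <- if (zero_row_policy == "uniform") 0.5 else 0
    S12 <- ifelse(r1 > 0, trans[, 2L] / r1, zr)
    S21 <- ifelse(r2 > 0, trans[, 3L] / r2, zr)
    den <- S12 + S21
    p1 <- ifelse(den > 0, S21 / den, ngrp[, 1L] / pmax(ngrp[, 1L] + ngrp[, 2L], 1L))
    n_fallbacks <- sum(den <= 0)
    est <- cbind(p1, 1 - p1)
    if (kind == "rds_adjusted") {
      D1 <- ifelse(is.na(D[, 1L]), 1, D[, 1L])
      D2 <- ifelse(is.na(D[, 2L]), 1, D[, 2L])
      ## a group absent from the replicate keeps weight 0 through pi = 0
      w1 <- est[, 1L] / D1
      w2 <- est[, 2L] / D2
      est <- cbind(w1, w2) / (w1 + w2)
    }
    return(list(est = est, n_fallbacks = n_fallbacks))
  }
  est <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    S <- matrix(as.numeric(trans[b, ]), k, k, byrow = TRUE)
    rs <- rowSums(S)
    for (i in seq_len(k)) {
      if (rs[i] > 0) S[i, ] <- S[i, ] / rs[i]
      else if (zero_row_policy == "uniform") S[i, ] <- 1 / k
      else { S[i, ] <- 0; S[i, i] <- 1 }
    }
    dimnames(S) <- list(groups, groups)
    pi <- tryCatch(equilibrium_distribution(S), error = function(e) NULL)
    if (is.null(pi)) {
      pi <- ngrp[b, ] / max(sum(ngrp[b, ]), 1L)
      n_fallbacks <- n_fallbacks + 1L
    }
    if (kind == "rds_adjusted") {
      Db <- ifelse(is.na(D[b, ]), 1, D[b, ])
      w <- pi / Db
      pi <- w / sum(w)
    }
    est[b, ] <- pi
  }
  list(est = est, n_fallbacks = n_fallbacks)
}

#' @export
print.rds_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Dependent chain bootstrap (%s estimator, B = %d%s)\n",
              x$kind, x$B,
              if (x$n_restarts > 0) sprintf(", %d restarts", x$n_restarts) else ""))
  out <- rbind(se = x$se, x$ci95)
  print(round(out, digits))
  invisible(x)
}
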