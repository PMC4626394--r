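DRUGS <- c("ketamine", "ecstasy", "marijuana", "methamphetamine", "heroin")
CLUB_DRUGS <- c("ketamine", "ecstasy", "marijuana")
HARD_DRUGS <- c("methamphetamine", "heroin")

#' Derive composite drug-use traits
#'
#' Adds, for each window (`lifetime`, `past_year`, where present), the
#' composites `any_illegal` (any of the five drugs), `any_club` (ketamine,
#' ecstasy or marijuana), `any_hard` (methamphetamine or heroin), and the
#' mutually exclusive use-pattern indicators `single` (exactly one drug),
#' `poly_no_hard` (two or more, none hard) and `poly_hard` (two or more,
#' at least one hard). Non-users are the complement, so the four pattern
#' classes partition the sample.
#'
#' @param records participant data frame with the per-drug trait columns.
#' @param windows which windows to derive (default: those present).
#' @return the records with added `trait:<name>:<window>` columns.
#' @export
derive_composite_traits <- function(records,
                                    windows = c("lifetime", "past_year")) {
  for (win in windows) {
    cols <- trait_col(DRUGS, win)
    if (!all(cols %in% names(records))) {
      if (!any(cols %in% names(records))) next
      rds_stop("rds_schema_error", "missing base trait column(s): %s",
               paste(setdiff(cols, names(records)), collapse = ", "))
    }
    m <- as.matrix(records[cols])
    n_drugs <- rowSums(m)
    hard <- rowSums(m[, trait_col(HARD_DRUGS, win), drop = FALSE])
    records[[trait_col("any_illegal", win)]] <- (n_drugs >= 1) * 1L
    records[[trait_col("any_club", win)]] <-
      (rowSums(m[, trait_col(CLUB_DRUGS, win), drop = FALSE]) >= 1) * 1L
    records[[trait_col("any_hard", win)]] <- (hard >= 1) * 1L
    records[[trait_col("single", win)]] <- (n_drugs == 1) * 1L
    records[[trait_col("poly_no_hard", win)]] <- (n_drugs >= 2 & hard == 0) * 1L
    records[[trait_col("poly_hard", win)]] <- (n_drugs >= 2 & hard >= 1) * 1L
  }
  records
}

## polynomial rolling hash over the serialized config, for run metadata
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-seq_len(14L)])
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run the full prevalence analysis
#'
#' End-to-end orchestration: derive composites, build (or reuse) the
#' recruitment forest, and for every requested trait and window estimate the
#' crude, equilibrium and RDS-adjusted prevalence with dependent-bootstrap
#' standard errors — overall and stratified by tobacco-onset stratum — plus
#' the early/late prevalence ratio, the Wald contrast, the cumulative wave
#' trace and the waves-to-equilibrium diagnostic. Stratified estimates use
#' the induced subforest of each stratum (cross-stratum referrals make the
#' recruit a pseudo-root of its stratum).
#'
#' @param x participant data frame, a `recruitment_forest`, or a
#'   `sim_config` (which is simulated first).
#' @param traits trait base names to analyse (default: five drugs plus
#'   composites and use patterns).
#' @param windows trait windows.
#' @param B bootstrap replicates per estimate.
#' @param seed integer seed governing simulation (if any) and all bootstrap
#'   streams.
#' @param stratify_by stratification column (`NULL` to skip stratification).
#' @param tolerance equilibrium tolerance.
#' @return an `rds_report`: list with `table` (one row per trait x window:
#'   n, crude/equilibrium/adjusted %, CI, per-stratum adjusted % and CI,
#'   ratio, Wald z and p), `traces`, `fits`, `meta`.
#' @export
run_analysis <- function(x, traits = c(DRUGS, "any_illegal", "any_club",
                                       "any_hard", "single", "poly_no_hard",
                                       "poly_hard"),
                         windows = c("lifetime", "past_year"),
                         B = 1000L, seed = NULL,
                         stratify_by = "onset_stratum",
                         tolerance = 0.02) {
  sim_seed <- if (is.null(seed)) NULL else seed
  if (inherits(x, "sim_config")) {
    sim <- simulate_study(x, seed = sim_seed)
    records <- sim$records
    forest <- sim$forest
    cfg <- x
  } else if (inherits(x, "recruitment_forest")) {
    records <- x$nodes; forest <- x; cfg <- NULL
  } else {
    records <- x
    forest <- build_recruitment_forest(records)
    cfg <- NULL
  }
  records <- derive_composite_traits(records)
  keep_wave <- forest$nodes$wave
  forest$nodes <- records[match(forest$nodes$pid, records$pid), , drop = FALSE]
  forest$nodes$wave <- keep_wave

  strata <- NULL
  if (!is.null(stratify_by) && stratify_by %in% names(records))
    strata <- sort(unique(records[[stratify_by]]))

  rows <- list(); traces <- list(); fits <- list()
  log_lines <- character(0)
  bseed <- function(i) if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
  i <- 0L
  for (win in windows) for (tr in traits) {
    col <- trait_col(tr, win)
    if (!col %in% names(records)) next
    i <- i + 1L
    fit <- rds_estimate(forest, col, B = B, seed = bseed(i),
                        tolerance = tolerance)
    fits[[col]] <- fit
    traces[[col]] <- fit$trace
    user <- function(f, kind) {
      e <- f$estimates
      e[e$group == "user" & e$kind == kind, ]
    }
    adj <- user(fit, "rds_adjusted")
    row <- data.frame(
      trait = tr, window = win,
      n = adj$n_contributing,
      crude_pct = 100 * user(fit, "crude")$proportion,
      equilibrium_pct = 100 * user(fit, "equilibrium")$proportion,
      adjusted_pct = 100 * adj$proportion,
      adjusted_se_pct = 100 * adj$se,
      ci_lo_pct = 100 * adj$ci_lo, ci_hi_pct = 100 * adj$ci_hi,
      converged_at = attr(fit$trace, "converged_at"),
      waves_to_equilibrium = fit$waves_to_equilibrium,
      stringsAsFactors = FALSE)
    if (!is.null(strata) && length(strata) == 2L) {
      sub <- lapply(strata, function(s) {
        sf <- subset_forest(forest, records$pid[records[[stratify_by]] == s])
        i <<- i + 1L
        tryCatch(rds_estimate(sf, col, B = B, seed = bseed(i),
                              tolerance = tolerance),
                 error = function(e) {
                   log_lines <<- c(log_lines,
                                   sprintf("stratum %s, %s: %s", s, col,
                                           conditionMessage(e)))
                   NULL
                 })
      })
      vals <- lapply(sub, function(f) if (is.null(f)) NULL else user(f, "rds_adjusted"))
      a <- vals[[1L]]; b <- vals[[2L]]
      row$stratum1 <- strata[1L]; row$stratum2 <- strata[2L]
      row$n1 <- if (is.null(a)) NA_integer_ else a$n_contributing
      row$n2 <- if (is.null(b)) NA_integer_ else b$n_contributing
      row$adjusted1_pct <- if (is.null(a)) NA_real_ else 100 * a$proportion
      row$adjusted2_pct <- if (is.null(b)) NA_real_ else 100 * b$proportion
      row$se1_pct <- if (is.null(a)) NA_real_ else 100 * a$se
      row$se2_pct <- if (is.null(b)) NA_real_ else 100 * b$se
      row$ratio <- if (!is.null(a) && !is.null(b) && isTRUE(b$proportion > 0))
        prevalence_ratio(a$proportion, b$proportion) else NA_real_
      wt <- if (!is.null(a) && !is.null(b) && isTRUE(a$se > 0) && isTRUE(b$se > 0))
        wald_test(a$proportion, a$se, b$proportion, b$se)
      else list(z = NA_real_, p_value = NA_real_)
      row$wald_z <- wt$z; row$wald_p <- wt$p_value
    }
    rows[[col]] <- row
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, traces = traces, fits = fits,
                 log = log_lines,
                 meta = list(seed = seed, B = B,
                             n = nrow(records),
                             config_hash = if (is.null(cfg)) NA_character_
                                           else config_hash(cfg),
                             tolerance = tolerance)),
            class = "rds_report")
}

#' @export
print.rds_report <- function(x, digits = 1, ...) {
  cat(sprintf("RDS analysis report: n = %d, B = %d, seed = %s\n\n",
              x$meta$n, x$meta$B,
              if (is.null(x$meta$seed)) "<none>" else x$meta$seed))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE) & !(names(tab) %in% c("n", "n1", "n2"))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$log)) cat("\nRun log:\n", paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report's tables to delimited files
#'
#' Writes `<stem>_estimates.csv` (the main table) and `<stem>_traces.csv`
#' (all cumulative wave traces), plus `<stem>_meta.csv` with the run
#' metadata, so every reported number can be recomputed from persisted
#' artifacts.
#'
#' @param report an `rds_report`. @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, stem) {
  paths <- c(estimates = paste0(stem, "_estimates.csv"),
             traces = paste0(stem, "_traces.csv"),
             meta = paste0(stem, "_meta.csv"))
  utils::write.csv(report$table, paths["estimates"], row.names = FALSE)
  tr <- do.call(rbind, lapply(names(report$traces), function(nm)
    trace_table(report$traces[[nm]], trait = nm)))
  utils::write.csv(tr, paths["traces"], row.names = FALSE)
  meta <- report$meta
  meta$seed <- if (is.null(meta$seed)) NA else meta$seed
  utils::write.csv(as.data.frame(meta), paths["meta"], row.names = FALSE)
  invisible(paths)
}
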