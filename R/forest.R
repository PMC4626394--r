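#' Build a recruitment forest from participant records
#'
#' Reconstructs the referral trees of a chain-referral (RDS) survey from the
#' participants' referral codes: each non-seed is attached to the participant
#' holding its parent code (last nonzero digit dropped). The result is a
#' forest rooted at the seeds, with the wave of every participant equal to the
#' number of leading nonzero digits of its code.
#'
#' Construction is order-independent: shuffling `records` yields an identical
#' forest. Invariants enforced: unique codes, every parent present, no
#' recruiter with more than `max_coupons` recruits.
#'
#' @param records a participant data frame with at least columns `pid` and
#'   `code` (see [read_participants()] for the full schema).
#' @param max_coupons maximum recruits per recruiter (the study design handed
#'   out at most 5 referral coupons).
#' @return an object of class `recruitment_forest`: a list with `nodes` (the
#'   record data frame, ordered by code, with a `wave` column), `edges` (data
#'   frame `recruiter`/`recruit` of pids) and `roots` (seed pids).
#' @examples
#' recs <- data.frame(pid = c("a", "b", "c"),
#'                    code = c("F001-0000000000", "F001-1000000000",
#'                             "F001-1100000000"))
#' f <- build_recruitment_forest(recs)
#' f$nodes$wave   # 0 1 2
#' @export
build_recruitment_forest <- function(records, max_coupons = 5L) {
  stopifnot(is.data.frame(records))
  if (!all(c("pid", "code") %in% names(records)))
    rds_stop("rds_schema_error", "records need 'pid' and 'code' columns")
  if (nrow(records) == 0L)
    rds_stop("rds_insufficient_data", "no participant records")
  if (anyDuplicated(records$code))
    rds_stop("rds_structure_error", "duplicated referral code(s): %s",
             paste(unique(records$code[duplicated(records$code)]), collapse = ", "))
  if (anyDuplicated(records$pid))
    rds_stop("rds_structure_error", "duplicated pid(s): %s",
             paste(unique(records$pid[duplicated(records$pid)]), collapse = ", "))

  records <- records[order(records$code), , drop = FALSE]
  rownames(records) <- NULL
  codes <- vapply(records$code, function(s) format_referral_code(parse_referral_code(s)), "")
  names(codes) <- NULL
  records$code <- codes
  records$wave <- code_waves(codes)

  parents <- vapply(codes, function(s) {
    p <- referral_parent(s)
    if (is.na(p)) "" else p
  }, "")
  names(parents) <- NULL
  is_seed <- parents == ""
  idx <- match(parents[!is_seed], codes)
  if (anyNA(idx)) {
    missing <- unique(parents[!is_seed][is.na(idx)])
    rds_stop("rds_missing_parent",
             "orphan code(s): parent code(s) not present: %s",
             paste(missing, collapse = ", "))
  }
  edges <- data.frame(recruiter = records$pid[idx],
                      recruit   = records$pid[!is_seed],
                      stringsAsFactors = FALSE)
  n_kids <- table(edges$recruiter)
  if (any(n_kids > max_coupons))
    rds_stop("rds_coupon_limit",
             "recruiter(s) exceed the %d-coupon limit: %s", max_coupons,
             paste(names(n_kids)[n_kids > max_coupons], collapse = ", "))
  ## child wave = parent wave + 1 holds by construction of referral_parent;
  ## degree sanity: a recruiter should report at least one contact
  if ("degree" %in% names(records)) {
    rec_deg <- records$degree[match(unique(edges$recruiter), records$pid)]
    if (any(!is.na(rec_deg) & rec_deg < 1))
      warning("recruiter(s) with reported degree < 1; they recruited, so degree is implausible",
              call. = FALSE)
  }
  structure(list(nodes = records, edges = edges,
                 roots = records$pid[is_seed]),
            class = "recruitment_forest")
}

#' @export
print.recruitment_forest <- function(x, ...) {
  cat(sprintf("Recruitment forest: %d participants, %d seeds, %d referral edges, max wave %d\n",
              nrow(x$nodes), length(x$roots), nrow(x$edges), max(x$nodes$wave)))
  invisible(x)
}

#' Group assignment (Markov-chain state) for a trait
#'
#' Builds the two-group partition `{user, non-user}` from a binary trait
#' column, or passes through a supplied factor. This is the state space of the
#' recruitment Markov chain.
#'
#' @param records participant data frame.
#' @param trait name of a 0/1 column (e.g. `"trait:ketamine:lifetime"`), or a
#'   factor/character vector of group labels aligned with `records`.
#' @return a factor of length `nrow(records)`, names set to pids. Binary
#'   traits get levels `c("user", "non-user")`.
#' @export
trait_partition <- function(records, trait) {
  if (length(trait) == 1L && is.character(trait)) {
    if (!trait %in% names(records))
      rds_stop("rds_schema_error", "trait column '%s' not found", trait)
    v <- records[[trait]]
    if (!all(v %in% c(0, 1)))
      rds_stop("rds_value_error", "trait column '%s' is not binary 0/1", trait)
    g <- factor(ifelse(v == 1, "user", "non-user"),
                levels = c("user", "non-user"))
  } else {
    if (length(trait) != nrow(records))
      rds_stop("rds_value_error", "partition length does not match records")
    g <- if (is.factor(trait)) trait else factor(trait)
  }
  if (anyNA(g))
    rds_stop("rds_value_error", "partition has missing group assignments")
  names(g) <- records$pid
  g
}

## Induced subforest on a subset of pids. Recruits whose recruiter falls
## outside the subset become pseudo-roots; original wave labels are kept.
## Used for stratified estimation.
subset_forest <- function(forest, pids) {
  keep <- forest$nodes$pid %in% pids
  nodes <- forest$nodes[keep, , drop = FALSE]
  e <- forest$edges
  e <- e[e$recruiter %in% nodes$pid & e$recruit %in% nodes$pid, , drop = FALSE]
  structure(list(nodes = nodes, edges = e,
                 roots = setdiff(nodes$pid, e$recruit)),
            class = "recruitment_forest")
}
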