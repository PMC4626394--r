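#' Read a participant file
#'
#' Participant files are UTF-8 delimited text (comma by default, tab
#' accepted) with one header line and no quoting. Mandatory columns: `pid`,
#' `code`, `degree`. Conventional columns: `year`, `seed_source`, `age`,
#' `sex`, `onset_stratum`, plus any number of binary trait columns named
#' `trait:<drug>:<window>` (e.g. `trait:ketamine:lifetime`). Unknown columns
#' are preserved verbatim, so write-then-read round-trips losslessly.
#'
#' Validation: trait columns must be 0/1; a recruiter (someone whose code is
#' the parent of another) with degree < 1 raises a warning and is flagged in
#' the returned frame's `degree_flagged` attribute, mirroring the estimator's
#' policy of excluding invalid degrees from weighting without dropping the
#' record.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @return a data frame of participant records (zero rows for a header-only
#'   file).
#' @seealso [write_participants()], [build_recruitment_forest()]
#' @export
read_participants <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    rds_stop("rds_schema_error", "file '%s' is empty (no header)", path)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  mandatory <- c("pid", "code", "degree")
  absent <- setdiff(mandatory, names(df))
  if (length(absent))
    rds_stop("rds_schema_error", "missing mandatory column(s): %s",
             paste(absent, collapse = ", "))
  df$pid <- as.character(df$pid)
  df$code <- as.character(df$code)
  for (tc in grep("^trait:", names(df), value = TRUE)) {
    if (!all(df[[tc]] %in% c(0L, 1L)))
      rds_stop("rds_value_error", "non-binary value in trait column '%s'", tc)
  }
  if (nrow(df)) {
    parents <- vapply(df$code, function(s) {
      p <- referral_parent(s); if (is.na(p)) "" else p
    }, "")
    is_recruiter <- df$code %in% parents
    flagged <- which(is_recruiter & (is.na(df$degree) | df$degree < 1))
    if (length(flagged)) {
      warning(sprintf("%d recruiter record(s) with degree < 1 (pids: %s); retained but excluded from degree weighting",
                      length(flagged),
                      paste(df$pid[flagged], collapse = ", ")), call. = FALSE)
      attr(df, "degree_flagged") <- df$pid[flagged]
    }
  }
  df
}

#' Write a participant file
#'
#' @param records participant data frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_participants <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an explicit recruiter-recruit edge list and cross-validate
#'
#' Edges are normally derived from referral codes; an explicit edge file
#' (columns `recruiter_pid`, `recruit_pid`) can be supplied and is checked
#' against the code-derived forest.
#'
#' @param path edge file path.
#' @param forest a `recruitment_forest` to validate against (optional).
#' @param sep separator, sniffed when `NULL`.
#' @return edge data frame.
#' @export
read_edges <- function(path, forest = NULL, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  e <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("recruiter_pid", "recruit_pid")
  if (!all(need %in% names(e)))
    rds_stop("rds_schema_error", "edge file needs columns %s",
             paste(need, collapse = ", "))
  if (!is.null(forest)) {
    a <- paste(e$recruiter_pid, e$recruit_pid, sep = "\r")
    b <- paste(forest$edges$recruiter, forest$edges$recruit, sep = "\r")
    if (!setequal(a, b))
      rds_stop("rds_structure_error",
               "edge file disagrees with referral codes (%d file-only, %d code-only edges)",
               length(setdiff(a, b)), length(setdiff(b, a)))
  }
  e
}

trait_col <- function(drug, window) sprintf("trait:%s:%s", drug, window)
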