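#' @keywords internal
"_PACKAGE"

## Classed conditions so callers (and tests) can distinguish failure modes.
rds_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "rdsprev_error")))
}

#' Parse a referral code
#'
#' Referral codes mark a participant's position in a recruitment chain: a
#' four-character seed label (one letter and three digits, e.g. `"F001"`)
#' followed by a dash and one digit per wave position. A seed carries all
#' zeros; each successive wave appends one nonzero digit (1-5, the recruit's
#' index among its recruiter's recruits), so `"F001-1100000000"` is a
#' second-wave recruit. The wave of a participant is the number of leading
#' nonzero digits.
#'
#' @param text a single code string, `"<label>-<digits>"`. The canonical
#'   width is 10 digit positions; longer digit fields are accepted for
#'   recruitment deeper than 10 waves.
#' @return an object of class `referral_code` with elements `seed_label`,
#'   `path` (integer vector of digit positions), `wave` and `width`.
#' @examples
#' parse_referral_code("F001-0000000000")$wave   # seed: 0
#' parse_referral_code("F001-1100000000")$wave   # second-wave recruit: 2
#' @seealso [format_referral_code()], [referral_parent()]
#' @export
parse_referral_code <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    rds_stop("rds_parse_error", "referral code must be a single string")
  dash <- regexpr("-", text, fixed = TRUE)
  if (dash != 5L)
    rds_stop("rds_parse_error",
             "malformed code '%s': expected '-' at position 5", text)
  label <- substr(text, 1L, 4L)
  if (!grepl("^[A-Za-z][0-9]{3}$", label))
    rds_stop("rds_parse_error",
             "malformed seed label '%s' (positions 1-4): need letter + 3 digits",
             label)
  digits <- substr(text, 6L, nchar(text))
  if (nchar(digits) < 10L)
    rds_stop("rds_parse_error",
             "malformed code '%s': fewer than 10 digit positions (position %d)",
             text, nchar(text) + 1L)
  bad <- regexpr("[^0-5]", digits)
  if (bad > 0L)
    rds_stop("rds_parse_error",
             "malformed code '%s': character '%s' at position %d is not a digit 0-5",
             text, substr(digits, bad, bad), 5L + bad)
  path <- as.integer(strsplit(digits, "", fixed = TRUE)[[1L]])
  nz <- which(path != 0L)
  if (length(nz) && any(diff(nz) != 1L) || (length(nz) && nz[1L] != 1L)) {
    first_zero <- which(path == 0L)[1L]
    rds_stop("rds_structure_error",
             "code '%s': nonzero digit after a zero at digit position %d (wave gaps are impossible)",
             text, first_zero)
  }
  structure(list(seed_label = toupper(label), path = path,
                 wave = length(nz), width = length(path)),
            class = "referral_code")
}

#' Format a referral code back to its string form
#'
#' Inverse of [parse_referral_code()]: `format_referral_code(parse_referral_code(x))`
#' returns `x` (label upper-cased).
#'
#' @param code a `referral_code` object.
#' @return a string.
#' @export
format_referral_code <- function(code) {
  stopifnot(inherits(code, "referral_code"))
  paste0(code$seed_label, "-", paste(code$path, collapse = ""))
}

#' @export
print.referral_code <- function(x, ...) {
  cat(sprintf("<referral code %s, wave %d>\n", format_referral_code(x), x$wave))
  invisible(x)
}

#' Parent code of a referral code
#'
#' Drops the last nonzero digit, yielding the recruiter's code. A seed has no
#' parent.
#'
#' @param code a `referral_code` object or code string.
#' @return a code string, or `NA_character_` for a seed.
#' @export
referral_parent <- function(code) {
  if (is.character(code)) code <- parse_referral_code(code)
  if (code$wave == 0L) return(NA_character_)
  path <- code$path
  path[code$wave] <- 0L
  paste0(code$seed_label, "-", paste(path, collapse = ""))
}

## Fast vectorized wave count for pre-validated code strings.
code_waves <- function(codes) {
  digits <- sub("^.....", "", codes)
  nchar(sub("0*$", "", digits))
}

make_code <- function(seed_label, path) {
  paste0(seed_label, "-", paste(path, collapse = ""))
}
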