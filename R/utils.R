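# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so library functions never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Midnight UTC at the start of a calendar date (Dates count days since
# 1970-01-01, so this is pure arithmetic).
as_utc_midnight <- function(date) {
  .POSIXct(as.numeric(as.Date(date)) * 86400, tz = "UTC")
}

#' Parse event timestamps
#'
#' Accepts POSIXct, Date, or character input. Character values may carry a
#' time component ("YYYY-MM-DD HH:MM:SS", "T" separator accepted); date-only
#' values are taken to span the whole day: a start becomes 00:00 and an end
#' becomes 24:00 of that date, reflecting de-identified EMR extracts that
#' often lack times.
#'
#' @param x timestamp vector.
#' @param role "start" or "end"; controls date-only semantics.
#' @return POSIXct vector (UTC); unparseable non-empty values raise an error.
#' @keywords internal
parse_event_time <- function(x, role = c("start", "end")) {
  role <- match.arg(role)
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) {
    out <- as_utc_midnight(x)
    if (role == "end") out <- out + 86400
    return(out)
  }
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  blank <- is.na(x) | !nzchar(x)
  timed <- !blank & grepl(":", x, fixed = TRUE)
  if (any(timed)) {
    out[timed] <- as.POSIXct(sub("T", " ", x[timed], fixed = TRUE),
                             tz = "UTC")
  }
  dateonly <- !blank & !timed
  if (any(dateonly)) {
    d <- as.Date(x[dateonly], format = "%Y-%m-%d")
    out[dateonly] <- as_utc_midnight(d) + if (role == "end") 86400 else 0
  }
  bad <- !blank & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  out
}

# Completed age in whole days at a timestamp or date, given the birth date.
age_in_days <- function(birth_date, at) {
  if (inherits(at, "POSIXct")) {
    floor((as.numeric(at) - as.numeric(as.Date(birth_date)) * 86400) / 86400)
  } else {
    as.numeric(as.Date(at)) - as.numeric(as.Date(birth_date))
  }
}

# Parse a date column, raising an error that names the table and offending
# rows when a non-empty value does not parse.
parse_date_col <- function(x, table, column) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  blank <- is.na(x) | !nzchar(x)
  out <- as.Date(rep(NA_character_, length(x)))
  out[!blank] <- as.Date(x[!blank], format = "%Y-%m-%d")
  bad <- which(!blank & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s in row(s) %s", table, column,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Small deterministic string hash (djb2 variant) used for config fingerprints
# in run metadata; not cryptographic.
djb2_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (v in utf8ToInt(x)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
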