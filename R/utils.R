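#' @keywords internal
"_PACKAGE"

MS_PER_DAY <- 86400000
MS_PER_HOUR <- 3600000

## Key-category levels used across the package. No text content is ever stored.
KEY_CATEGORIES <- c("alphanumeric", "backspace", "punctuation", "space",
                    "autocorrection", "suggestion", "other")

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Calendar day number of an epoch-millisecond timestamp
#'
#' Days since 1970-01-01 in the given timezone. All "same date" rules in the
#' window-assignment algorithm use this convention; the timezone is a
#' per-dataset setting (single zone, no DST handling is attempted for
#' generated data).
#'
#' @param ts_ms numeric vector, milliseconds since epoch (UTC).
#' @param tz timezone string, default "UTC".
#' @return integer-valued numeric vector of day numbers.
#' @keywords internal
day_number <- function(ts_ms, tz = "UTC") {
  if (identical(tz, "UTC")) {
    floor(ts_ms / MS_PER_DAY)
  } else {
    lt <- as.POSIXlt(ts_ms / 1000, origin = "1970-01-01", tz = tz)
    as.numeric(as.Date(lt))
  }
}

#' Epoch milliseconds at local midnight starting a given day number
#' @keywords internal
day_start_ms <- function(day, tz = "UTC") {
  if (identical(tz, "UTC")) {
    day * MS_PER_DAY
  } else {
    as.numeric(as.POSIXct(as.character(as.Date(day, origin = "1970-01-01")),
                          tz = tz)) * 1000
  }
}

## mean/sd z-scoring with a guard for constant columns
z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    warning("z-scoring a constant column; returning zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Merge user options into defaults, rejecting unknown keys.
merge_options <- function(defaults, user, where = "options") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_validation("%s must be a list", where)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop_validation("unknown %s key(s): %s", where,
                    paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}
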