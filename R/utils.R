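# Internal helpers shared across modules.

PHASES <- c("post_surgery", "chemotherapy")
DIMENSIONS <- c("occurrence", "frequency", "distress")
SEVERITIES <- c("red", "yellow")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half up
#'
#' Commercial ("half up") rounding at a fixed number of decimals. Base R's
#' `round()` uses round-half-even, which disagrees with how clinical
#' percentages are conventionally printed (e.g. 13.655 -> 13.7, not 13.6).
#'
#' @param x numeric vector.
#' @param digits non-negative integer number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(13.655, 1)  # 13.7
#' round_half_up(0.5, 0)     # 1
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly *.5 after the
  # decimal shift (up to binary representation error) round upward
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# FNV-1a 32-bit hash of a string, returned as 8 hex chars. Used for
# deterministic, reproducible alert identifiers; not cryptographic.
fnv1a32 <- function(s) {
  vapply(s, function(one) {
    bytes <- utf8ToInt(enc2utf8(one))
    h <- 2166136261
    for (b in bytes) {
      # xor only touches the low byte (b < 256); keeps h a double-safe value
      h <- h - (h %% 256) + bitwXor(h %% 256, b)
      # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
      # split so each intermediate stays exactly representable in a double
      h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out) && !all(is.na(x))) {
    bad <- x[is.na(suppressWarnings(as.Date(x)))]
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  out
}

as_time_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate_free_utc(x))
  if (is.character(x))  # accept ISO-8601 "2020-01-02T08:00:00Z" as well
    x <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  as.POSIXct(x, tz = "UTC")
}

lubridate_free_utc <- function(x) {
  attr(x, "tzone") <- "UTC"
  x
}

# seconds since local midnight for a POSIXct (in its own tz)
secs_of_day <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

hm_to_secs <- function(hm) {
  parts <- strsplit(hm, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("time of day must be 'HH:MM'", call. = FALSE)
  as.integer(parts[1]) * 3600 + as.integer(parts[2]) * 60
}

# deterministic 31-bit substream seed derived from a master seed and an index
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
}
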