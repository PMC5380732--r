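# internal helpers: clock arithmetic and scoped RNG

# Parse ISO 8601-ish local timestamps into POSIXct anchored in UTC.
# UTC is used as a fixed "local clock" so no DST shift can ever occur;
# only the clock face matters for circadian phase.
parse_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    stop("unparsable timestamp(s): ", paste(head(x[is.na(out)], 3), collapse = ", "))
  }
  out
}

format_time <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# decimal clock hour in [0, 24) of a POSIXct
clock_hour <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# midnight preceding t (same local day)
midnight_of <- function(t) {
  as.POSIXct(trunc(as.POSIXlt(t, tz = "UTC"), "days"), tz = "UTC")
}

# circular mean of clock hours, result in [0, 24)
circ_mean_clock <- function(hours) {
  hours <- hours[!is.na(hours)]
  if (!length(hours)) return(NA_real_)
  ang <- hours * pi / 12
  m <- atan2(mean(sin(ang)), mean(cos(ang))) * 12 / pi
  m %% 24
}

#' Signed circular difference between two clock hours
#'
#' Maps `b - a` onto `(-12, +12]` hours, so a phase just after midnight
#' minus one just before midnight is a small positive delay.
#'
#' @param a,b clock hours in `[0, 24)` (vectors recycle).
#' @return signed difference in hours, in `(-12, 12]`.
#' @examples
#' clock_diff(23.5, 0.5)  # +1: wraps midnight
#' @export
clock_diff <- function(a, b) {
  d <- (b - a) %% 24
  ifelse(d > 12, d - 24, d)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (NULL = use the ambient stream untouched).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# sub-seeds derived from a master seed, each < 2^31
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
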