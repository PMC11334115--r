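#' Derive a reproducible substream seed from a global seed
#'
#' One global seed fans out to named per-component substreams, so adding a
#' new generator never shifts the draws of an existing one.
#'
#' @param seed Integer global seed.
#' @param name Character name of the component stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 1000003 + h) %% 2147483646)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local calendar day of a timestamp
#'
#' Day boundaries are drawn on a configurable local civil clock, expressed
#' as a fixed offset from UTC in hours.
#'
#' @param time POSIXct vector (UTC).
#' @param utc_offset Offset in hours added before truncating to days.
#' @return Date vector.
#' @export
local_date <- function(time, utc_offset = 0) {
  as.Date(time + utc_offset * 3600, tz = "UTC")
}

assert_hourly <- function(time, what = "series") {
  if (length(time) < 2L) stop(what, ": need at least two timestamps")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) stop(what, ": timestamps must be strictly increasing")
  if (any(abs(dt - 3600) > 1e-6)) stop(what, ": timestamps must be equally spaced hourly")
  invisible(TRUE)
}
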