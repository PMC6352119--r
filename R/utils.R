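#' @keywords internal
"_PACKAGE"

# Indices of strict-ish local maxima: x[i] > x[i-1] and x[i] >= x[i+1].
# Plateau starts count once; endpoints are never extrema.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

local_minima <- function(x) local_maxima(-x)

# First element of idx strictly greater than t, or NA
first_after <- function(idx, t) {
  idx <- idx[idx > t]
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

# Alternating extrema with a minimum vertical excursion ("zigzag" filter):
# walks the raw local extrema of x over [from, to) and keeps an extremum only
# if it differs from the last kept one by at least delta; a same-type, more
# extreme point replaces the last kept one. Suppresses sub-noise wiggles
# while preserving genuine small waves.
zigzag_extrema <- function(x, from, to, delta) {
  mx <- local_maxima(x); mn <- local_minima(x)
  idx <- sort(c(mx, mn))
  idx <- idx[idx >= from & idx < to]
  if (length(idx) == 0L)
    return(data.frame(i = integer(0), type = character(0)))
  type <- ifelse(idx %in% mx, "max", "min")
  ki <- integer(0); kt <- character(0)
  for (j in seq_along(idx)) {
    i <- idx[j]; ty <- type[j]
    if (length(ki) == 0L) { ki <- i; kt <- ty; next }
    last <- length(ki)
    if (ty == kt[last]) {
      better <- if (ty == "max") x[i] > x[ki[last]] else x[i] < x[ki[last]]
      if (better) ki[last] <- i
    } else if (abs(x[i] - x[ki[last]]) >= delta) {
      ki <- c(ki, i); kt <- c(kt, ty)
    }
  }
  data.frame(i = ki, type = kt, stringsAsFactors = FALSE)
}

trapz <- function(y, dx = 1) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * sum((y[-1L] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ppght <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
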