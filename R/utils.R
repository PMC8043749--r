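# internal numeric helpers shared across modules

#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Centered rolling mean with shrink-to-available edges.
# For even windows the window extends one frame further into the past
# (left = floor(w/2), right = w - 1 - left).
#' @noRd
.roll_mean <- function(x, window) {
  n <- length(x)
  left <- floor(window / 2)
  right <- window - 1L - left
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered rolling standard deviation (denominator n-1), shrink-to-available
# edges; windows of size 1 give sd 0.  x is centered globally first so the
# cumulative sums stay small relative to the tiny variances we threshold on.
#' @noRd
.roll_sd <- function(x, window) {
  n <- length(x)
  xc <- x - mean(x)
  left <- floor(window / 2)
  right <- window - 1L - left
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc * xc))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s * s / m) / pmax(m - 1L, 1L)
  v[m < 2L] <- 0
  sqrt(pmax(v, 0))
}

# Maximal runs of TRUE in a logical vector as half-open [start, end) 0-based
# frame intervals.
#' @noRd
.runs_of <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' @noRd
.ols_slope <- function(y, x) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}
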