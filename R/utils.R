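#' @keywords internal
"_PACKAGE"

## Small numeric helpers shared across the signal-processing code.

#' Centred moving-average smoother
#'
#' Endpoints that the filter cannot cover keep their original values, so a
#' constant segment stays exactly constant after smoothing.
#'
#' @param x numeric vector.
#' @param n window width in samples (`n <= 1` returns `x` unchanged).
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
smooth_ma <- function(x, n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L      # odd width keeps the filter centred
  if (n <= 1L || length(x) < n) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  na <- is.na(y)
  y[na] <- x[na]
  y
}

#' Trapezoidal integral of y over t
#' @keywords internal
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Local maxima with a topographic-prominence floor
#'
#' Prominence of a peak is its height above the higher of the two minima
#' separating it from higher ground (or from the segment boundary).
#'
#' @param x numeric vector.
#' @param min_prominence minimal prominence for a peak to be reported.
#' @return integer indices of retained peaks.
#' @keywords internal
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    (x[i] - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Stop unless a condition holds, with a formatted message
#' @keywords internal
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
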