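# Continuous power-law tail fit for srd distributions.
#
# Above a lower cutoff xmin the tail density is
#   f(x) = (alpha - 1)/xmin * (x/xmin)^(-alpha),   x >= xmin, alpha > 1,
# with complementary CDF P(X >= x) = (x/xmin)^(1 - alpha). alpha is
# estimated by maximum likelihood (alpha = 1 + m / sum(log(x_i/xmin)) over
# the m tail points) and xmin by scanning candidate cutoffs and keeping the
# one minimising the Kolmogorov-Smirnov distance between the tail's
# empirical CDF and the fitted model (the Clauset procedure).

#' Fit a power-law tail to a sample of scores
#'
#' @param x Numeric vector of scores; non-finite and non-positive values
#'   are ignored (they lie below any admissible cutoff).
#' @param min_tail Minimum number of points that must lie at or above the
#'   chosen cutoff (default 10).
#' @param max_candidates Cap on the number of candidate cutoffs scanned;
#'   when the data have more distinct values, an evenly spaced subset of
#'   the sorted unique values is used (a grid in rank space).
#' @return An object of class `srd_plfit` with elements `alpha`, `xmin`,
#'   `ks_distance`, `n_tail`, `n`.
#' @seealso [predict.srd_plfit()] for tail significance, [rpowerlaw()] for
#'   sampling.
#' @export
fit_power_law <- function(x, min_tail = 10, max_candidates = 200) {
  x <- x[is.finite(x) & x > 0]
  n <- length(x)
  if (n < min_tail) stopf("too few positive values (%d) for a tail fit", n)
  x <- sort(x)
  if (x[1L] == x[n]) stopf("degenerate data: all values equal")
  cand <- unique(x)
  # keep cutoffs leaving at least min_tail points in the tail
  cand <- cand[cand <= x[n - min_tail + 1L]]
  if (length(cand) == 0L) stopf("no cutoff leaves %d tail points", min_tail)
  if (length(cand) > max_candidates) {
    keep <- unique(round(seq(1L, length(cand), length.out = max_candidates)))
    cand <- cand[keep]
  }
  logx <- log(x)
  clog <- c(0, cumsum(logx))
  best <- NULL
  for (u in cand) {
    i <- findInterval(u, x, left.open = TRUE) + 1L  # first index with x >= u
    m <- n - i + 1L
    slog <- (clog[n + 1L] - clog[i]) - m * log(u)
    if (slog <= 0) next  # all tail values equal to the cutoff
    alpha <- 1 + m / slog
    tail <- x[i:n]
    fhat <- 1 - (tail / u)^(1 - alpha)
    ks <- max(pmax(abs(fhat - (seq_len(m) - 1) / m),
                   abs(fhat - seq_len(m) / m)))
    if (is.null(best) || ks < best$ks_distance) {
      best <- list(alpha = alpha, xmin = u, ks_distance = ks, n_tail = m,
                   n = n)
    }
  }
  if (is.null(best)) stopf("degenerate data: no admissible power-law cutoff")
  structure(best, class = "srd_plfit")
}

#' Draw from a continuous power law
#'
#' Inverse-CDF sampling from the density `(alpha-1)/xmin (x/xmin)^-alpha`.
#'
#' @param n Number of draws.
#' @param alpha Tail exponent (> 1).
#' @param xmin Lower cutoff (> 0).
#' @export
rpowerlaw <- function(n, alpha, xmin = 1) {
  stopifnot(alpha > 1, xmin > 0)
  xmin * (1 - stats::runif(n))^(-1 / (alpha - 1))
}

#' Tail significance of scores under a fitted power law
#'
#' The significance of a score is the fitted tail's complementary CDF,
#' `p = (x/xmin)^(1-alpha)` for `x >= xmin`; scores below the cutoff are
#' not in the modelled tail and get `p = 1`.
#'
#' @param object An `srd_plfit`.
#' @param newdata Numeric vector of scores.
#' @param ... Unused.
#' @return Numeric vector of tail probabilities in (0, 1]; `NA` in,
#'   `NA` out.
#' @export
predict.srd_plfit <- function(object, newdata, ...) {
  p <- rep(1, length(newdata))
  hi <- !is.na(newdata) & newdata >= object$xmin
  p[hi] <- (newdata[hi] / object$xmin)^(1 - object$alpha)
  p[is.na(newdata)] <- NA_real_
  p
}

#' @export
coef.srd_plfit <- function(object, ...) {
  c(alpha = object$alpha, xmin = object$xmin)
}

#' @export
print.srd_plfit <- function(x, ...) {
  cat("Power-law tail fit\n")
  cat(sprintf("  alpha = %.4f, xmin = %.4g\n", x$alpha, x$xmin))
  cat(sprintf("  tail: %d of %d points; KS distance %.4f\n",
              x$n_tail, x$n, x$ks_distance))
  invisible(x)
}

#' Log-log CCDF of the data with the fitted tail overlaid
#'
#' @param x An `srd_plfit`.
#' @param data The scores the fit was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.srd_plfit <- function(x, data, ...) {
  d <- sort(data[is.finite(data) & data > 0])
  ccdf <- rev(seq_along(d)) / length(d)
  graphics::plot(d, ccdf, log = "xy", pch = 20, cex = 0.4,
                 xlab = "srd", ylab = "P(X >= x)", ...)
  tail_frac <- x$n_tail / x$n
  curve_x <- exp(seq(log(x$xmin), log(max(d)), length.out = 100))
  graphics::lines(curve_x, tail_frac * (curve_x / x$xmin)^(1 - x$alpha),
                  col = "red3", lwd = 2)
  graphics::abline(v = x$xmin, lty = 3, col = "grey40")
  invisible(x)
}
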