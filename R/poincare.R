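#' Build Poincare pairs from a heart-rate series
#'
#' The Poincare (lag-1 return) map plots each heart-rate value against the
#' next one on the uniform grid. A pair is formed for every adjacent index
#' `(i, i+1)` where both samples are valid; pairs are never formed across a
#' filtered (invalid) sample, so an excluded ectopic cannot re-enter the
#' analysis through its neighbours. Each pair is stamped with the time of
#' its later member.
#'
#' @param series A uniformly sampled [hr_series()].
#' @return An object of class `poincare_pairs` with fields `x`, `y` (bpm)
#'   and `pair_times` (seconds).
#' @seealso [sd_descriptors()]
#' @export
#' @examples
#' make_pairs(hr_series(c(60, 61, 62)))
make_pairs <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  p <- pairs_of(series)
  if (length(p$x) == 0) {
    hrv_insufficient("no adjacent pair of valid samples to form Poincare pairs")
  }
  p
}

# Internal pair extraction that tolerates zero pairs (streaming windows may
# legitimately be empty).
pairs_of <- function(series) {
  v <- series$values
  n <- length(v)
  if (n < 2) {
    return(structure(list(x = numeric(0), y = numeric(0),
                          pair_times = numeric(0)),
                     class = "poincare_pairs"))
  }
  ok <- series$valid[-n] & series$valid[-1]
  i <- which(ok)
  t <- hr_times(series)
  structure(list(x = v[i], y = v[i + 1L], pair_times = t[i + 1L]),
            class = "poincare_pairs")
}

#' @export
print.poincare_pairs <- function(x, ...) {
  cat(sprintf("<poincare_pairs> %d pairs\n", length(x$x)))
  invisible(x)
}

#' Poincare ellipse descriptors SD1/SD2
#'
#' Fits the standard ellipse to the Poincare cloud: with differences
#' `d_i = x_i - y_i` and sums `s_i = x_i + y_i`,
#' `SD1 = sqrt(Var(d) / 2)` is the dispersion perpendicular to the line of
#' identity (short-term, beat-to-beat variability) and
#' `SD2 = sqrt(Var(s) / 2)` the dispersion along it (longer-term
#' variability). `Var` is the unbiased sample variance (denominator
#' `n_pairs - 1`). Equivalently, SD1 and SD2 are the standard deviations of
#' the cloud after a 45 degree rotation.
#'
#' The SD1/SD2 ratio is reported when `SD2 > 0` and is `NA` otherwise
#' (a degenerate cloud lying exactly on the identity line).
#'
#' @param pairs A [make_pairs()] result with at least 2 pairs.
#' @return An object of class `poincare_descriptors` with fields `sd1`,
#'   `sd2`, `ratio`, `centroid_x`, `centroid_y`, `n_pairs`.
#' @export
#' @examples
#' sd_descriptors(make_pairs(hr_series(c(60, 61, 62, 63, 64))))
sd_descriptors <- function(pairs) {
  stopifnot(inherits(pairs, "poincare_pairs"))
  n <- length(pairs$x)
  if (n < 2) hrv_insufficient("need at least 2 Poincare pairs for SD1/SD2")
  d <- pairs$x - pairs$y
  s <- pairs$x + pairs$y
  sd1 <- sqrt(stats::var(d) / 2)
  sd2 <- sqrt(stats::var(s) / 2)
  structure(
    list(sd1 = sd1, sd2 = sd2,
         ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
         centroid_x = mean(pairs$x), centroid_y = mean(pairs$y),
         n_pairs = n),
    class = "poincare_descriptors"
  )
}

#' @export
print.poincare_descriptors <- function(x, ...) {
  cat(sprintf("<poincare_descriptors> n_pairs = %d\n", x$n_pairs))
  cat(sprintf("  SD1 = %.4f bpm   SD2 = %.4f bpm   SD1/SD2 = %s\n",
              x$sd1, x$sd2,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio)))
  cat(sprintf("  centroid = (%.2f, %.2f) bpm\n", x$centroid_x, x$centroid_y))
  invisible(x)
}

#' Geometry of the fitted Poincare ellipse
#'
#' Converts descriptors to plotting geometry: the ellipse is centered on
#' the cloud centroid, its semi-axis along the line of identity has length
#' SD2, the perpendicular semi-axis has length SD1, and its orientation is
#' fixed at 45 degrees to the x-axis.
#'
#' @param desc A [sd_descriptors()] result.
#' @return A list with `center` (length-2, bpm), `semi_axes` (named:
#'   `along_identity` = SD2, `perpendicular` = SD1) and `orientation_deg`
#'   (always 45).
#' @export
ellipse_geometry <- function(desc) {
  stopifnot(inherits(desc, "poincare_descriptors"))
  list(center = c(x = desc$centroid_x, y = desc$centroid_y),
       semi_axes = c(along_identity = desc$sd2, perpendicular = desc$sd1),
       orientation_deg = 45)
}

#' @description Scatter plot of the Poincare cloud with the fitted ellipse
#'   and the line of identity.
#' @param x A `poincare_pairs` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @rdname make_pairs
#' @export
plot.poincare_pairs <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "HR(t) [bpm]", ylab = "HR(t+1) [bpm]",
                 asp = 1, pch = 16, col = "#00000055", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  if (length(x$x) >= 2) {
    g <- ellipse_geometry(sd_descriptors(x))
    th <- seq(0, 2 * pi, length.out = 181)
    u <- g$semi_axes[["along_identity"]] * cos(th)
    w <- g$semi_axes[["perpendicular"]] * sin(th)
    r <- sqrt(2) / 2
    graphics::lines(g$center[["x"]] + r * (u - w),
                    g$center[["y"]] + r * (u + w), col = "red", lwd = 2)
  }
  invisible(x)
}
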