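#' Negative-derivative melt trace
#'
#' Converts a raw fluorescence trace to the smoothed negative derivative
#' -dF/dT on the same temperature grid. A linear background is first fitted
#' to the post-melt plateau (the last `baseline_frac` of grid points, the
#' flattest region of the trace once every duplex has melted) and subtracted,
#' so the corrected fluorescence decays to zero and the derivative returns to
#' zero on both plateaus - which keeps melt-peak areas meaningful for
#' heteroplasmy estimation. The corrected trace is smoothed with a
#' Savitzky-Golay filter and differentiated with a second Savitzky-Golay
#' pass; both passes fit local polynomials, so endpoints are estimated by
#' polynomial extrapolation rather than truncation.
#'
#' The default windows (3.1 and 2.1 degrees at a 0.1-degree grid) are matched
#' to the width of a probe melt peak (FWHM about 1.8 degrees at the default
#' transition slope) and are well below the smallest calibrated peak spacing
#' of the shipped panel (4.26 degrees), so true peaks are never merged while
#' point noise is strongly attenuated.
#'
#' The trace's raw noise level is estimated robustly (median absolute
#' deviation of first differences) and propagated through the exact combined
#' filter gain; the result is stored as `noise_sd` on the returned object and
#' used by [detect_peaks()] as a detection floor.
#'
#' @param curve A [melt_curve()].
#' @param smooth_window Savitzky-Golay window of the differentiation pass, in
#'   points; odd, greater than `poly_order`, shorter than the trace.
#' @param poly_order Polynomial order of the differentiation pass.
#' @param presmooth_window Window of the preceding smoothing pass; `0`
#'   disables it.
#' @param presmooth_order Polynomial order of the smoothing pass.
#' @param baseline_frac Fraction of points in the post-melt plateau used for
#'   the baseline fit.
#' @param remove_baseline Subtract the fitted linear background first.
#' @return A list of class `deriv_curve` with `temperature`, `d` (-dF/dT),
#'   `temp_step`, and `noise_sd` (estimated noise standard deviation of `d`).
#' @export
derivative_curve <- function(curve, smooth_window = 21, poly_order = 2,
                             presmooth_window = 31, presmooth_order = 3,
                             baseline_frac = 0.10, remove_baseline = TRUE) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temperature)
  if (smooth_window %% 2 != 1 || smooth_window <= poly_order ||
      smooth_window >= n) {
    stop("smooth_window must be odd, > poly_order and < trace length",
         call. = FALSE)
  }
  if (presmooth_window > 0 &&
      (presmooth_window %% 2 != 1 || presmooth_window <= presmooth_order ||
       presmooth_window >= n)) {
    stop("presmooth_window must be 0 or odd, > presmooth_order and < trace length",
         call. = FALSE)
  }
  temps <- curve$temperature
  f <- curve$fluorescence
  step <- stats::median(diff(temps))
  # robust point-noise estimate from first differences of the raw trace
  sigma_f <- stats::mad(diff(f)) / sqrt(2)
  if (remove_baseline) {
    k <- max(2L, floor(n * baseline_frac))
    idx <- seq(n - k + 1L, n)
    fit <- stats::lm.fit(cbind(1, temps[idx]), f[idx])
    f <- f - (fit$coefficients[1] + fit$coefficients[2] * temps)
  }
  apply_filters <- function(x) {
    if (presmooth_window > 0) {
      x <- signal::sgolayfilt(x, p = presmooth_order, n = presmooth_window)
    }
    -signal::sgolayfilt(x, p = poly_order, n = smooth_window, m = 1, ts = step)
  }
  d <- apply_filters(f)
  # exact white-noise gain of the combined filter (interior response)
  m <- 4L * max(smooth_window, presmooth_window, 25L) + 1L
  imp <- numeric(m); imp[(m + 1L) %/% 2L] <- 1
  gain <- sqrt(sum(apply_filters(imp)^2))
  structure(list(temperature = temps, d = as.numeric(d), temp_step = step,
                 noise_sd = sigma_f * gain,
                 f_scale = max(diff(range(curve$fluorescence)),
                               max(abs(curve$fluorescence)),
                               .Machine$double.eps)),
            class = "deriv_curve")
}

# Topographic prominence of local maxima: height above the higher of the two
# valley floors separating the peak from the nearest higher terrain (or the
# trace boundary).
peak_prominence <- function(d, peaks) {
  vapply(peaks, function(p) {
    h <- d[p]
    left <- d[seq_len(p)]
    higher_l <- which(left > h)
    lmin <- min(left[seq(if (length(higher_l)) max(higher_l) else 1L, p)])
    right <- d[seq(p, length(d))]
    higher_r <- which(right > h)
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect melt peaks in a derivative trace
#'
#' Local maxima of -dF/dT with topographic prominence of at least
#' `min_prominence_frac` times the global maximum AND at least `min_snr`
#' times the trace's estimated derivative noise level, thinned so surviving
#' peaks are at least `min_separation` degrees apart (the higher of a
#' violating pair is kept; ties break toward lower temperature). Peak area is
#' the trapezoidal integral of -dF/dT between the flanking minima (the lowest
#' point between adjacent kept peaks, or the trace boundary).
#'
#' Both thresholds scale with the data - the prominence floor with the global
#' maximum, the noise floor with the robustly estimated point noise - so
#' detection is invariant to affine transforms of the fluorescence, and the
#' noise floor vanishes for noise-free traces.
#'
#' @param deriv A `deriv_curve` from [derivative_curve()].
#' @param min_prominence_frac Fraction of the global maximum below which a
#'   local maximum is discarded; in (0, 1).
#' @param min_separation Minimum spacing between reported peaks, degrees
#'   Celsius.
#' @param min_snr Minimum ratio of prominence to the estimated derivative
#'   noise standard deviation.
#' @return A data frame of class `melt_peaks`, sorted by `tm` ascending, with
#'   columns `tm`, `height`, `prominence`, `area`, `index`, `at_boundary`.
#'   Zero rows for a flat or peakless trace.
#' @export
detect_peaks <- function(deriv, min_prominence_frac = 0.10,
                         min_separation = 1.5, min_snr = 8) {
  stopifnot(inherits(deriv, "deriv_curve"),
            min_prominence_frac > 0, min_prominence_frac < 1)
  d <- deriv$d
  n <- length(d)
  empty <- data.frame(tm = numeric(), height = numeric(),
                      prominence = numeric(), area = numeric(),
                      index = integer(), at_boundary = logical())
  class(empty) <- c("melt_peaks", "data.frame")
  # numerically flat traces (relative to the raw fluorescence scale) have no
  # peaks; the threshold scales with the data, preserving affine invariance
  flat_tol <- 1e-9 * (deriv$f_scale %||% 0) / deriv$temp_step
  if (n < 3 || diff(range(d)) <= flat_tol || max(d) <= 0) return(empty)
  is_max <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (!length(is_max)) return(empty)
  prom <- peak_prominence(d, is_max)
  noise_sd <- deriv$noise_sd %||% 0
  floor_abs <- max(min_prominence_frac * max(d), min_snr * noise_sd)
  keep <- prom >= floor_abs & d[is_max] > 0
  cand <- is_max[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  # greedy thinning: strongest first; ties toward lower temperature
  ord <- order(-d[cand], deriv$temperature[cand])
  kept <- integer()
  for (i in ord) {
    if (!length(kept) ||
        all(abs(deriv$temperature[cand[i]] - deriv$temperature[kept]) >=
            min_separation)) {
      kept <- c(kept, cand[i])
    }
  }
  sel <- sort(match(kept, cand))
  cand <- cand[sel]
  prom <- prom[sel]
  # flanking minima: lowest point between adjacent kept peaks / boundaries
  bounds <- c(1L, vapply(seq_len(length(cand) - 1), function(i) {
    seg <- seq(cand[i], cand[i + 1])
    seg[which.min(d[seg])]
  }, integer(1)), n)
  area <- vapply(seq_along(cand), function(i) {
    seg <- seq(bounds[i], bounds[i + 1])
    sum(diff(deriv$temperature[seg]) * (d[seg][-1] + d[seg][-length(seg)]) / 2)
  }, numeric(1))
  out <- data.frame(tm = deriv$temperature[cand], height = d[cand],
                    prominence = prom, area = area, index = cand,
                    at_boundary = cand <= 1L | cand >= n)
  out <- out[order(out$tm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("melt_peaks", "data.frame")
  out
}

#' Refine a peak's melting temperature by parabolic interpolation
#'
#' Fits a parabola through the discrete maximum and its two neighbours and
#' returns the abscissa of its apex; the refinement never moves the estimate
#' by more than one grid step. A peak sitting on the grid boundary cannot be
#' refined and is returned unchanged with `refined = FALSE`.
#'
#' @param deriv The `deriv_curve` the peak was detected on.
#' @param peak One row of the [detect_peaks()] result (or a list with
#'   `index`).
#' @return A list with `tm` (degrees Celsius) and logical `refined`.
#' @export
refine_tm <- function(deriv, peak) {
  stopifnot(inherits(deriv, "deriv_curve"))
  i <- peak$index
  n <- length(deriv$d)
  if (i <= 1L || i >= n) {
    return(list(tm = deriv$temperature[i], refined = FALSE))
  }
  y1 <- deriv$d[i - 1]; y2 <- deriv$d[i]; y3 <- deriv$d[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(tm = deriv$temperature[i], refined = FALSE))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 1), -1)
  list(tm = deriv$temperature[i] + delta * deriv$temp_step, refined = TRUE)
}

#' Full peak pipeline for one curve
#'
#' Convenience wrapper: [derivative_curve()], [detect_peaks()], then
#' [refine_tm()] on every peak.
#'
#' @param curve A [melt_curve()].
#' @param smooth_window,poly_order,presmooth_window,presmooth_order,baseline_frac,remove_baseline
#'   Passed to [derivative_curve()].
#' @param min_prominence_frac,min_separation,min_snr Passed to
#'   [detect_peaks()].
#' @return A `melt_peaks` data frame whose `tm` column holds refined values;
#'   `tm_discrete` keeps the grid value and `refined` the flag.
#' @export
find_melt_peaks <- function(curve, smooth_window = 21, poly_order = 2,
                            presmooth_window = 31, presmooth_order = 3,
                            baseline_frac = 0.10, remove_baseline = TRUE,
                            min_prominence_frac = 0.10, min_separation = 1.5,
                            min_snr = 8) {
  deriv <- derivative_curve(curve, smooth_window, poly_order,
                            presmooth_window, presmooth_order,
                            baseline_frac, remove_baseline)
  pk <- detect_peaks(deriv, min_prominence_frac, min_separation, min_snr)
  if (!nrow(pk)) {
    pk$tm_discrete <- numeric()
    pk$refined <- logical()
    return(pk)
  }
  ref <- lapply(seq_len(nrow(pk)), function(i) refine_tm(deriv, pk[i, ]))
  pk$tm_discrete <- pk$tm
  pk$tm <- vapply(ref, `[[`, numeric(1), "tm")
  pk$refined <- vapply(ref, `[[`, logical(1), "refined")
  pk
}
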