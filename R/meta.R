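#' Random-effects meta-analysis of carrier proportions
#'
#' Pools per-study carrier proportions with the DerSimonian-Laird
#' moment estimator. Per study `i` with `x_i` carriers out of `n_i`, the
#' effect and its variance are computed on the chosen scale:
#' \describe{
#'   \item{none}{`p = x/n`, `v = p(1-p)/n`;}
#'   \item{logit}{`theta = log(p/(1-p))`, `v = 1/x + 1/(n-x)`, with a 0.5
#'     continuity correction added to both cells when `x` is 0 or `n`
#'     (default scale);}
#'   \item{double_arcsine}{Freeman-Tukey
#'     `theta = (asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))) / 2`,
#'     `v = 1/(4n+2)`, back-transformed by Miller's formula using the
#'     harmonic mean of the `n_i`.}
#' }
#' With fixed-effect weights `w_i = 1/v_i`:
#' `Q = sum w_i (theta_i - theta_fixed)^2`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`,
#' random-effects weights `w*_i = 1/(v_i + tau^2)`, pooled estimate
#' `sum w* theta / sum w*` with standard error `sqrt(1 / sum w*)`, and
#' `I^2 = max(0, (Q - (k-1)) / Q) * 100`. A single study pools to its own
#' proportion with `tau^2 = Q = I^2 = 0`.
#'
#' @param studies Data frame with columns `study_label` (optional),
#'   `carriers`, `n_screened`.
#' @param transform `"logit"` (default), `"none"`, or `"double_arcsine"`.
#' @param conf_level Confidence level of the pooled interval.
#' @return A list of class `meta_result`: `pooled` (proportion), `ci_lower`,
#'   `ci_upper`, `tau_squared`, `Q`, `df`, `I_squared` (percent), `k`,
#'   `transform`, and `weights` (random-effects weights, summing to 1, in
#'   study order).
#' @export
meta_random_effects <- function(studies, transform = c("logit", "none", "double_arcsine"),
                                conf_level = 0.95) {
  transform <- match.arg(transform)
  studies <- as.data.frame(studies)
  if (!all(c("carriers", "n_screened") %in% names(studies))) {
    stop("studies must have columns 'carriers' and 'n_screened'", call. = FALSE)
  }
  k <- nrow(studies)
  if (k == 0) stop("meta-analysis requires at least one study", call. = FALSE)
  x <- studies$carriers
  n <- studies$n_screened
  if (any(n <= 0)) stop("every study needs n_screened > 0", call. = FALSE)
  if (any(x < 0 | x > n)) {
    stop("carriers must lie in [0, n_screened]", call. = FALSE)
  }
  if (transform == "none") {
    p <- x / n
    theta <- p
    v <- p * (1 - p) / n
    if (any(v == 0)) {
      stop("zero variance under the untransformed scale (p of 0 or 1); ",
           "use a transform", call. = FALSE)
    }
    back <- function(t) t
  } else if (transform == "logit") {
    xx <- x; nn <- n
    cc <- x == 0 | x == n
    xx[cc] <- x[cc] + 0.5
    nn[cc] <- n[cc] + 1
    theta <- log(xx / (nn - xx))
    v <- 1 / xx + 1 / (nn - xx)
    back <- function(t) stats::plogis(t)
  } else {
    theta <- 0.5 * (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1))))
    v <- 1 / (4 * n + 2)
    nh <- k / sum(1 / n)   # harmonic mean for Miller back-transform
    back <- function(t) {
      s2 <- sin(2 * t)
      pmin(1, pmax(0, 0.5 * (1 - sign(cos(2 * t)) *
        sqrt(pmax(0, 1 - (s2 + (s2 - 1 / s2) / nh)^2)))))
    }
  }
  w <- 1 / v
  theta_fixed <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_fixed)^2)
  df <- k - 1
  tau2 <- if (k == 1) 0 else
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  pooled_t <- sum(wr * theta) / sum(wr)
  se <- sqrt(1 / sum(wr))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  I2 <- if (k == 1 || Q == 0) 0 else max(0, (Q - df) / Q) * 100
  structure(list(
    pooled = back(pooled_t), ci_lower = back(pooled_t - zc * se),
    ci_upper = back(pooled_t + zc * se),
    pooled_transformed = pooled_t, se_transformed = se,
    tau_squared = tau2, Q = Q, df = df, I_squared = I2, k = k,
    transform = transform, weights = wr / sum(wr)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "random-effects pooled proportion (%s scale, DerSimonian-Laird):\n", x$transform))
  cat(sprintf("  %.4f [%.4f, %.4f], k = %d\n", x$pooled, x$ci_lower,
              x$ci_upper, x$k))
  cat(sprintf("  tau^2 = %.5g, Q = %.4g (df %d), I^2 = %.1f%%\n",
              x$tau_squared, x$Q, x$df, x$I_squared))
  invisible(x)
}
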