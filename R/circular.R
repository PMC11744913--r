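#' @useDynLib myelotrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd lm coef median fft nextn pnorm dnorm
#' @importFrom utils head tail
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into a half-open interval
#'
#' `wrap180()` maps axial orientations onto \[0, 180) degrees (a fibre has no
#' head or tail, so theta and theta + 180 are the same orientation);
#' `wrap360()` maps directions onto \[0, 360).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles.
#' @export
wrap180 <- function(x) ((x %% 180) + 180) %% 180

#' @rdname wrap180
#' @export
wrap360 <- function(x) ((x %% 360) + 360) %% 360

#' Circular mean of angular data
#'
#' For axial data (orientations modulo 180 degrees) the angles are doubled,
#' averaged as directions on the full circle, and halved back. This is the
#' standard embedding that makes moments of 0-180 degree data well defined.
#'
#' @param theta_deg angles in degrees.
#' @param axial logical; `TRUE` (default) treats the data as axial on
#'   \[0, 180), `FALSE` as directions on \[0, 360).
#' @return the circular mean in degrees, on the same scale as the input.
#' @export
circ_mean_deg <- function(theta_deg, axial = TRUE) {
  stopifnot(length(theta_deg) >= 1, all(is.finite(theta_deg)))
  mult <- if (axial) 2 else 1
  a <- deg2rad(theta_deg * mult)
  m <- atan2(mean(sin(a)), mean(cos(a)))
  if (axial) wrap180(rad2deg(m) / 2) else wrap360(rad2deg(m))
}

#' Circular standard deviation in degrees
#'
#' Mardia's circular standard deviation `sqrt(-2 log R)` where `R` is the mean
#' resultant length, computed on the doubled circle for axial data and mapped
#' back to the axial scale.
#'
#' @inheritParams circ_mean_deg
#' @export
circ_sd_deg <- function(theta_deg, axial = TRUE) {
  mult <- if (axial) 2 else 1
  a <- deg2rad(theta_deg * mult)
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- min(R, 1)
  rad2deg(sqrt(-2 * log(R))) / mult
}

#' Signed shortest angular difference
#'
#' Returns `a - b` wrapped to the shortest signed arc: (-90, 90\] degrees for
#' axial data, (-180, 180\] for directional data.
#'
#' @param a,b angles in degrees.
#' @param axial logical, see [circ_mean_deg()].
#' @export
circ_diff_deg <- function(a, b, axial = TRUE) {
  per <- if (axial) 180 else 360
  d <- (a - b) %% per
  ifelse(d > per / 2, d - per, d)
}

#' Highest posterior density interval for circular draws
#'
#' Computes the shortest arc containing `mass` of the draws. Draws are mapped
#' to the circle (doubling them first when `axial = TRUE`), sorted, and the
#' minimum-width window over `ceiling(mass * n)` consecutive order statistics
#' (with wrap-around) is returned, mapped back to the input scale.
#'
#' @param draws_deg numeric vector of at least 100 posterior draws, in degrees.
#' @param mass posterior mass to cover (default 0.95).
#' @param axial logical; axial \[0, 180) data (default) or directions.
#' @return a named numeric vector `c(lower, upper)` in degrees, with
#'   `upper = lower + width`. `upper` may exceed the period (180 for axial
#'   data) when the interval wraps through 0; use [in_hpd()] for containment
#'   checks. The attribute `"multimodal"` is `TRUE` when the shortest covering
#'   arc spans more than half the support, indicating a spread-out or
#'   multimodal set of draws; the interval is still returned (with a warning).
#' @export
hpd_interval <- function(draws_deg, mass = 0.95, axial = TRUE) {
  stopifnot(is.numeric(draws_deg), mass > 0, mass <= 1)
  if (length(draws_deg) < 100)
    stop("hpd_interval() needs at least 100 draws")
  mult <- if (axial) 2 else 1
  per <- 360
  x <- sort(wrap360(draws_deg * mult))
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) {
    # full-mass interval: the shortest arc covering all draws
    gaps <- diff(c(x, x[1] + per))
    k <- which.max(gaps)
    lo <- wrap360(x[(k %% n) + 1L])
    width <- per - gaps[k]
  } else {
    # windows of m consecutive sorted draws, wrapping around the circle
    xx <- c(x, x + per)
    widths <- xx[seq_len(n) + m - 1L] - x
    k <- which.min(widths)
    lo <- x[k]
    width <- widths[k]
  }
  multimodal <- width > per / 2
  if (multimodal)
    warning("HPD interval spans more than half the circle; ",
            "draws may be multimodal")
  out <- c(lower = lo / mult, upper = (lo + width) / mult)
  attr(out, "multimodal") <- multimodal
  attr(out, "width") <- width / mult
  out
}

#' Test whether an angle lies inside a (possibly wrapping) HPD interval
#'
#' @param theta_deg angle in degrees on the interval's scale.
#' @param interval result of [hpd_interval()].
#' @param axial logical, must match the interval's construction.
#' @export
in_hpd <- function(theta_deg, interval, axial = TRUE) {
  per <- if (axial) 180 else 360
  lo <- interval[["lower"]]
  up <- interval[["upper"]]
  th <- ((theta_deg - lo) %% per + per) %% per
  th <= (up - lo) + 1e-12
}

#' Effective sample size of an MCMC series
#'
#' Autocorrelation-based effective sample size using the initial positive
#' sequence estimator: sums of adjacent autocorrelation pairs are accumulated
#' while positive.
#'
#' @param x numeric vector (one chain of draws).
#' @return estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[, 1, 1]
  s <- 0
  k <- 2
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Two-sample Kuiper test on the circle
#'
#' Rotation-invariant analogue of the Kolmogorov-Smirnov two-sample test:
#' `V = D+ + D-`. Used to check that a stratified bootstrap subsample
#' reproduces the distribution of the full stratum. The p-value uses the
#' asymptotic series with Stephens' small-sample correction.
#'
#' @param x,y numeric samples (angles in degrees or any common scale).
#' @return list with `statistic` (V) and `p.value`.
#' @export
kuiper_test <- function(x, y) {
  stopifnot(length(x) > 1, length(y) > 1)
  all_v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  V <- max(Fx - Fy) + max(Fy - Fx)
  n <- length(x) * length(y) / (length(x) + length(y))
  lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = V, p.value = max(0, min(1, p)))
}
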