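#' Extrapolate wind speed to another height with the logarithmic profile
#'
#' Under neutral stratification the mean wind speed grows with the logarithm of
#' height above ground, scaled by the terrain roughness length z0:
#' `u(z) = u(z_ref) * ln(z / z0) / ln(z_ref / z0)`. Meteorological stations
#' measure at 10 m; hub-height resource assessments need speeds at 50 m or more.
#'
#' @param u10 measured speed(s) at the reference height, m/s.
#' @param z_target height to extrapolate to, m.
#' @param z10 measurement (reference) height, m. Default 10.
#' @param z0 roughness length, m (must be positive and below `z10`); a user
#'   input per station, typically 0.01 (open water) to 1 (forest/town).
#' @return speed(s) at `z_target`, m/s.
#' @examples
#' extrapolate_speed(5, z_target = 50, z10 = 10, z0 = 0.05)
#' @export
extrapolate_speed <- function(u10, z_target, z10 = 10, z0 = 0.03) {
  if (!is.numeric(z0) || z0 <= 0) stop("roughness length z0 must be positive")
  if (z10 <= z0) stop("measurement height z10 must exceed the roughness length")
  if (any(z_target < z0)) stop("target height below the roughness length")
  if (any(u10 < 0)) stop("wind speeds must be non-negative")
  u10 * log(z_target / z0) / log(z10 / z0)
}

#' Mean wind power density of a Weibull wind regime
#'
#' The mean power per unit rotor-swept area is `0.5 * rho * E[u^3]`; for a
#' Weibull speed distribution with scale `c` and shape `k` the third moment is
#' `c^3 * gamma(1 + 3/k)`.
#'
#' @param c Weibull scale, m/s.
#' @param k Weibull shape (dimensionless).
#' @param rho air density, kg/m^3 (default sea-level standard 1.225).
#' @return power density in W/m^2.
#' @examples
#' power_density(8, 2) # about 417 W/m^2
#' @export
power_density <- function(c, k, rho = 1.225) {
  if (any(c <= 0) || any(k <= 0) || rho <= 0)
    stop("c, k and rho must be positive")
  0.5 * rho * c^3 * gamma(1 + 3 / k)
}

#' Fit a Weibull distribution to wind speeds by maximum likelihood
#'
#' Zero speeds (calms) are removed before fitting, since the Weibull
#' log-likelihood is undefined at zero; the number removed is recorded on the
#' returned object. The shape k solves the profile score equation
#' `sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0` (damped Newton from k = 2,
#' relative tolerance 1e-8, at most 200 iterations), after which
#' `c = (mean(x^k))^(1/k)`. Mean speed `c*gamma(1+1/k)` and mean power density
#' are derived from the fit.
#'
#' @param speeds numeric vector of non-negative wind speeds, m/s. At least 30
#'   positive values are required.
#' @param rho air density for the derived power density, kg/m^3.
#' @return object of class `weibull_fit` with elements `c`, `k`, `mean_speed`,
#'   `power_density`, `n`, `n_calms`, `loglik`, `iterations`.
#' @examples
#' set.seed(1)
#' fit <- fit_weibull(rweibull(5000, shape = 2, scale = 8))
#' coef(fit)
#' @export
fit_weibull <- function(speeds, rho = 1.225) {
  if (!is.numeric(speeds) || anyNA(speeds)) stop("speeds must be numeric without NA")
  if (any(speeds < 0)) stop("wind speeds must be non-negative")
  x <- speeds[speeds > 0]
  n_calms <- length(speeds) - length(x)
  if (length(x) < 30)
    stop("need at least 30 positive speeds after removing calms, have ", length(x))
  if (max(x) == min(x))
    stop("degenerate sample: all positive speeds identical")

  lx <- log(x)
  mlx <- mean(lx)
  score <- function(k) {
    w <- x^k
    sum(w * lx) / sum(w) - 1 / k - mlx
  }
  dscore <- function(k) {
    w <- x^k
    sw <- sum(w); swl <- sum(w * lx); swl2 <- sum(w * lx^2)
    swl2 / sw - (swl / sw)^2 + 1 / k^2
  }

  k <- 2
  it <- 0L
  repeat {
    it <- it + 1L
    f <- score(k)
    step <- f / dscore(k)
    # halve the step until the iterate stays positive
    while (k - step <= 0) step <- step / 2
    k_new <- k - step
    if (abs(k_new - k) <= 1e-8 * k_new) { k <- k_new; break }
    k <- k_new
    if (it >= 200)
      stop("Weibull MLE did not converge after 200 iterations (last k = ",
           format(k), ")")
  }
  c_hat <- mean(x^k)^(1 / k)

  structure(list(
    c = c_hat, k = k,
    mean_speed = c_hat * gamma(1 + 1 / k),
    power_density = power_density(c_hat, k, rho),
    rho = rho,
    n = length(x), n_calms = n_calms,
    loglik = sum(stats::dweibull(x, shape = k, scale = c_hat, log = TRUE)),
    iterations = it),
    class = "weibull_fit")
}

#' @export
coef.weibull_fit <- function(object, ...) c(shape = object$k, scale = object$c)

#' @export
logLik.weibull_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
print.weibull_fit <- function(x, digits = 4, ...) {
  cat("Weibull wind-regime fit (MLE)\n")
  cat(sprintf("  shape k = %s, scale c = %s m/s\n",
              format(x$k, digits = digits), format(x$c, digits = digits)))
  cat(sprintf("  mean speed %s m/s, power density %s W/m^2 (rho = %s kg/m^3)\n",
              format(x$mean_speed, digits = digits),
              format(x$power_density, digits = digits), format(x$rho)))
  cat(sprintf("  n = %d positive speeds (%d calms removed)\n", x$n, x$n_calms))
  invisible(x)
}

#' @export
summary.weibull_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood %.2f in %d Newton iterations\n",
              object$loglik, object$iterations))
  invisible(object)
}

#' Simulate speeds from a fitted Weibull wind regime
#'
#' @param object a `weibull_fit`.
#' @param nsim number of speeds to draw.
#' @param seed optional seed passed to [set.seed()].
#' @param ... ignored.
#' @export
simulate.weibull_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rweibull(nsim, shape = object$k, scale = object$c)
}

#' Read an hourly wind-speed series
#'
#' Expects a CSV with columns `timestamp` and `speed_ms`.
#'
#' @param file path to the CSV.
#' @return data frame with the two columns; speeds validated non-negative.
#' @export
read_wind_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "speed_ms") %in% names(df)))
    stop("wind CSV must have columns timestamp and speed_ms")
  if (anyNA(df$speed_ms) || any(df$speed_ms < 0))
    stop("wind CSV contains missing or negative speeds")
  df
}

#' Wind-resource summary for a station series
#'
#' Convenience wrapper: extrapolates the measured series to the target height
#' with the log profile, then fits the Weibull regime at that height.
#'
#' @param speeds measured speeds at `z10`, m/s.
#' @param z_target assessment height, m (default 50).
#' @inheritParams extrapolate_speed
#' @inheritParams fit_weibull
#' @return a `weibull_fit` at the target height.
#' @export
wind_resource <- function(speeds, z_target = 50, z10 = 10, z0 = 0.03, rho = 1.225) {
  fit_weibull(extrapolate_speed(speeds, z_target, z10, z0), rho = rho)
}
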