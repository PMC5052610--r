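#' Put a tracer C-curve on dimensionless axes
#'
#' Normalises time by the nominal HRT (\eqn{\theta = t / HRT}) and
#' concentration by the reference concentration (\eqn{C_\theta = C / C_0}).
#'
#' @param curve a [ccurve()] with positive `c0` and `nominal_hrt`.
#' @return An object of class `normalized_curve` with fields `theta` and
#'   `c_theta`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "ccurve"))
  if (curve$nominal_hrt <= 0 || curve$c0 <= 0)
    stop("`nominal_hrt` and `c0` must be positive to normalize", call. = FALSE)
  structure(
    list(theta = curve$times / curve$nominal_hrt,
         c_theta = curve$concentrations / curve$c0),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("Normalized C-curve: %d points, theta in [%.3g, %.3g]\n",
              length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' First two moments of a normalized C-curve
#'
#' Computes the concentration-weighted mean and variance of dimensionless
#' time,
#' \deqn{\theta_m = \frac{\int \theta C \, d\theta}{\int C \, d\theta},
#'   \qquad
#'   \sigma_\theta^2 = \frac{\int (\theta-\theta_m)^2 C \, d\theta}
#'                          {\int C \, d\theta},}
#' by trapezoidal quadrature on the sampled grid (no smoothing or
#' interpolation). Optionally restricts the curve to `theta <= upper_theta`.
#'
#' @param norm a `normalized_curve`.
#' @param upper_theta optional truncation point; moments are computed on
#'   `[0, upper_theta]`.
#' @return A list with elements `mean_theta` and `variance_theta`.
#' @export
curve_moments <- function(norm, upper_theta = NULL) {
  stopifnot(inherits(norm, "normalized_curve"))
  theta <- norm$theta
  c_theta <- norm$c_theta
  if (!is.null(upper_theta)) {
    keep <- theta <= upper_theta
    theta <- theta[keep]
    c_theta <- c_theta[keep]
  }
  if (length(theta) < 3L)
    stop("need at least 3 points within the integration range", call. = FALSE)
  area <- pracma::trapz(theta, c_theta)
  if (area <= 0)
    stop("moments undefined: curve has zero area", call. = FALSE)
  mean_theta <- pracma::trapz(theta, theta * c_theta) / area
  variance_theta <- pracma::trapz(theta, (theta - mean_theta)^2 * c_theta) / area
  list(mean_theta = mean_theta, variance_theta = variance_theta)
}

#' Measured hydraulic retention time
#'
#' The centroid of the full C-curve converted back to hours:
#' \eqn{\theta_m \times HRT_{nominal}}.
#'
#' @param norm a `normalized_curve`.
#' @param nominal_hrt nominal HRT in hours.
#' @return Measured HRT in hours.
#' @export
measured_hrt <- function(norm, nominal_hrt) {
  if (nominal_hrt <= 0) stop("`nominal_hrt` must be positive", call. = FALSE)
  curve_moments(norm)$mean_theta * nominal_hrt
}

#' Hydraulic dead-space fraction from the truncated C-curve
#'
#' Estimates the fraction of reactor volume bypassed by flow as
#' \deqn{V_d / V_T = 1 - \theta_m^{[0,2]},}
#' one minus the centroid of the C-curve restricted to \eqn{\theta \in [0,
#' 2]}, clamped to \eqn{[0, 1]}. For an ideal stirred tank this evaluates to
#' about 0.313; for ideal plug flow (a narrow pulse at \eqn{\theta = 1}) it
#' is 0. The estimate depends only on curve shape, not on concentration
#' scale.
#'
#' @param norm a `normalized_curve` extending to at least
#'   `theta = upper_theta`.
#' @param upper_theta truncation point of the centroid; default 2.
#' @return Dead-space fraction in `[0, 1]`.
#' @export
dead_space_fraction <- function(norm, upper_theta = 2) {
  stopifnot(inherits(norm, "normalized_curve"))
  if (max(norm$theta) < upper_theta)
    stop("curve must extend to theta >= ", upper_theta,
         " for the dead-space estimate", call. = FALSE)
  m <- curve_moments(norm, upper_theta = upper_theta)
  min(max(1 - m$mean_theta, 0), 1)
}

#' Tanks-in-series fit from the RTD variance
#'
#' The tanks-in-series model relates the normalized RTD variance to the
#' equivalent number of ideal stirred tanks by \eqn{N = 1/\sigma_\theta^2}.
#' N is reported as a real number (fractional tanks are meaningful) and
#' clamped below at 1, the completely-mixed limit.
#'
#' @param variance_theta normalized RTD variance, positive.
#' @return Equivalent number of tanks in series (>= 1).
#' @examples
#' fit_tanks_in_series(0.28)  # 3.57
#' fit_tanks_in_series(0.30)  # 3.33
#' @export
fit_tanks_in_series <- function(variance_theta) {
  if (!is.numeric(variance_theta) || length(variance_theta) != 1L ||
      variance_theta <= 0)
    stop("`variance_theta` must be a single positive number", call. = FALSE)
  max(1, 1 / variance_theta)
}

#' Axial dispersion number from the RTD variance
#'
#' Fits the dispersion number \eqn{d = D/\mu L} (the reciprocal Peclet
#' number) from the normalized variance. The default `"small-dispersion"`
#' closed form is \eqn{d = \sigma_\theta^2 / 2}. The `"closed-vessel"`
#' method solves the implicit closed-closed boundary relation
#' \deqn{\sigma_\theta^2 = 2d - 2d^2 (1 - e^{-1/d})}
#' by bracketed bisection to 1e-10; it requires \eqn{\sigma_\theta^2 < 1}
#' (the relation saturates at 1 as \eqn{d \to \infty}).
#'
#' @param variance_theta normalized RTD variance, positive.
#' @param method `"small-dispersion"` (default) or `"closed-vessel"`.
#' @return The dispersion number \eqn{D/\mu L}.
#' @examples
#' fit_dispersion(0.28)  # 0.14
#' fit_dispersion(0.2408, method = "closed-vessel")  # ~0.14
#' @export
fit_dispersion <- function(variance_theta,
                           method = c("small-dispersion", "closed-vessel")) {
  method <- match.arg(method)
  if (!is.numeric(variance_theta) || length(variance_theta) != 1L ||
      variance_theta <= 0)
    stop("`variance_theta` must be a single positive number", call. = FALSE)
  if (method == "small-dispersion") return(variance_theta / 2)
  if (variance_theta >= 1)
    stop("closed-vessel fit has no solution for variance >= 1 ",
         "(system beyond the dispersion-model range)", call. = FALSE)
  f <- function(d) 2 * d - 2 * d^2 * (1 - exp(-1 / d)) - variance_theta
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2  # f -> 1 - variance > 0 as d grows
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify a mixing pattern from the dispersion number
#'
#' Dispersion numbers below 0.02 indicate plug flow and above 0.2 complete
#' mixing; values between (boundaries included) are intermediate.
#'
#' @param dispersion_number non-negative dispersion number \eqn{D/\mu L}.
#' @return One of `"plug-flow"`, `"intermediate"`, `"completely-mixed"`.
#' @examples
#' classify_mixing(0.33)  # completely-mixed
#' classify_mixing(0.14)  # intermediate
#' @export
classify_mixing <- function(dispersion_number) {
  if (!is.numeric(dispersion_number) || length(dispersion_number) != 1L ||
      dispersion_number < 0)
    stop("`dispersion_number` must be a single non-negative number", call. = FALSE)
  if (dispersion_number < 0.02) "plug-flow"
  else if (dispersion_number > 0.2) "completely-mixed"
  else "intermediate"
}

#' Full RTD summary of a tracer curve
#'
#' Composes normalisation, moments, measured HRT, dead-space estimation,
#' dispersion fit, tanks-in-series fit and mixing classification into one
#' record. Deterministic given the curve and method choices.
#'
#' @param curve a [ccurve()] extending to at least `theta = 2`.
#' @param dispersion_method passed to [fit_dispersion()].
#' @param dead_space_upper truncation point for [dead_space_fraction()].
#' @return An object of class `rtd_summary`: a list with `mean_theta`,
#'   `variance_theta`, `measured_hrt` (hours), `dead_space_fraction`,
#'   `dispersion_number`, `peclet`, `n_tanks` and `mixing_class`.
#' @export
summarize_rtd <- function(curve,
                          dispersion_method = c("small-dispersion", "closed-vessel"),
                          dead_space_upper = 2) {
  stopifnot(inherits(curve, "ccurve"))
  dispersion_method <- match.arg(dispersion_method)
  norm <- normalize_curve(curve)
  m <- curve_moments(norm)
  d <- fit_dispersion(m$variance_theta, method = dispersion_method)
  structure(
    list(
      mean_theta = m$mean_theta,
      variance_theta = m$variance_theta,
      measured_hrt = m$mean_theta * curve$nominal_hrt,
      dead_space_fraction = dead_space_fraction(norm, upper_theta = dead_space_upper),
      dispersion_number = d,
      peclet = 1 / d,
      n_tanks = fit_tanks_in_series(m$variance_theta),
      mixing_class = classify_mixing(d),
      dispersion_method = dispersion_method
    ),
    class = "rtd_summary"
  )
}

#' @export
print.rtd_summary <- function(x, ...) {
  cat("RTD summary\n")
  cat(sprintf("  mean theta        : %.4f\n", x$mean_theta))
  cat(sprintf("  variance theta    : %.4f\n", x$variance_theta))
  cat(sprintf("  measured HRT      : %.2f h\n", x$measured_hrt))
  cat(sprintf("  dead space        : %.1f %%\n", 100 * x$dead_space_fraction))
  cat(sprintf("  dispersion number : %.4f (%s)\n", x$dispersion_number,
              x$dispersion_method))
  cat(sprintf("  tanks in series N : %.2f\n", x$n_tanks))
  cat(sprintf("  mixing pattern    : %s\n", x$mixing_class))
  invisible(x)
}

#' @export
as.data.frame.rtd_summary <- function(x, ...) {
  data.frame(
    mean_theta = x$mean_theta, variance_theta = x$variance_theta,
    measured_hrt_h = x$measured_hrt,
    dead_space_pct = 100 * x$dead_space_fraction,
    dispersion_number = x$dispersion_number, peclet = x$peclet,
    n_tanks = x$n_tanks, mixing_class = x$mixing_class
  )
}
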