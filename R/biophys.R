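# Explicit measurement formulas: spherical-Hertz AFM fitting with joint
# contact-point estimation, Laurdan generalized polarization with G-factor
# calibration, and optical-stretcher axial strain. SI units internally
# (m, N, Pa).

#' Spherical Hertz contact force
#'
#' `F = 4 E sqrt(R) / (3 (1 - mu^2)) * delta^(3/2)` for a rigid sphere of
#' radius `R` indenting an elastic half-space by `delta`.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param R sphere radius (m), > 0.
#' @param delta indentation (m), >= 0 (vectorized).
#' @param mu Poisson ratio, default 0.5 (incompressible).
#' @return force (N).
#' @examples
#' hertz_force(1000, 2.25e-6, 1e-6)  # ~2.67 nN
#' @export
hertz_force <- function(E, R, delta, mu = 0.5) {
  if (E <= 0 || R <= 0) stop("E and R must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  4 * E * sqrt(R) / (3 * (1 - mu^2)) * delta^1.5
}

#' Fit the spherical Hertz model to a force curve
#'
#' Jointly estimates Young's modulus `E`, the contact displacement `z_c`
#' and the deflection offset `d_0` by nonlinear least squares on the
#' force `F = k (d - d_0)` versus `Hertz(E, delta)` with
#' `delta = (z - z_c) - (d - d_0)` restricted to the `delta >= 0` branch
#' (pre-contact points contribute their offset residual `k (d - d_0)`).
#' Given `(z_c, d_0)` the modulus is profiled out linearly, and the
#' remaining 2-D problem is solved with a deterministic Nelder-Mead
#' search started at the pre-contact median deflection and the
#' maximum-curvature point of the deflection record.
#'
#' @param curve a `force_curve` (list with `z`, `d`, `k_cant`), e.g. from
#'   [gen_force_curve()].
#' @param R_bead probe sphere radius (m).
#' @param mu Poisson ratio.
#' @return Object of class `hertz_fit`: list(E, z_c, d_0, mu, R_bead,
#'   rss, convergence).
#' @export
fit_hertz <- function(curve, R_bead = 2.25e-6, mu = 0.5) {
  z <- curve$z; d <- curve$d; k <- curve$k_cant
  if (length(z) != length(d) || length(z) < 10)
    stop("curve needs equal-length z and d with at least 10 samples")
  if (k <= 0) stop("k_cant must be > 0")

  # profile C = 4 E sqrt(R)/(3(1-mu^2)) linearly given (z_c, d_0)
  rss_of <- function(par) {
    z_c <- par[1]; d_0 <- par[2]
    dr <- d - d_0
    delta <- (z - z_c) - dr
    post <- delta > 0 & z > z_c
    if (sum(post) < 5) return(Inf)
    Fobs <- k * dr
    phi <- delta^1.5
    Chat <- sum(Fobs[post] * phi[post]) / sum(phi[post]^2)
    if (!is.finite(Chat) || Chat <= 0) return(Inf)
    sum((Fobs[post] - Chat * phi[post])^2) + sum(Fobs[!post]^2)
  }

  # initialization: offset from the first decile of the ramp; contact at
  # the maximum-curvature point of the deflection record
  n <- length(z)
  pre <- seq_len(max(5L, floor(n / 10)))
  d0_init <- stats::median(d[pre])
  if (n >= 5) {
    dd2 <- abs(diff(diff(d)))
    zc_init <- z[which.max(dd2) + 1L]
  } else zc_init <- stats::median(z)

  opt <- stats::optim(c(zc_init, d0_init), rss_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  # polish
  opt <- stats::optim(opt$par, rss_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (!is.finite(opt$value))
    stop("fit_hertz did not converge: no post-contact branch found")
  z_c <- opt$par[1]; d_0 <- opt$par[2]
  dr <- d - d_0
  delta <- (z - z_c) - dr
  post <- delta > 0 & z > z_c
  if (sum(post) < 5) stop("insufficient post-contact points")
  phi <- delta[post]^1.5
  Chat <- sum((k * dr[post]) * phi) / sum(phi^2)
  E <- Chat * 3 * (1 - mu^2) / (4 * sqrt(R_bead))
  if (E <= 0) stop("fit_hertz produced a non-positive modulus")
  structure(list(E = E, z_c = z_c, d_0 = d_0, mu = mu, R_bead = R_bead,
                 rss = opt$value, convergence = opt$convergence),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit>  E=%.4g Pa  z_c=%.4g m  d_0=%.4g m  rss=%.3g\n",
    x$E, x$z_c, x$d_0, x$rss))
  invisible(x)
}

#' Laurdan generalized polarization
#'
#' `GP = (I440 - G I490) / (I440 + G I490)`, elementwise. With `G = 1`
#' and nonnegative intensities GP lies in [-1, 1]. Elements with a zero
#' denominator are returned as `NaN` with a warning.
#'
#' @param I440,I490 emission intensities centred at 440 nm and 490 nm
#'   (arrays of equal shape).
#' @param G calibration factor for the wavelength dependence of the
#'   detection system (see [calibrate_g()]).
#' @return GP values shaped like the inputs.
#' @export
laurdan_gp <- function(I440, I490, G = 1) {
  if (length(I440) != length(I490))
    stop("I440 and I490 must have the same length")
  den <- I440 + G * I490
  if (any(den == 0)) warning(sum(den == 0), " element(s) with zero ",
                             "denominator flagged as NaN")
  out <- (I440 - G * I490) / den
  out[den == 0] <- NaN
  out
}

#' Calibrate the Laurdan G factor from a reference solution
#'
#' Inverts the GP formula for a solution of known GP (the published
#' reference is Laurdan in dimethyl sulfoxide):
#' `G = (I440_ref / I490_ref) * (1 - gp_known) / (1 + gp_known)`, so that
#' `laurdan_gp(I440_ref, I490_ref, G) == gp_known` to machine precision.
#'
#' @param I440_ref,I490_ref reference intensities, > 0 (scalars or equal
#'   shape; means are taken).
#' @param gp_known reference GP value, strictly inside (-1, 1).
#' @return G.
#' @export
calibrate_g <- function(I440_ref, I490_ref, gp_known) {
  if (any(I440_ref <= 0) || any(I490_ref <= 0))
    stop("reference intensities must be > 0")
  if (gp_known <= -1 || gp_known >= 1)
    stop("gp_known must lie strictly inside (-1, 1)")
  (mean(I440_ref) / mean(I490_ref)) * (1 - gp_known) / (1 + gp_known)
}

#' Optical-stretcher axial strain
#'
#' `Strain(t) = (r(t) - r0) / r0`: relative elongation of the cell's
#' major axis against its length during the initial trapping period.
#'
#' @param r_t major-axis length series.
#' @param r0 initial (trapped) length, > 0.
#' @param percent report in percent.
#' @return strain series (dimensionless, or % when `percent`).
#' @export
os_strain <- function(r_t, r0, percent = FALSE) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0)
    stop("r0 must be a scalar > 0")
  s <- (r_t - r0) / r0
  if (percent) 100 * s else s
}
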