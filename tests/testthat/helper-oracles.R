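# Independent oracles used across the suite. These deliberately do not
# share code paths with the package implementation.

# Classic DBSCAN by seed-point reachability expansion (queue of
# unexpanded neighbors, border points labeled during expansion).
dbscan_oracle <- function(df, eps, minpts) {
  n <- nrow(df)
  if (!n) return(integer(0))
  D2 <- as.matrix(stats::dist(cbind(df$x, df$y)))^2
  eps2 <- eps^2
  labels <- rep(0L, n)  # 0 = unvisited, -1 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nbi <- which(D2[i, ] <= eps2)
    if (length(nbi) < minpts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nbi, i)
    while (length(seeds)) {
      q <- seeds[[1]]; seeds <- seeds[-1]
      if (labels[q] == -1L) labels[q] <- cl
      if (labels[q] != 0L) next
      labels[q] <- cl
      nbq <- which(D2[q, ] <= eps2)
      if (length(nbq) >= minpts) seeds <- c(seeds, setdiff(nbq, q))
    }
  }
  # normalize border points to the implementation's documented tie rule
  # (lowest neighboring cluster id); core membership is order-independent
  core <- vapply(seq_len(n), function(i)
    sum(D2[i, ] <= eps2) >= minpts, logical(1))
  for (i in which(!core & labels > 0)) {
    ids <- labels[which(D2[i, ] <= eps2 & core)]
    labels[i] <- min(ids[ids > 0])
  }
  labels
}

# TRUE when two labelings induce the same partition of the non-noise
# points and agree on which points are noise.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1, b == -1)) return(FALSE)
  ok <- a != -1
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(TRUE)
  key_a <- match(a, unique(a))
  key_b <- match(b, unique(b))
  identical(key_a, key_b)
}

# Term-by-term numeric quadrature of the cap energy: bending integrated
# over the cap surface, excess area from the surface/projection
# integrals, rim from the boundary circle.
energy_quadrature <- function(A_d, u, coat, sigma) {
  if (u == 0) {
    return(2 * coat$kappa_c * A_d * coat$c0^2 +
             coat$lambda_rim * 2 * pi * sqrt(A_d / pi))
  }
  R <- sqrt(A_d / (2 * pi * u))
  psi <- acos(1 - u)
  bend <- stats::integrate(function(th)
    2 * coat$kappa_c * (1 / R - coat$c0)^2 * 2 * pi * R^2 * sin(th),
    0, psi, rel.tol = 1e-12)$value
  area <- stats::integrate(function(th) 2 * pi * R^2 * sin(th),
                           0, psi, rel.tol = 1e-12)$value
  A_p <- pi * (R * sin(psi))^2
  rim <- 2 * pi * R * sin(psi)
  bend + sigma * (area - A_p) + coat$lambda_rim * rim
}

# Numeric minimizer of the cap energy over u in [0, 2] with explicit
# boundary candidates; used against the closed form.
numeric_u_star <- function(A_d, coat, sigma) {
  f <- function(u) mech_energy(cap_from(A_d, u), coat, sigma)
  opt <- stats::optimize(f, c(0, 2), tol = 1e-12)
  cand <- c(opt$minimum, 0, 2)
  vals <- c(opt$objective, f(0), f(2))
  cand[which.min(vals)]
}

# Brute-force grid argmin of the ensemble free energy over
# (condensed fraction, log A_d, u).
grid_min_ensemble <- function(coat, sigma, phi_bar,
                              nt = 20, nA = 20, nu = 20) {
  ts <- seq(1e-6, 1, length.out = nt)
  lAs <- seq(log(1e3), log(1e6), length.out = nA)
  us <- seq(0, 2, length.out = nu)
  best <- list(f = Inf)
  for (t in ts) for (lA in lAs) for (u in us) {
    A <- exp(lA)
    f <- free_energy_density(t * phi_bar / A, A, u, coat, sigma, phi_bar)
    if (f < best$f) best <- list(f = f, t = t, logA = lA, u = u)
  }
  best$steps <- c(t = diff(ts)[1], logA = diff(lAs)[1], u = diff(us)[1])
  best
}

# Hertz pressure-distribution oracle: total force as the integral of the
# Hertzian contact pressure p(r) = p0 sqrt(1 - (r/a)^2) over the contact
# disc, with a = sqrt(R delta) and p0 = 2 E* a / (pi R).
hertz_pressure_integral <- function(E, R, delta, mu = 0.5) {
  Estar <- E / (1 - mu^2)
  a <- sqrt(R * delta)
  p0 <- 2 * Estar * a / (pi * R)
  stats::integrate(function(r) p0 * sqrt(1 - (r / a)^2) * 2 * pi * r,
                   0, a, rel.tol = 1e-10)$value
}

# Small helper: build a localization table from bare coordinates.
loc_table <- function(x, y, frame = seq_along(x), sigma = 150,
                      intensity = 1000, uncertainty = 15,
                      roi_area = NULL, roi_polygon = NULL) {
  d <- data.frame(frame = frame, x = x, y = y,
                  sigma = rep_len(sigma, length(x)),
                  intensity = rep_len(intensity, length(x)),
                  uncertainty = rep_len(uncertainty, length(x)))
  if (is.null(roi_area) && is.null(roi_polygon))
    roi_area <- max(1, diff(range(x)) * diff(range(y)))
  localization_table(d, roi_area = roi_area, roi_polygon = roi_polygon)
}
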