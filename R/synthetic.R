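# Synthetic inputs for every analysis module: clustered blink tables with
# ground truth, Hertzian force curves, and Laurdan intensity pairs. All
# generators are pure functions of (params, seed): no hidden global state.

.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generate a synthetic blink table with known cluster ground truth
#'
#' Emulates the statistical structure of a dSTORM acquisition: `K`
#' Gaussian blink clusters plus uniform noise blinks over a square ROI,
#' frames uniform over `n_frames` (the published acquisitions typically
#' span 9,000-10,000 frames). Cluster centers sit on a jittered grid with
#' at least ~200 nm separation so ground truth is unambiguous. Blink
#' attributes follow documented synthetic conventions chosen to pass the
#' default filters: intensity ~ lognormal(log 1000, 0.5), uncertainty ~
#' Gamma(9, scale 5/3) (mean 15 nm), sigma ~ N(150, 20) nm. A fraction
#' `out_of_filter_rate` of records is injected with attributes outside
#' the filter window to exercise filtering.
#'
#' @param K number of clusters.
#' @param blinks_per_cluster blink count per cluster (scalar or length-K).
#' @param cluster_sd isotropic Gaussian spread of each cluster (nm;
#'   scalar or length-K).
#' @param noise_rate noise blinks as a fraction of clustered blinks.
#' @param roi_side side of the square ROI (nm).
#' @param n_frames number of acquisition frames.
#' @param out_of_filter_rate fraction of records pushed outside the
#'   filter window.
#' @param seed integer seed; identical (params, seed) give identical
#'   tables.
#' @return list with `table` (a [localization_table()] whose ROI polygon
#'   is the square) and `truth` (centers, per-cluster counts, noise
#'   count, roi_area, seed).
#' @export
gen_blinks <- function(K = 10, blinks_per_cluster = 100, cluster_sd = 10,
                       noise_rate = 0.1, roi_side = 2300, n_frames = 9000,
                       out_of_filter_rate = 0, seed = 1) {
  if (K < 0 || any(blinks_per_cluster < 0) || noise_rate < 0 ||
      out_of_filter_rate < 0 || out_of_filter_rate > 1)
    stop("infeasible generator parameters")
  counts <- rep_len(blinks_per_cluster, max(K, 1L))[seq_len(K)]
  sds <- rep_len(cluster_sd, max(K, 1L))[seq_len(K)]
  .with_seed(seed, {
    # jittered-grid centers: guarantees separation >= spacing - 2*jitter
    g <- ceiling(sqrt(max(K, 1L)))
    margin <- 150
    spacing <- (roi_side - 2 * margin) / max(g - 1, 1)
    if (K > 1 && spacing < 200)
      stop("ROI too small to separate ", K, " clusters")
    gx <- rep(seq_len(g), each = g)[seq_len(K)]
    gy <- rep(seq_len(g), times = g)[seq_len(K)]
    jit <- min(spacing / 8, 40)
    centers <- cbind(
      x = margin + (gx - 1) * spacing + stats::runif(K, -jit, jit),
      y = margin + (gy - 1) * spacing + stats::runif(K, -jit, jit))
    n_clustered <- sum(counts)
    n_noise <- round(noise_rate * n_clustered)
    cl_id <- rep(seq_len(K), times = counts)
    x <- c(stats::rnorm(n_clustered, centers[cl_id, 1], sds[cl_id]),
           stats::runif(n_noise, 0, roi_side))
    y <- c(stats::rnorm(n_clustered, centers[cl_id, 2], sds[cl_id]),
           stats::runif(n_noise, 0, roi_side))
    n <- n_clustered + n_noise
    d <- data.frame(
      frame = sample.int(n_frames, n, replace = TRUE),
      x = x, y = y,
      sigma = stats::rnorm(n, 150, 20),
      intensity = stats::rlnorm(n, log(1000), 0.5),
      uncertainty = stats::rgamma(n, shape = 9, scale = 5 / 3))
    d$sigma <- pmin(pmax(d$sigma, 1), 299.9)
    d$intensity <- pmin(pmax(d$intensity, 301), 4999)
    d$uncertainty <- pmin(d$uncertainty, 34.9)
    if (out_of_filter_rate > 0 && n > 0) {
      n_bad <- round(out_of_filter_rate * n)
      bad <- sample.int(n, n_bad)
      mode <- sample.int(4, n_bad, replace = TRUE)
      d$intensity[bad[mode == 1]] <- 100       # too dim
      d$intensity[bad[mode == 2]] <- 6000      # too bright
      d$uncertainty[bad[mode == 3]] <- 50      # too imprecise
      d$sigma[bad[mode == 4]] <- 400           # too wide
    }
    d <- d[order(d$frame), ]
    rownames(d) <- NULL
    poly <- cbind(x = c(0, roi_side, roi_side, 0),
                  y = c(0, 0, roi_side, roi_side))
    list(table = localization_table(d, roi_polygon = poly),
         truth = list(centers = centers, counts = counts,
                      cluster_sd = sds, n_noise = n_noise,
                      roi_area = roi_side^2, n_frames = n_frames,
                      seed = seed))
  })
}

#' Generate a synthetic AFM force curve
#'
#' Synthesizes a deflection-displacement record consistent with the
#' spherical Hertz contact model and the indentation definition
#' `delta = (z - z_c) - (d - d_0)`: before contact the deflection sits at
#' the offset `d_0`; after contact the deflection solves
#' `k (d - d_0) = Hertz(E_true, delta)` self-consistently. Gaussian noise
#' of standard deviation `noise_sd` is added to the deflection channel.
#'
#' @param E_true Young's modulus (Pa).
#' @param R_bead probe sphere radius (m); the published probe was a
#'   4.5 um diameter microsphere, so 2.25e-6 by default.
#' @param k_cant cantilever spring constant (N/m).
#' @param z_c contact displacement (m).
#' @param d_0 deflection offset (m).
#' @param z_max ramp amplitude (m).
#' @param n_points samples along the ramp.
#' @param mu Poisson ratio.
#' @param noise_sd deflection noise (m).
#' @param seed integer seed.
#' @return Object of class `force_curve`: list(z, d, k_cant) plus the
#'   generating truth as attribute `truth`.
#' @export
gen_force_curve <- function(E_true = 1000, R_bead = 2.25e-6, k_cant = 0.03,
                            z_c = 1e-6, d_0 = 2e-8, z_max = 2.2e-6,
                            n_points = 400, mu = 0.5, noise_sd = 1e-9,
                            seed = 1) {
  if (E_true <= 0 || R_bead <= 0 || k_cant <= 0)
    stop("E_true, R_bead and k_cant must be > 0")
  if (z_max <= z_c) stop("infeasible geometry: ramp never reaches contact")
  z <- seq(0, z_max, length.out = n_points)
  C <- 4 * E_true * sqrt(R_bead) / (3 * (1 - mu^2))
  d_rel <- vapply(z, function(zi) {
    if (zi <= z_c) return(0)
    # solve k*dr = C*((zi - z_c) - dr)^(3/2), dr in [0, zi - z_c]
    stats::uniroot(function(dr) k_cant * dr - C * ((zi - z_c) - dr)^1.5,
                   lower = 0, upper = zi - z_c, tol = 1e-18)$root
  }, numeric(1))
  d <- d_0 + d_rel
  if (noise_sd > 0)
    d <- .with_seed(seed, d + stats::rnorm(length(d), 0, noise_sd))
  structure(list(z = z, d = d, k_cant = k_cant),
            class = "force_curve",
            truth = list(E_true = E_true, R_bead = R_bead, z_c = z_c,
                         d_0 = d_0, mu = mu, noise_sd = noise_sd,
                         seed = seed))
}

#' Generate paired Laurdan intensity images for a known GP map
#'
#' Inverse of the generalized-polarization formula: given the target GP
#' map and calibration factor `G`, emits intensity pairs whose noiseless
#' GP equals the target exactly: `I490 = I0`,
#' `I440 = G * I0 * (1 + gp) / (1 - gp)`.
#'
#' @param gp_true_map numeric array of target GP values, each in (-1, 1).
#' @param G calibration factor.
#' @param I0 base intensity of the 490 nm channel.
#' @param noise_sd additive Gaussian noise on both channels (0 = exact).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with arrays `I440` and `I490` shaped like `gp_true_map`.
#' @export
gen_gp_frames <- function(gp_true_map, G = 1, I0 = 100, noise_sd = 0,
                          seed = 1) {
  if (any(gp_true_map <= -1 | gp_true_map >= 1))
    stop("gp_true must lie strictly inside (-1, 1)")
  I490 <- gp_true_map * 0 + I0  # I0 in the shape of the input map
  I440 <- G * I0 * (1 + gp_true_map) / (1 - gp_true_map)
  if (noise_sd > 0) {
    .with_seed(seed, {
      I440 <- I440 + stats::rnorm(length(I440), 0, noise_sd)
      I490 <- I490 + stats::rnorm(length(I490), 0, noise_sd)
    })
  }
  list(I440 = I440, I490 = I490)
}
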