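# dSTORM localization-clustering pipeline: read -> filter -> merge ->
# homogenize -> cluster (DBSCAN) -> measure -> stratify. Every step is
# deterministic; reruns on identical inputs are bit-identical.

#' Pipeline configuration
#'
#' Defaults are the published analysis settings: strict localization
#' filters intensity in (300, 5000), uncertainty < 35 nm, sigma < 300 nm;
#' consecutive-blink merge radius 20 nm; global target blink density
#' 2e-4 nm^-2; DBSCAN eps = 20 nm and minpts = 30; cluster-area strata
#' bounds 25^2 pi and 50^2 pi nm^2.
#'
#' @param intensity_min,intensity_max exclusive intensity window (photons).
#' @param uncertainty_max exclusive bound on localization precision (nm).
#' @param sigma_max exclusive bound on fitted PSF width (nm).
#' @param merge_radius consecutive-event merge radius (nm).
#' @param target_density global target blink density (nm^-2).
#' @param eps,minpts DBSCAN neighborhood radius (nm) and minimum
#'   neighborhood size (counting the point itself).
#' @param a_small,a_large strata bounds (nm^2), `a_small < a_large`.
#' @param exclude_border_clusters drop clusters touching the ROI polygon
#'   (only possible when a polygon is available).
#' @export
smlm_config <- function(intensity_min = 300, intensity_max = 5000,
                        uncertainty_max = 35, sigma_max = 300,
                        merge_radius = 20, target_density = 2e-4,
                        eps = 20, minpts = 30,
                        a_small = 25^2 * pi, a_large = 50^2 * pi,
                        exclude_border_clusters = TRUE) {
  vals <- c(intensity_min = intensity_min, intensity_max = intensity_max,
            uncertainty_max = uncertainty_max, sigma_max = sigma_max,
            merge_radius = merge_radius, target_density = target_density,
            eps = eps, minpts = minpts, a_small = a_small, a_large = a_large)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  if (a_small >= a_large) stop("a_small must be < a_large")
  structure(c(as.list(vals),
              list(exclude_border_clusters = isTRUE(exclude_border_clusters))),
            class = "smlm_config")
}

# shoelace area of a polygon given as a 2-column matrix (open or closed)
.polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2 &&
      all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Localization table
#'
#' Blink records plus the segmented cell (ROI) area. Records keep their
#' input order. Frames are 1-based.
#'
#' @param data data.frame with numeric columns `frame`, `x`, `y`, `sigma`,
#'   `intensity`, `uncertainty` (nm / photons).
#' @param roi_area segmented cell area (nm^2), > 0. Derived from
#'   `roi_polygon` when omitted.
#' @param roi_polygon optional closed, non-self-intersecting polygon
#'   (2-column matrix or data.frame of x, y in nm). If both are given, the
#'   polygon area must match `roi_area` to 1e-6 relative.
#' @return Object of class `localization_table`.
#' @export
localization_table <- function(data, roi_area = NULL, roi_polygon = NULL) {
  need <- c("frame", "x", "y", "sigma", "intensity", "uncertainty")
  if (!all(need %in% names(data)))
    stop("missing mandatory columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  data <- as.data.frame(data)[need]
  for (cl in need) {
    if (!is.numeric(data[[cl]]))
      stop("column '", cl, "' must be numeric")
  }
  if (nrow(data)) {
    if (any(data$frame < 1 | data$frame != round(data$frame)))
      stop("frames must be integers >= 1 (frames are 1-based)")
    if (any(data$sigma < 0) || any(data$intensity < 0) ||
        any(data$uncertainty < 0))
      stop("sigma, intensity and uncertainty must be >= 0")
  }
  if (!is.null(roi_polygon)) {
    roi_polygon <- as.matrix(as.data.frame(roi_polygon)[, 1:2])
    p_area <- .polygon_area(roi_polygon)
    if (is.null(roi_area)) roi_area <- p_area
    else if (abs(p_area - roi_area) > 1e-6 * roi_area)
      stop("roi_polygon area differs from roi_area by more than 1e-6 relative")
  }
  if (is.null(roi_area) || !is.numeric(roi_area) || roi_area <= 0)
    stop("roi_area must be > 0 (give roi_area or roi_polygon)")
  structure(list(data = data, roi_area = as.numeric(roi_area),
                 roi_polygon = roi_polygon),
            class = "localization_table")
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table>  %d blinks, roi_area=%.4g nm^2%s\n",
              nrow(x$data), x$roi_area,
              if (is.null(x$roi_polygon)) "" else " (polygon)"))
  invisible(x)
}

# ThunderSTORM-style header aliases -> canonical names
.TS_ALIASES <- c(
  "frame" = "frame",
  "x" = "x", "x [nm]" = "x", "x_nm" = "x",
  "y" = "y", "y [nm]" = "y", "y_nm" = "y",
  "sigma" = "sigma", "sigma [nm]" = "sigma", "sigma_nm" = "sigma",
  "intensity" = "intensity", "intensity [photon]" = "intensity",
  "intensity [photons]" = "intensity",
  "uncertainty" = "uncertainty", "uncertainty [nm]" = "uncertainty",
  "uncertainty_xy [nm]" = "uncertainty")

#' Read a ThunderSTORM-style localization CSV
#'
#' Maps common header aliases (e.g. `"x [nm]"` to `x`), preserves row
#' order, and reports malformed (non-numeric) rows with their line
#' numbers. Extra columns are ignored.
#'
#' @param path CSV file with a header line.
#' @param roi_area,roi_polygon passed to [localization_table()].
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, roi_area = NULL, roi_polygon = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  nm <- tolower(trimws(names(raw)))
  canon <- unname(.TS_ALIASES[nm])
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  need <- c("frame", "x", "y", "sigma", "intensity", "uncertainty")
  if (!all(need %in% names(raw)))
    stop("missing mandatory columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  out <- raw[need]
  bad <- rep(FALSE, nrow(out))
  for (cl in need) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    bad <- bad | (is.na(v) & !(trimws(out[[cl]]) %in% c("NA")))
    out[[cl]] <- v
  }
  if (any(bad))
    stop("malformed (non-numeric) rows at lines: ",
         paste(which(bad) + 1L, collapse = ", "))  # +1 for the header line
  localization_table(out, roi_area = roi_area, roi_polygon = roi_polygon)
}

#' Write a localization table as ThunderSTORM-style CSV
#' @param table a [localization_table()].
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  out <- table$data
  names(out) <- c("frame", "x [nm]", "y [nm]", "sigma [nm]",
                  "intensity [photon]", "uncertainty [nm]")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter localizations
#'
#' Keeps records satisfying all four strict inequalities:
#' `intensity > intensity_min`, `intensity < intensity_max`,
#' `uncertainty < uncertainty_max`, `sigma < sigma_max`. Order is
#' preserved; the number of removed records is attached as attribute
#' `n_removed` and reported via `message()`.
#'
#' @param table a [localization_table()].
#' @param config an [smlm_config()].
#' @return Filtered [localization_table()].
#' @export
filter_localizations <- function(table, config = smlm_config()) {
  stopifnot(inherits(table, "localization_table"),
            inherits(config, "smlm_config"))
  d <- table$data
  keep <- d$intensity > config$intensity_min &
    d$intensity < config$intensity_max &
    d$uncertainty < config$uncertainty_max &
    d$sigma < config$sigma_max
  out <- table
  out$data <- d[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " localization(s) removed by filtering")
  out
}

#' Merge consecutive blinks of the same fluorophore
#'
#' Greedy chaining on the frame-sorted table: a chain is extended by the
#' nearest event in the next frame lying within `merge_radius` of the
#' chain's latest position. Each chain is replaced by one record at the
#' unweighted mean coordinates, with frame = first frame of the chain,
#' intensity summed, uncertainty = minimum, sigma = mean. Records not in
#' any chain are unchanged.
#'
#' @param table a [localization_table()].
#' @param merge_radius radius (nm).
#' @return Merged [localization_table()] (sorted by frame).
#' @export
merge_consecutive <- function(table, merge_radius = 20) {
  stopifnot(inherits(table, "localization_table"))
  d <- table$data
  if (!nrow(d)) return(table)
  d <- d[order(d$frame), , drop = FALSE]
  rownames(d) <- NULL
  n <- nrow(d)
  used <- rep(FALSE, n)
  by_frame <- split(seq_len(n), d$frame)
  frames <- as.numeric(names(by_frame))
  out <- vector("list", n)
  n_out <- 0L
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    chain <- i
    cx <- d$x[i]; cy <- d$y[i]; f <- d$frame[i]
    repeat {
      j <- match(f + 1, frames)
      if (is.na(j)) break
      cand <- by_frame[[j]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      dist2 <- (d$x[cand] - cx)^2 + (d$y[cand] - cy)^2
      k <- cand[which.min(dist2)]
      if (min(dist2) > merge_radius^2) break
      used[k] <- TRUE
      chain <- c(chain, k)
      cx <- d$x[k]; cy <- d$y[k]; f <- f + 1
    }
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(
      frame = d$frame[chain[1]],
      x = mean(d$x[chain]), y = mean(d$y[chain]),
      sigma = mean(d$sigma[chain]),
      intensity = sum(d$intensity[chain]),
      uncertainty = min(d$uncertainty[chain]))
  }
  res <- table
  res$data <- do.call(rbind, out[seq_len(n_out)])
  res$data <- res$data[order(res$data$frame), , drop = FALSE]
  rownames(res$data) <- NULL
  res
}

#' Homogenize the global blink density
#'
#' Keeps only blinks from the first `k` frames, choosing
#' `k = argmin_k |density(k) - target|` with
#' `density(k) = #(frame <= k) / roi_area`, ties broken toward smaller
#' `k`. When even the full record undershoots the target, all frames are
#' kept and a warning is raised (samples with few blinks are not
#' discarded).
#'
#' @param table a [localization_table()].
#' @param config an [smlm_config()] (uses `target_density`).
#' @return list with the truncated `table`, `k_frames_used` and
#'   `achieved_density` (nm^-2).
#' @export
homogenize_density <- function(table, config = smlm_config()) {
  stopifnot(inherits(table, "localization_table"),
            inherits(config, "smlm_config"))
  d <- table$data
  if (!nrow(d)) stop("cannot homogenize an empty table")
  kmax <- max(d$frame)
  counts <- tabulate(d$frame, nbins = kmax)
  dens <- cumsum(counts) / table$roi_area
  err <- abs(dens - config$target_density)
  k <- which.min(err)  # which.min takes the first, i.e. smallest k, on ties
  if (dens[kmax] < config$target_density) {
    k <- kmax
    warning("even the full record undershoots the target density (",
            signif(dens[kmax], 4), " < ", config$target_density,
            " nm^-2); keeping all frames")
  }
  out <- table
  out$data <- d[d$frame <= k, , drop = FALSE]
  rownames(out$data) <- NULL
  list(table = out, k_frames_used = k, achieved_density = dens[k])
}

#' DBSCAN clustering of blink coordinates
#'
#' Standard DBSCAN on the Euclidean (x, y) metric: a core point has at
#' least `minpts` neighbors within `eps` *counting itself*; clusters are
#' the connected components of core points under eps-adjacency, plus
#' border points (non-core within eps of a core), assigned to the
#' lowest-id neighboring cluster so membership is order-independent.
#' Noise is labeled -1.
#'
#' @param table a [localization_table()] (or a data.frame with x, y).
#' @param eps neighborhood radius (nm).
#' @param minpts minimum neighborhood size including the point itself.
#' @return integer vector of labels (1, 2, ... or -1 for noise).
#' @export
cluster_dbscan <- function(table, eps = 20, minpts = 30) {
  d <- if (inherits(table, "localization_table")) table$data else table
  n <- nrow(d)
  if (!n) return(integer(0))
  x <- d$x; y <- d$y
  eps2 <- eps^2
  # neighbor lists via a coarse grid bucketing to avoid the full n^2 matrix
  cell <- eps
  cx <- floor(x / cell); cy <- floor(y / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
    nb[[i]] <- cand  # includes i itself
  }
  core <- vapply(nb, length, integer(1)) >= minpts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (core[q] && labels[q] == -1L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  # border points join the lowest-id cluster among their CORE neighbors
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != -1L) next
    ids <- labels[nb[[i]][core[nb[[i]]]]]
    ids <- ids[ids > 0]
    if (length(ids)) labels[i] <- min(ids)
  }
  labels
}

# segment intersection test (proper or touching), for border detection
.seg_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

.points_in_polygon <- function(px, py, poly) {
  # even-odd ray casting; boundary points count as outside (conservative
  # for border exclusion)
  nv <- nrow(poly)
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    cnt <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      if ((poly[i, 2] > py[k]) != (poly[j, 2] > py[k])) {
        xint <- (poly[j, 1] - poly[i, 1]) * (py[k] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]
        if (px[k] < xint) cnt <- !cnt
      }
      j <- i
    }
    inside[k] <- cnt
  }
  inside
}

#' Measure DBSCAN clusters
#'
#' Per cluster: convex-hull area of the member coordinates (shoelace on
#' the hull), blink density = members / hull area, Feret diameter = the
#' longest distance between any two hull vertices, and a border flag.
#' Clusters with degenerate hulls (area < 1 nm^2) are flagged and
#' excluded from density statistics; clusters touching the ROI polygon
#' are excluded when configured (with only `roi_area` given, border
#' exclusion is skipped and logged).
#'
#' @param table a [localization_table()].
#' @param labels labels from [cluster_dbscan()].
#' @param config an [smlm_config()].
#' @return Object of class `cluster_set`: data.frame `clusters` with
#'   columns (cluster, n_blinks, hull_area, blink_density, feret_diameter,
#'   stratum, touches_border, degenerate, excluded) plus the member index
#'   list.
#' @export
measure_clusters <- function(table, labels, config = smlm_config()) {
  stopifnot(inherits(table, "localization_table"))
  d <- table$data
  ids <- sort(unique(labels[labels > 0]))
  members <- lapply(ids, function(id) which(labels == id))
  poly <- table$roi_polygon
  if (config$exclude_border_clusters && is.null(poly))
    message("no ROI polygon available: border exclusion skipped")
  rows <- lapply(seq_along(ids), function(k) {
    idx <- members[[k]]
    px <- d$x[idx]; py <- d$y[idx]
    h <- grDevices::chull(px, py)
    hx <- px[h]; hy <- py[h]
    area <- if (length(h) >= 3)
      .polygon_area(cbind(hx, hy)) else 0
    feret <- if (length(h) >= 2)
      sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2)) else 0
    degenerate <- area < 1
    touches <- FALSE
    if (!is.null(poly)) {
      pin <- .points_in_polygon(px, py, poly)
      touches <- !all(pin)
      if (!touches && length(h) >= 2) {
        np <- nrow(poly)
        hseq <- c(seq_along(h), 1L)
        for (a in seq_along(h)) {
          for (b in seq_len(np)) {
            b2 <- if (b == np) 1L else b + 1L
            if (.seg_intersect(c(hx[a], hy[a]),
                               c(hx[hseq[a + 1L]], hy[hseq[a + 1L]]),
                               poly[b, ], poly[b2, ])) {
              touches <- TRUE
              break
            }
          }
          if (touches) break
        }
      }
    }
    stratum <- if (area < config$a_small) "small"
    else if (area < config$a_large) "medium" else "large"
    data.frame(cluster = ids[k], n_blinks = length(idx),
               hull_area = area,
               blink_density = if (area > 0) length(idx) / area else NA_real_,
               feret_diameter = feret, stratum = stratum,
               touches_border = touches, degenerate = degenerate)
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n_blinks = integer(0),
               hull_area = numeric(0), blink_density = numeric(0),
               feret_diameter = numeric(0), stratum = character(0),
               touches_border = logical(0), degenerate = logical(0))
  clusters$excluded <- clusters$degenerate |
    (config$exclude_border_clusters & !is.null(poly) & clusters$touches_border)
  structure(list(clusters = clusters, members = members,
                 roi_area = table$roi_area, config = config),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set>  %d clusters (%d excluded)\n",
              nrow(x$clusters), sum(x$clusters$excluded)))
  invisible(x)
}

#' Stratified cluster summary
#'
#' Assigns strata by hull area against the half-open bounds
#' (small: area < a_small; medium: a_small <= area < a_large;
#' large: area >= a_large), then reports per stratum the cluster count,
#' the median blink density (median of an even count = mean of the
#' central pair) and the cluster density per ROI area in um^-2. Empty
#' strata report a missing (NA) median, not zero. Excluded clusters
#' (degenerate or border-touching) do not contribute.
#'
#' @param clusters a [measure_clusters()] result.
#' @param config an [smlm_config()].
#' @param roi_area ROI area (nm^2); defaults to the one recorded in
#'   `clusters`.
#' @return Object of class `strata_summary` with data.frame `strata`.
#' @export
stratify_and_summarize <- function(clusters, config = smlm_config(),
                                   roi_area = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (is.null(roi_area)) roi_area <- clusters$roi_area
  cl <- clusters$clusters[!clusters$clusters$excluded, , drop = FALSE]
  strata <- c("small", "medium", "large")
  rows <- lapply(strata, function(s) {
    sub <- cl[cl$stratum == s, , drop = FALSE]
    data.frame(stratum = s, n_clusters = nrow(sub),
               median_blink_density = if (nrow(sub))
                 stats::median(sub$blink_density) else NA_real_,
               clusters_per_um2 = nrow(sub) / roi_area * 1e6)
  })
  structure(list(strata = do.call(rbind, rows),
                 total_clusters = nrow(cl), roi_area = roi_area),
            class = "strata_summary")
}

#' @export
print.strata_summary <- function(x, ...) {
  cat("<strata_summary>\n")
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Run the full dSTORM cluster pipeline
#'
#' Fixed order: filter -> merge -> homogenize -> DBSCAN -> measure ->
#' stratify. Deterministic; rerunning with identical inputs and config is
#' bit-identical.
#'
#' @param table a [localization_table()].
#' @param config an [smlm_config()].
#' @return list with `table` (processed), `labels`, `clusters`
#'   (cluster_set), `summary` (strata_summary), `k_frames_used`,
#'   `achieved_density`.
#' @export
run_smlm_pipeline <- function(table, config = smlm_config()) {
  filt <- suppressMessages(filter_localizations(table, config))
  merged <- merge_consecutive(filt, config$merge_radius)
  hom <- homogenize_density(merged, config)
  labels <- cluster_dbscan(hom$table, eps = config$eps,
                           minpts = config$minpts)
  cs <- suppressMessages(measure_clusters(hom$table, labels, config))
  summ <- stratify_and_summarize(cs, config)
  list(table = hom$table, labels = labels, clusters = cs, summary = summ,
       k_frames_used = hom$k_frames_used,
       achieved_density = hom$achieved_density)
}
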