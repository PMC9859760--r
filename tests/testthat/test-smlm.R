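test_that("localization CSV round-trips through the ThunderSTORM dialect", {
  tbl <- loc_table(x = c(100, 200.5, 300), y = c(50, 60, 70.25),
                   frame = c(1, 2, 5), roi_area = 1e6)
  path <- tempfile(fileext = ".csv")
  write_localizations(tbl, path)
  back <- read_localizations(path, roi_area = 1e6)
  expect_equal(back$data, tbl$data)

  # header aliases map onto canonical names
  path2 <- tempfile(fileext = ".csv")
  writeLines(c(
    'frame,"x [nm]","y [nm]","sigma [nm]","intensity [photon]","uncertainty [nm]"',
    "1,10,20,150,1000,15"), path2)
  t2 <- read_localizations(path2, roi_area = 100)
  expect_identical(names(t2$data),
                   c("frame", "x", "y", "sigma", "intensity", "uncertainty"))
  expect_identical(t2$data$uncertainty, 15)

  # empty file with a header parses to an empty table
  path3 <- tempfile(fileext = ".csv")
  writeLines("frame,x [nm],y [nm],sigma [nm],intensity [photon],uncertainty [nm]",
             path3)
  expect_identical(nrow(read_localizations(path3, roi_area = 10)$data), 0L)

  # malformed rows are reported with line numbers
  path4 <- tempfile(fileext = ".csv")
  writeLines(c("frame,x [nm],y [nm],sigma [nm],intensity [photon],uncertainty [nm]",
               "1,10,20,150,1000,15",
               "2,oops,20,150,1000,15"), path4)
  expect_error(read_localizations(path4, roi_area = 10), "lines: 3")

  # missing mandatory columns are fatal
  path5 <- tempfile(fileext = ".csv")
  writeLines(c("frame,x [nm],y [nm]", "1,10,20"), path5)
  expect_error(read_localizations(path5, roi_area = 10), "missing mandatory")
})

test_that("the four localization filters are strict inequalities", {
  base <- data.frame(frame = 1:5, x = 1:5, y = 1:5,
                     sigma = c(100, 100, 100, 300, 100),
                     intensity = c(300, 1000, 5000, 1000, 1000),
                     uncertainty = c(10, 35, 10, 10, 10))
  tbl <- localization_table(base, roi_area = 1e6)
  out <- suppressMessages(filter_localizations(tbl))
  # one violation per row in rows 1-4 (intensity low bound, uncertainty,
  # intensity high bound, sigma); exactly the last row survives
  expect_identical(nrow(out$data), 1L)
  expect_identical(out$data$frame, 5L)
  expect_identical(attr(out, "n_removed"), 4L)
  # boundary record is removed (not strict-greater), near-boundary kept
  near <- localization_table(
    data.frame(frame = 1:2, x = 0, y = 0, sigma = c(100, 299),
               intensity = c(300, 301), uncertainty = c(10, 34.9)),
    roi_area = 1)
  out2 <- suppressMessages(filter_localizations(near))
  expect_identical(out2$data$frame, 2L)
})

test_that("consecutive-blink merging averages chains and leaves others alone", {
  # coincident chain over frames 1:3 collapses to one record
  t1 <- loc_table(x = c(0, 0, 0), y = c(5, 5, 5), frame = 1:3,
                  intensity = c(400, 500, 600), uncertainty = c(20, 10, 15),
                  roi_area = 1)
  m1 <- merge_consecutive(t1)
  expect_identical(nrow(m1$data), 1L)
  expect_identical(m1$data$frame, 1L)
  expect_identical(m1$data$intensity, 1500)
  expect_identical(m1$data$uncertainty, 10)

  # two events 30 nm apart in consecutive frames stay separate
  t2 <- loc_table(x = c(0, 30), y = c(0, 0), frame = 1:2, roi_area = 1)
  expect_identical(nrow(merge_consecutive(t2)$data), 2L)

  # chain (0,0)@f1 -> (10,0)@f2 merges at the mean (5,0)
  t3 <- loc_table(x = c(0, 10), y = c(0, 0), frame = 1:2, roi_area = 1)
  m3 <- merge_consecutive(t3)
  expect_identical(nrow(m3$data), 1L)
  expect_identical(m3$data$x, 5)
  expect_identical(m3$data$y, 0)

  # a frame gap breaks the chain
  t4 <- loc_table(x = c(0, 0), y = c(0, 0), frame = c(1, 3), roi_area = 1)
  expect_identical(nrow(merge_consecutive(t4)$data), 2L)
})

test_that("density homogenization picks the frame cutoff nearest the target", {
  # 1000 blinks uniform over 10 frames in 1e6 nm^2: k = 2 gives exactly
  # the target 2e-4 nm^-2
  tbl <- loc_table(x = runif(1000), y = runif(1000),
                   frame = rep(1:10, each = 100), roi_area = 1e6)
  h <- homogenize_density(tbl)
  expect_identical(h$k_frames_used, 2L)
  expect_identical(nrow(h$table$data), 200L)
  expect_equal(h$achieved_density, 2e-4)

  # exact hit in frame 1
  tbl2 <- loc_table(x = runif(200), y = runif(200),
                    frame = rep(1, 200), roi_area = 1e6)
  expect_identical(homogenize_density(tbl2)$k_frames_used, 1L)

  # sparse sample: keeps all frames and warns
  tbl3 <- loc_table(x = runif(50), y = runif(50),
                    frame = rep(1:5, each = 10), roi_area = 1e6)
  expect_warning(h3 <- homogenize_density(tbl3), "undershoots")
  expect_identical(h3$k_frames_used, 5L)
  expect_identical(nrow(h3$table$data), 50L)
})

test_that("DBSCAN counts the point itself and matches the reachability oracle", {
  # 29 coincident points: below minpts, all noise
  t29 <- loc_table(x = rep(1, 29), y = rep(2, 29), roi_area = 1)
  expect_true(all(cluster_dbscan(t29, eps = 20, minpts = 30) == -1))
  # 30 coincident points: one cluster (self-counting core definition)
  t30 <- loc_table(x = rep(1, 30), y = rep(2, 30), roi_area = 1)
  expect_true(all(cluster_dbscan(t30, eps = 20, minpts = 30) == 1))

  # two well-separated Gaussian blobs: exactly 2 clusters, no noise,
  # identical to the brute-force expansion oracle
  set.seed(9)
  d <- data.frame(
    x = c(rnorm(50, 0, 3), rnorm(50, 200, 3)),
    y = c(rnorm(50, 0, 3), rnorm(50, 0, 3)))
  tbl <- loc_table(d$x, d$y, roi_area = 1e6)
  lab <- cluster_dbscan(tbl, eps = 20, minpts = 30)
  expect_identical(sort(unique(lab)), c(1L, 2L))
  expect_true(all(lab != -1))
  expect_true(same_partition(lab, dbscan_oracle(tbl$data, 20, 30)))

  # randomized fixtures up to 500 points, several eps/minpts settings
  set.seed(33)
  for (i in 1:6) {
    n <- sample(80:500, 1)
    K <- sample(2:5, 1)
    centers <- matrix(runif(2 * K, 0, 600), ncol = 2)
    id <- sample.int(K, n, replace = TRUE)
    d <- data.frame(x = rnorm(n, centers[id, 1], 8),
                    y = rnorm(n, centers[id, 2], 8))
    tbl <- loc_table(d$x, d$y, roi_area = 1e6)
    eps <- sample(c(10, 20, 30), 1)
    minpts <- sample(c(5, 10, 30), 1)
    expect_true(same_partition(cluster_dbscan(tbl, eps, minpts),
                               dbscan_oracle(tbl$data, eps, minpts)))
  }
})

test_that("cluster measurements: hull area, Feret diameter and border flags", {
  # right triangle with 10 nm legs, padded with interior points so the
  # triangle passes minpts with a tiny eps
  tri <- data.frame(x = c(0, 10, 0), y = c(0, 0, 10))
  tbl <- loc_table(tri$x, tri$y, roi_area = 1e6)
  cs <- suppressMessages(measure_clusters(tbl, labels = c(1L, 1L, 1L)))
  expect_equal(cs$clusters$hull_area, 50)
  expect_equal(cs$clusters$feret_diameter, sqrt(200))
  expect_identical(cs$clusters$stratum, "small")

  # Feret of the two extreme points (0,0) and (3,4) is exactly 5
  seg <- loc_table(c(0, 1.5, 3), c(0, 2.2, 4), roi_area = 1)
  cs2 <- suppressMessages(measure_clusters(seg, labels = rep(1L, 3)))
  expect_equal(cs2$clusters$feret_diameter, 5)

  # border detection against an ROI polygon
  poly <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  inside <- loc_table(c(40, 60, 50), c(40, 40, 60), roi_polygon = poly)
  cs3 <- measure_clusters(inside, labels = rep(1L, 3))
  expect_false(cs3$clusters$touches_border)
  straddling <- loc_table(c(90, 110, 95), c(40, 40, 60), roi_polygon = poly)
  cs4 <- measure_clusters(straddling, labels = rep(1L, 3))
  expect_true(cs4$clusters$touches_border)
  expect_true(cs4$clusters$excluded)

  # degenerate (collinear) clusters are flagged and excluded
  line <- loc_table(c(0, 5, 10), c(0, 0, 0), roi_area = 1)
  cs5 <- suppressMessages(measure_clusters(line, labels = rep(1L, 3)))
  expect_true(cs5$clusters$degenerate)
})

test_that("strata use the published half-open area bounds and report medians", {
  mk <- function(areas, dens) {
    cl <- data.frame(cluster = seq_along(areas), n_blinks = 100,
                     hull_area = areas, blink_density = dens,
                     feret_diameter = 1,
                     stratum = ifelse(areas < 25^2 * pi, "small",
                                      ifelse(areas < 50^2 * pi, "medium",
                                             "large")),
                     touches_border = FALSE, degenerate = FALSE,
                     excluded = FALSE)
    structure(list(clusters = cl, members = list(), roi_area = 1e8,
                   config = smlm_config()), class = "cluster_set")
  }
  # area exactly 25^2 pi belongs to the medium stratum (left-closed)
  cs <- mk(c(25^2 * pi, 100, 50^2 * pi), c(1, 2, 3))
  expect_identical(cs$clusters$stratum, c("medium", "small", "large"))

  s <- stratify_and_summarize(mk(c(10, 20, 30, 9000, 9100),
                                 c(1, 2, 3, 5, 7)))
  med <- s$strata
  expect_identical(med$n_clusters, c(3L, 0L, 2L))
  expect_equal(med$median_blink_density[med$stratum == "small"], 2)
  expect_equal(med$median_blink_density[med$stratum == "large"], 6)  # even count
  expect_true(is.na(med$median_blink_density[med$stratum == "medium"]))
  expect_equal(med$clusters_per_um2[med$stratum == "small"], 3 / 1e8 * 1e6)
  expect_identical(sum(med$n_clusters), s$total_clusters)
})

test_that("the pipeline runs in a fixed order and is bit-identical on reruns", {
  gen <- gen_blinks(K = 4, blinks_per_cluster = 60, roi_side = 1500,
                    noise_rate = 0.05, out_of_filter_rate = 0.05, seed = 5)
  r1 <- suppressWarnings(run_smlm_pipeline(gen$table))
  r2 <- suppressWarnings(run_smlm_pipeline(gen$table))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$summary$strata, r2$summary$strata)

  # manual composition in the documented order reproduces the pipeline
  cfg <- smlm_config()
  filt <- suppressMessages(filter_localizations(gen$table, cfg))
  merged <- merge_consecutive(filt, cfg$merge_radius)
  hom <- suppressWarnings(homogenize_density(merged, cfg))
  lab <- cluster_dbscan(hom$table, cfg$eps, cfg$minpts)
  expect_identical(lab, r1$labels)
  expect_identical(hom$k_frames_used, r1$k_frames_used)
})
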