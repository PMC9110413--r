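loc_tab <- function(frame, x, y, intensity = 10, precision = 15,
                    interval = 20) {
  localization_table(frame = frame, x_nm = x, y_nm = y,
                     intensity = rep_len(intensity, length(frame)),
                     precision_nm = rep_len(precision, length(frame)),
                     frame_interval_ms = interval)
}

test_that("quality filtering applies the signal and precision cutoffs", {
  locs <- loc_tab(0:3, 1:4, 1:4, intensity = c(10, 2, 10, 10),
                  precision = c(10, 10, 40, 10))
  out <- quality_filter(locs)
  expect_equal(nrow(out), 2)
  expect_equal(out$x_nm, c(1, 4))
  all_pass <- loc_tab(0:2, 1:3, 1:3)
  expect_equal(nrow(quality_filter(all_pass)), 3)
  # count check on a mixed table
  set.seed(4)
  n <- 100
  bad <- sample(n, 30)
  prec <- rep(10, n); prec[bad] <- 50
  mixed <- loc_tab(seq_len(n) - 1, rnorm(n), rnorm(n), precision = prec)
  expect_equal(nrow(quality_filter(mixed)), 70)
})

test_that("persistent emitters are flagged as fiducials and removed", {
  truth <- ground_truth(
    aggregates = data.frame(shape = "blob", x_nm = 3000, y_nm = 3000,
                            size_nm = 80, orientation = 0),
    fiducials = data.frame(x_nm = 500, y_nm = 500),
    seed = 8)
  locs <- gen_smlm_stream(truth, emitter_model(precision_nm = 10),
                          n_frames = 700, n_bursts = 10L)
  res <- detect_fiducials(locs)
  expect_equal(nrow(res$fiducials), 1)
  expect_equal(res$fiducials$x_nm, 500, tolerance = 2)
  expect_gt(res$fiducials$n_frames, 500)
  expect_false(any(abs(res$locs$x_nm - 500) < 50))
  # a 100-frame emitter is retained
  short <- loc_tab(0:99, rep(100, 100), rep(100, 100))
  res2 <- detect_fiducials(short)
  expect_equal(nrow(res2$fiducials), 0)
  expect_equal(nrow(res2$locs), 100)
  empty <- loc_tab(integer(), numeric(), numeric())
  res3 <- detect_fiducials(empty)
  expect_equal(nrow(res3$fiducials), 0)
  expect_equal(nrow(res3$locs), 0)
})

test_that("burst grouping follows the staged DBSCAN contract", {
  # 2 isolated localizations 100 nm apart: spatial minpts unmet
  two <- loc_tab(c(0, 1), c(0, 100), c(0, 0))
  expect_equal(nrow(group_bursts(two)), 0)
  # 5 localizations within 10 nm in frames 10-14 -> one burst of 5
  five <- loc_tab(10:14, c(0, 4, 8, 2, 6), rep(0, 5))
  b <- group_bursts(five)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_locs, 5)
  expect_equal(b$start_frame, 10)
  expect_equal(b$end_frame, 14)
  # same site active in frames 10-14 and 600-604 -> two bursts
  revisit <- loc_tab(c(10:14, 600:604), rep(c(0, 4, 8, 2, 6), 2), rep(0, 10))
  b2 <- group_bursts(revisit)
  expect_equal(nrow(b2), 2)
  expect_equal(sort(b2$start_frame), c(10, 600))
})

test_that("staged grouping equals the brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(50:300, 1)
    # clumped point process: sites with bursts plus uniform noise
    n_sites <- sample(3:8, 1)
    sx <- runif(n_sites, 0, 2000); sy <- runif(n_sites, 0, 2000)
    frame <- integer(0); x <- numeric(0); y <- numeric(0)
    while (length(x) < n) {
      s <- sample(n_sites, 1)
      f0 <- sample(0:500, 1)
      dur <- sample(1:4, 1)
      frame <- c(frame, f0:(f0 + dur - 1))
      x <- c(x, sx[s] + rnorm(dur, 0, 8))
      y <- c(y, sy[s] + rnorm(dur, 0, 8))
    }
    keep <- seq_len(n)
    locs <- loc_tab(frame[keep], x[keep], y[keep])
    got <- burst_member_sets(group_bursts(locs))
    want <- key_member_sets(oracle_bursts(locs))
    expect_identical(got, want)
  }
})

test_that("burst clustering respects the minimum burst count and epsilon", {
  co <- function(n, cx, cy, r = 50) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    data.frame(id = seq_len(n), x_nm = cx + r * cos(th),
               y_nm = cy + r * sin(th))
  }
  b19 <- co(19, 0, 0)
  expect_length(cluster_bursts(b19), 0)
  b25 <- co(25, 0, 0)
  cl <- cluster_bursts(b25)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_bursts, 25)
  btwo <- rbind(co(25, 0, 0), co(25, 1000, 1000))
  btwo$id <- seq_len(50)
  expect_length(cluster_bursts(btwo), 2)
})

test_that("density clustering labels match the oracle across parameters", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(30:150, 1)
    coords <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    eps <- sample(c(15, 40, 80), 1)
    minpts <- sample(2:5, 1)
    expect_identical(tauaggr:::dbscan_labels(coords, eps, minpts),
                     oracle_dbscan(coords, eps, minpts))
  }
  # 1-D temporal clustering too
  t <- c(0, 20, 40, 200, 220, 1000)
  expect_identical(tauaggr:::dbscan_labels(matrix(t, ncol = 1), 21, 2),
                   oracle_dbscan(matrix(t, ncol = 1), 21, 2))
})

test_that("shrinking epsilon never merges; raising min_bursts never adds", {
  set.seed(10)
  n <- 120
  coords <- cbind(runif(n, 0, 800), runif(n, 0, 800))
  lab_wide <- tauaggr:::dbscan_labels(coords, 100, 3)
  lab_narrow <- tauaggr:::dbscan_labels(coords, 50, 3)
  # every narrow cluster is contained in one wide cluster
  for (k in seq_len(max(lab_narrow)))
    expect_length(unique(lab_wide[lab_narrow == k]), 1)
  b <- data.frame(id = seq_len(n), x_nm = coords[, 1], y_nm = coords[, 2])
  expect_gte(length(cluster_bursts(b, 100, 5)),
             length(cluster_bursts(b, 100, 15)))
})

test_that("cluster skeleton lengths recover the generating geometry", {
  # degenerate: coincident bursts
  cl0 <- list(x_nm = rep(100, 30), y_nm = rep(100, 30))
  expect_equal(as.numeric(cluster_length(cl0)), 0)
  # bursts along a 500 nm segment
  set.seed(11)
  u <- runif(250, -250, 250)
  cl1 <- list(x_nm = 3000 + u * cos(0.6) + rnorm(250, 0, 8),
              y_nm = 3000 + u * sin(0.6) + rnorm(250, 0, 8))
  l1 <- as.numeric(cluster_length(cl1))
  expect_lt(abs(l1 - 500) / 500, 0.15)
  # L-shape with 300 + 400 nm arms
  arm1 <- runif(150, 0, 300)
  arm2 <- runif(200, 0, 400)
  cl2 <- list(x_nm = c(arm1, rep(0, 200)) + rnorm(350, 0, 6) + 2000,
              y_nm = c(rep(0, 150), arm2) + rnorm(350, 0, 6) + 2000)
  l2 <- as.numeric(cluster_length(cl2))
  expect_lt(abs(l2 - 700) / 700, 0.15)
})

test_that("rendering conserves localization counts", {
  locs <- loc_tab(0:4, c(5, 12, 40, 41, 80), c(3, 9, 22, 22, 60))
  img <- render_superres(locs, pixel_nm = 10)
  expect_equal(sum(img), 5)
  img20 <- render_superres(locs, pixel_nm = 20)
  expect_equal(sum(img20), 5)
  one <- loc_tab(0, 5, 5)
  expect_equal(sum(render_superres(one, 10) > 0), 1)
})

test_that("cluster size fractions partition correctly", {
  f <- cluster_size_fractions(c(190, 280, 1450))
  expect_equal(f$below_500_nm, 2 / 3)
  expect_equal(sum(f$partition), 1)
  expect_equal(cluster_size_fractions(c(100, 200))$below_500_nm, 1)
  expect_error(cluster_size_fractions(numeric(0)), "empty")
})

test_that("the full pipeline runs end to end on a mixed scene", {
  truth <- ground_truth(
    aggregates = data.frame(shape = c("segment", "blob"),
                            x_nm = c(2000, 5000), y_nm = c(2000, 5000),
                            size_nm = c(600, 80),
                            orientation = c(0.9, 0)),
    fiducials = data.frame(x_nm = 500, y_nm = 6000),
    seed = 12)
  locs <- gen_smlm_stream(truth, emitter_model(precision_nm = 15),
                          n_frames = 10000, n_bursts = c(300L, 60L))
  res <- smlm_analyze(locs)
  expect_s3_class(res, "smlm_result")
  expect_equal(nrow(res$fiducials), 1)
  expect_equal(nrow(res$clusters), 2)
  expect_true(all(res$clusters$n_bursts >= 20))
  lens <- sort(res$clusters$length_nm)
  expect_lt(lens[1], 300)                       # the blob
  expect_lt(abs(lens[2] - 600) / 600, 0.25)     # the fibril
})
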