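make_cluster_slide <- function(centers, n_each = 5, sd_um = 30, seed = 1,
                               width = 20000, height = 20000) {
  set.seed(seed)
  x <- numeric(); y <- numeric()
  for (k in seq_len(nrow(centers))) {
    x <- c(x, rnorm(n_each, centers[k, 1], sd_um))
    y <- c(y, rnorm(n_each, centers[k, 2], sd_um))
  }
  detection_table(x, y, label = "TB", source = "DETECTOR")
}

test_that("an all-zero density map yields no hotspots (with a warning)", {
  g <- slide_geometry(2000, 2000, 8)
  map <- compute_density(detection_table(numeric(), numeric()), geometry = g)
  expect_warning(h <- select_hotspots(map, k = 10), "exhausted")
  expect_identical(nrow(h), 0L)
})

test_that("one tight cluster is captured whole by the rank-1 hotspot", {
  set.seed(3)
  d <- detection_table(2000 + runif(12, -50, 50), 2000 + runif(12, -50, 50),
                       label = "TB", source = "DETECTOR")
  map <- compute_density(d, radius_um = 500)
  h <- select_hotspots(map, k = 1)
  expect_identical(h$count, 12L)
  expect_true(all(point_in_circle(d$x_um, d$y_um,
                                  circle(h$cx_um, h$cy_um, 500))))
  oracle <- densest_disk_oracle(d$x_um, d$y_um, 500, geometry = map$geometry)
  expect_identical(h$count, oracle$count)
  expect_equal(c(h$cx_um, h$cy_um), c(oracle$circle$cx, oracle$circle$cy))
})

test_that("well-separated clusters yield the default ten hotspots", {
  centers <- as.matrix(expand.grid(x = seq(2000, 18000, by = 4000),
                                   y = seq(2000, 10000, by = 4000)))[1:15, ]
  d <- make_cluster_slide(centers)
  map <- compute_density(d, geometry = slide_geometry(20000, 12000, 8))
  h <- select_hotspots(map)
  expect_identical(nrow(h), 10L)
  expect_identical(h$rank, 1:10)
  expect_true(all(diff(h$count) <= 0))
})

test_that("rank-1 equals the densest-disk scan and centers stay a radius apart", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- sample(30:150, 1)
    d <- detection_table(runif(n, 0, 6000), runif(n, 0, 6000),
                         label = "TB", source = "DETECTOR")
    g <- slide_geometry(6000, 6000, 8)
    map <- compute_density(d, geometry = g, radius_um = 500)
    h <- suppressWarnings(select_hotspots(map, k = 10))
    oracle <- densest_disk_oracle(d$x_um, d$y_um, 500, geometry = g)
    expect_identical(h$count[1], oracle$count)
    expect_identical(max(map$counts), oracle$count)
    expect_equal(c(h$cx_um[1], h$cy_um[1]),
                 c(oracle$circle$cx, oracle$circle$cy))
    if (nrow(h) > 1) {
      dmat <- as.matrix(dist(cbind(h$cx_um, h$cy_um)))
      expect_true(all(dmat[upper.tri(dmat)] >= 500))
      expect_true(all(diff(h$count) <= 0))
    }
  }
})

test_that("remove-and-recount suppression also returns separated hotspots", {
  set.seed(21)
  d <- detection_table(runif(80, 0, 5000), runif(80, 0, 5000),
                       label = "TB", source = "DETECTOR")
  g <- slide_geometry(5000, 5000, 8)
  map <- compute_density(d, geometry = g, radius_um = 400)
  h <- suppressWarnings(select_hotspots(map, k = 5, detections = d,
                                        recount = TRUE))
  expect_identical(h$count[1], max(map$counts))
  if (nrow(h) > 1) {
    dmat <- as.matrix(dist(cbind(h$cx_um, h$cy_um)))
    expect_true(all(dmat[upper.tri(dmat)] >= 400))
  }
})

test_that("in-circle counting matches a linear scan", {
  expect_identical(count_in_circle(detection_table(numeric(), numeric()),
                                   circle(0, 0, 500)), 0L)
  d <- detection_table(rep(10, 7), rep(20, 7), label = "TB",
                       source = "DETECTOR")
  expect_identical(count_in_circle(d, circle(10, 20, 100)), 7L)
  set.seed(4)
  d <- detection_table(runif(300, 0, 4000), runif(300, 0, 4000),
                       label = sample(c("TB", "NON_TB"), 300, replace = TRUE),
                       source = "DETECTOR")
  cc <- circle(2000, 2000, 700)
  manual <- sum((d$x_um - 2000)^2 + (d$y_um - 2000)^2 <= 700^2 &
                  d$label == "TB")
  expect_identical(count_in_circle(d, cc), as.integer(manual))
})

test_that("manual-vs-auto matching reports the lowest matching rank", {
  r <- 500
  manual <- circle(5000, 5000, r)
  mk <- function(cx, cy, rank) data.frame(rank = rank, cx_um = cx, cy_um = cy,
                                          radius_um = r, count = 50 - rank,
                                          source = "AUTO")
  # concentric rank 1
  m <- match_hotspots(manual, mk(5000, 5000, 1))
  expect_equal(m$dice, 1.0)
  expect_true(m$top3_match && m$top10_match && !m$no_match)
  # all autos far away
  far <- do.call(rbind, lapply(1:10, function(k) mk(5000 + 2 * r + 100 * k,
                                                    5000, k)))
  m <- match_hotspots(manual, far)
  expect_true(m$no_match && !m$top10_match)
  expect_true(is.na(m$matched_rank))
  # match only at rank 7: ranks 1-6 beyond 2r, rank 7 within the 0.7 distance
  dstar <- dice_to_distance(0.7, r)
  auto <- rbind(do.call(rbind, lapply(1:6, function(k)
    mk(5000 + 2 * r + 50 * k, 5000, k))),
    mk(5000 + dstar - 1, 5000, 7),
    mk(5000, 5000, 8))  # better overlap at worse rank is ignored
  m <- match_hotspots(manual, auto)
  expect_identical(m$matched_rank, 7)
  expect_true(m$top10_match && !m$top3_match && !m$no_match)
  # empty auto list
  m <- match_hotspots(manual, mk(1, 1, 1)[0, ])
  expect_true(m$no_match)
})
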