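test_that("simulation is exactly reproducible under a fixed seed", {
  cfg <- simulation_config(width_mm = 5, height_mm = 5, seed = 71)
  a <- simulate_slide(cfg)
  b <- simulate_slide(cfg)
  expect_identical(a$true_buds, b$true_buds)
  expect_identical(a$teacher_detections, b$teacher_detections)
  expect_identical(a$manual_annotations, b$manual_annotations)
  expect_identical(a$planted_hotspot, b$planted_hotspot)
  # and byte-identical once serialized
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_detections(a$teacher_detections, f1)
  write_detections(b$teacher_detections, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  c <- simulate_slide(simulation_config(width_mm = 5, height_mm = 5,
                                        seed = 72))
  expect_false(identical(a$true_buds, c$true_buds))
})

test_that("a single cluster with all rates zero gives exactly its buds", {
  cfg <- simulation_config(width_mm = 5, height_mm = 5, background_rate = 0,
                           distractor_rate = 0, teacher_fp_rate = 0,
                           manual_fraction = 0,
                           clusters = list(list(center_um = c(2500, 2500),
                                                sd_um = 50, n_buds = 12)),
                           seed = 73)
  sl <- simulate_slide(cfg)
  expect_identical(nrow(sl$true_buds), 12L)
  expect_identical(nrow(sl$distractors), 0L)
  expect_identical(sl$planted_count, 12L)
  expect_true(all(point_in_circle(sl$true_buds$x_um, sl$true_buds$y_um,
                                  sl$planted_hotspot)))
})

test_that("background counts follow the configured Poisson intensity", {
  # 2 buds/mm^2 over 100 mm^2: mean 200; check the mean over simulations
  # lands inside a 99% normal band for the mean of n draws
  n_sim <- 40
  counts <- vapply(seq_len(n_sim), function(s) {
    cfg <- simulation_config(background_rate = 2, clusters = list(),
                             distractor_rate = 0, teacher_fp_rate = 0,
                             manual_fraction = 0, seed = 1000 + s)
    nrow(simulate_slide(cfg, oracle_spacing_um = 64)$true_buds)
  }, numeric(1))
  expect_gt(mean(counts), 200 - 2.576 * sqrt(200 / n_sim))
  expect_lt(mean(counts), 200 + 2.576 * sqrt(200 / n_sim))
})

test_that("the planted hotspot is the brute-force densest disk", {
  for (s in 1:5) {
    sl <- simulate_slide(simulation_config(width_mm = 4, height_mm = 4,
                                           background_rate = 3, seed = s))
    # independent confirmation on the same grid via the density map maximum
    map <- compute_density(sl$true_buds, geometry = sl$geometry)
    expect_identical(sl$planted_count, max(map$counts))
    expect_identical(
      count_in_circle(sl$true_buds, sl$planted_hotspot), sl$planted_count)
  }
})

test_that("teacher likelihoods separate true buds from false positives only partly", {
  sl <- simulate_slide(simulation_config(seed = 74, teacher_fp_rate = 2))
  td <- sl$teacher_detections
  lk_true <- td$likelihood[td$truth == "TRUE_BUD"]
  lk_fp <- td$likelihood[td$truth == "FALSE_POSITIVE"]
  expect_gt(mean(lk_true), mean(lk_fp))
  # Beta(8,2) vs Beta(2,8): the 0.80 cut keeps most but not all true buds
  expect_gt(mean(lk_true > 0.8), 0.2)
  expect_lt(mean(lk_true > 0.8), 0.9)
  expect_lt(mean(lk_fp > 0.8), 0.1)
})

test_that("rendered tiles roundtrip through deconvolution and masking", {
  base_cfg <- function(clusters, seed) simulation_config(
    width_mm = 0.5, height_mm = 0.5, background_rate = 0,
    distractor_rate = 0, teacher_fp_rate = 0, manual_fraction = 0,
    clusters = clusters, seed = seed)
  # zero objects: uniform white (up to the bounded noise)
  empty <- simulate_slide(base_cfg(list(), 75), oracle_spacing_um = 16)
  expect_error(render_ihc(empty, spacing_um = 2, blob_radius_um = 3),
               "blob_radius_um")
  tile <- render_ihc(empty, spacing_um = 2, noise = 2)
  expect_gte(min(tile$pixels), 250)
  # well-separated buds are recovered exactly, over a 10x DAB intensity range
  spread <- list(list(center_um = c(100, 100), sd_um = 1, n_buds = 1),
                 list(center_um = c(400, 120), sd_um = 1, n_buds = 1),
                 list(center_um = c(250, 380), sd_um = 1, n_buds = 1))
  sl <- simulate_slide(base_cfg(spread, 76), oracle_spacing_um = 16)
  for (od in c(0.2, 0.6, 2.0)) {
    tile <- render_ihc(sl, spacing_um = 2, blob_radius_um = 8, dab_od = od)
    msk <- dab_mask(deconvolve(tile))
    expect_identical(nrow(msk$components), 3L)
    # centroids land on the planted buds
    near <- vapply(seq_len(3), function(i) min(
      sqrt((msk$components$cx_um - sl$true_buds$x_um[i])^2 +
             (msk$components$cy_um - sl$true_buds$y_um[i])^2)), numeric(1))
    expect_true(all(near < 4))
  }
  # hematoxylin-only distractors produce no DAB components
  dis <- simulate_slide(base_cfg(list(), 77))
  dis$distractors <- detection_table(c(150, 350), c(150, 350),
                                     label = "NON_TB", source = "DETECTOR")
  tile <- render_ihc(dis, spacing_um = 2)
  expect_identical(nrow(dab_mask(deconvolve(tile))$components), 0L)
})
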