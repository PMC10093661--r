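test_that("likelihood filtering is strictly greater-than and manuals bypass it", {
  d <- detection_table(1:4 * 10, 1:4 * 10,
                       likelihood = c(0.80, 0.95, 0.10, NA),
                       label = c("UNLABELED", "UNLABELED", "UNLABELED", "TB"),
                       source = c("DETECTOR", "DETECTOR", "DETECTOR",
                                  "MANUAL"))
  kept <- filter_by_likelihood(d, 0.80)
  expect_identical(nrow(kept), 2L)
  expect_identical(kept$x_um, c(20, 40))          # 0.80 exactly is rejected
  # retained-set size is monotone non-increasing in the threshold
  set.seed(51)
  d <- detection_table(runif(200), runif(200), likelihood = runif(200))
  sizes <- vapply(seq(0.05, 0.95, by = 0.05), function(th)
    nrow(filter_by_likelihood(d, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the DAB mask gate keeps on-mask candidates, rejects background", {
  m <- matrix(FALSE, 20, 20)
  m[5:10, 5:10] <- TRUE                  # component: x,y in (4,10) um at 1 um/px
  msk <- dab_mask(m * 1, spacing_um = 1, od_threshold = 0.5,
                  min_area_um2 = 0, opening_radius_px = 0)
  d <- detection_table(c(7, 18, 12.6, 7, 50),
                       c(7, 18, 7, 2, 7),
                       likelihood = 0.9,
                       label = c(rep("UNLABELED", 4), "TB"),
                       source = c(rep("DETECTOR", 4), "MANUAL"))
  strict <- filter_by_dab(d, msk, tolerance_um = 0)
  expect_identical(strict$x_um, c(7, 50))         # on-mask + manual bypass
  rej <- attr(strict, "rejected")
  expect_identical(nrow(rej), 3L)
  expect_true(all(rej$reason == "outside_dab_mask"))
  # the candidate 3 um off the component edge passes with 5 um tolerance
  tol <- filter_by_dab(d, msk, tolerance_um = 5)
  expect_true(12.6 %in% tol$x_um)
  expect_false(18 %in% tol$x_um)
  # (7, 2) is ~2.5 um from the nearest positive pixel center: out at 1 um
  tol1 <- filter_by_dab(d, msk, tolerance_um = 1)
  expect_false(any(tol1$x_um == 7 & tol1$y_um == 2))
  # out-of-extent detections are rejected with a logged reason
  rej <- attr(filter_by_dab(detection_table(-5, 3, likelihood = 1), msk),
              "rejected")
  expect_identical(rej$reason, "out_of_extent")
  # retained set grows (weakly) with tolerance
  sizes <- vapply(c(0, 1, 3, 6, 12), function(t)
    nrow(filter_by_dab(d, msk, tolerance_um = t)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("merging assigns certainties 1.0 / 0.80 and drops colliding pseudo-labels", {
  cfg <- pseudolabel_config()
  set.seed(52)
  manual <- detection_table(runif(5, 0, 1000), runif(5, 0, 1000),
                            label = "TB", source = "MANUAL")
  pseudo <- detection_table(runif(18, 2000, 3000), runif(18, 0, 1000),
                            likelihood = 0.9, source = "DETECTOR")
  # two pseudo-labels sit on manual annotations (within the collision radius)
  pseudo <- rbind(pseudo,
                  detection_table(manual$x_um[1:2] + 3, manual$y_um[1:2],
                                  likelihood = 0.95, source = "DETECTOR"))
  manifest <- merge_and_weight(pseudo, manual, cfg)
  expect_identical(nrow(manifest), 23L)
  expect_identical(sum(manifest$certainty == 1.0), 5L)
  expect_identical(sum(manifest$certainty == 0.80), 18L)
  expect_identical(attr(manifest, "n_collisions"), 2L)
  expect_true(all(manifest$label[manifest$source == "PSEUDO"] == "TB"))
  expect_true(all(manifest$patch_side_px == 512L))
  # disjoint sets simply add up
  far <- detection_table(5000, 5000, likelihood = 1, source = "DETECTOR")
  expect_identical(nrow(merge_and_weight(far, manual, cfg)), 6L)
  # pseudo exactly on a manual point is dropped
  dup <- detection_table(manual$x_um[1], manual$y_um[1], likelihood = 1,
                         source = "DETECTOR")
  expect_identical(nrow(merge_and_weight(dup, manual, cfg)), 5L)
})

test_that("the retained set is independent of input row order", {
  set.seed(53)
  d <- detection_table(runif(100, 0, 500), runif(100, 0, 500),
                       likelihood = runif(100))
  keyset <- function(x) sort(paste(x$x_um, x$y_um))
  perm <- d[sample(nrow(d)), ]
  expect_identical(keyset(filter_by_likelihood(d, 0.5)),
                   keyset(filter_by_likelihood(perm, 0.5)))
  m <- matrix(runif(2500) > 0.5, 50, 50)
  msk <- dab_mask(m * 1, spacing_um = 10, od_threshold = 0.5,
                  min_area_um2 = 0, opening_radius_px = 0)
  expect_identical(keyset(filter_by_dab(d, msk)),
                   keyset(filter_by_dab(perm, msk)))
})

test_that("a perfect teacher yields exactly the planted buds plus manuals", {
  sl <- simulate_slide(simulation_config(width_mm = 4, height_mm = 4,
                                         seed = 54))
  # idealized teacher: likelihood 1 at true buds, noise strictly below 0.8
  n_noise <- 30
  set.seed(55)
  teacher <- detection_table(
    c(sl$true_buds$x_um, runif(n_noise, 0, 4000)),
    c(sl$true_buds$y_um, runif(n_noise, 0, 4000)),
    likelihood = c(rep(1, nrow(sl$true_buds)), runif(n_noise, 0, 0.79)),
    source = "DETECTOR")
  manual <- detection_table(6000, 6000, label = "TB", source = "MANUAL")
  manifest <- build_training_manifest(teacher, manual,
                                      config = pseudolabel_config())
  expect_identical(nrow(manifest), nrow(sl$true_buds) + 1L)
  expect_setequal(manifest$x_um, c(sl$true_buds$x_um, 6000))
})
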