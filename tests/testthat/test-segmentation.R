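test_that("contrast stretch maps the percentile window to [0, 1]", {
  cfg0 <- pipeline_config(stretch_low = 0, stretch_high = 100,
                          smooth_sigma = 0)
  # constant image: documented degenerate contract, all zeros
  expect_equal(stretch_and_smooth(matrix(7, 5, 5), cfg0), matrix(0, 5, 5))
  # two-level image: endpoints map to 0 and 1
  img <- matrix(c(rep(10, 20), rep(50, 5)), 5, 5)
  out <- stretch_and_smooth(img, cfg0)
  expect_true(all(out[img == 10] == 0) && all(out[img == 50] == 1))
  # ramp with 1-99 stretch: clipping outside the window, linear inside
  ramp <- matrix(seq(0, 1, length.out = 401), 401, 3)
  cfg <- pipeline_config(stretch_low = 1, stretch_high = 99, smooth_sigma = 0)
  out <- stretch_and_smooth(ramp, cfg)
  q <- quantile(ramp, c(0.01, 0.99), names = FALSE)
  manual <- pmin(pmax((ramp - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out, manual)
  expect_true(all(out[ramp <= q[1]] == 0) && all(out[ramp >= q[2]] == 1))
})

test_that("composite equals the per-pixel maximum oracle", {
  z <- matrix(0, 6, 6)
  ch <- withr::with_seed(31, matrix(runif(36), 6, 6))
  expect_equal(composite_image(list(ch, z, z, z)), ch)
  expect_equal(composite_image(list(z, z, z, z)), z)
  withr::with_seed(32, {
    for (k in 1:20) {
      stack <- lapply(1:4, function(i)
        matrix(sample(0:2, 64, replace = TRUE) / 2, 8, 8))
      expect_equal(composite_image(stack), ref_composite_max(stack))
    }
  })
  expect_error(composite_image(list(z, z, z, matrix(0, 3, 3))), "shapes")
})

test_that("background threshold sits just above the background peak", {
  vals <- withr::with_seed(33, c(rnorm(5000, 100, 5), rnorm(500, 1000, 50)))
  gray <- matrix(vals, 50)
  thr <- background_threshold(gray, pipeline_config(threshold_offset_k = 3))
  expect_gt(thr, 100); expect_lt(thr, 1000)
  # k = 3 with background sd 5: offset roughly 2-4 sd above the mode
  expect_gt(thr, 100 - 5 + 2 * 5); expect_lt(thr, 100 + 5 + 4 * 5)
  thr0 <- background_threshold(gray, pipeline_config(threshold_offset_k = 1e-9))
  expect_lt(abs(thr0 - 100), 10)  # ~ the background mode itself
  expect_lt(thr0, thr)
  # noiseless two-level image stays separable
  img2 <- matrix(c(rep(0, 90), rep(1, 10)), 10)
  thr2 <- background_threshold(img2, pipeline_config())
  expect_gt(thr2, 0); expect_lt(thr2, 1)
  expect_error(background_threshold(matrix(1, 4, 4)), "constant")
})

test_that("erosion separates touching disks and expansion stays in the mask", {
  # single disk: one label, regrown exactly to the geodesically reachable disk
  m1 <- disk_mask(40, 40, 20, 20, 10)
  lab <- separate_and_label(m1, pipeline_config(erosion_cycles = 3))
  expect_equal(max(lab), 1)
  expect_equal(lab != 0, m1)
  # two disks fused by a narrow neck: enough cycles break it into 2 labels
  m2 <- disk_mask(40, 40, 20, 12, 8) | disk_mask(40, 40, 20, 27, 8)
  expect_equal(
    max(stacksr:::label_components_cpp(matrix(as.integer(m2), 40), 8L)), 1)
  lab2 <- separate_and_label(m2, pipeline_config(erosion_cycles = 4))
  expect_equal(max(lab2), 2)
  expect_true(all(m2[lab2 != 0]))          # containment in the original mask
  expect_gt(sum(lab2 == 1), 50); expect_gt(sum(lab2 == 2), 50)
  # over-erosion: a tiny object yields no label
  m3 <- matrix(0, 20, 20); m3[9:11, 9:11] <- 1
  expect_equal(max(separate_and_label(m3, pipeline_config(erosion_cycles = 3))), 0)
  # empty mask: empty labeling, no error
  expect_equal(max(separate_and_label(matrix(0, 8, 8), pipeline_config())), 0)
})

test_that("component labeling matches the stack-walk reference", {
  withr::with_seed(41, {
    for (k in 1:40) {
      m <- random_mask(sample(8:24, 1), sample(8:24, 1))
      for (conn in c(4L, 8L)) {
        got <- label_components_cpp(m, conn)
        ref <- ref_label(m, conn)
        expect_identical(got, ref)
      }
    }
  })
})

test_that("geodesic expansion matches the matrix-shift reference", {
  withr::with_seed(42, {
    for (k in 1:60) {
      m <- random_mask(sample(8:32, 1), sample(8:32, 1))
      seeds <- label_components_cpp(
        matrix(as.integer(EBImage::erode(m, EBImage::makeBrush(3, "box")) != 0),
               nrow(m)), 8L)
      got <- geodesic_expand_cpp(seeds, m, 4L)
      ref <- ref_geodesic_expand(seeds, m, 4)
      expect_identical(got, ref)
      expect_true(all(m[got != 0] != 0))   # mask containment
      expect_true(all(got[seeds != 0] == seeds[seeds != 0]))  # seeds kept
    }
  })
})

test_that("object filtering enforces area and border rules", {
  labs <- matrix(0L, 20, 20)
  labs[1, 3:8] <- 1L                  # touches border
  labs[5:6, 5:6] <- 2L                # area 4
  labs[10:14, 10:14] <- 3L            # area 25
  cfg <- pipeline_config(min_object_px = 5, exclude_border = TRUE)
  out <- filter_objects(labs, cfg)
  expect_equal(sort(unique(as.integer(out))), c(0L, 1L))
  expect_true(all(out[labs == 3L] == 1L))   # survivor relabeled to 1
  # boundary of the area filter: area = min kept, area = min - 1 removed
  cfg4 <- pipeline_config(min_object_px = 4, exclude_border = FALSE)
  expect_true(any(filter_objects(labs, cfg4) != 0 & labs == 2L))
  cfg5 <- pipeline_config(min_object_px = 5, exclude_border = FALSE)
  expect_true(all(filter_objects(labs, cfg5)[labs == 2L] == 0L))
  # filtering never increases the object count
  expect_lte(max(out), max(labs))
})

test_that("measurements use original intensities and normalized contributions", {
  nr <- 40
  disk <- disk_mask(nr, nr, 20, 20, 8)
  labs <- matrix(0L, nr, nr); labs[disk] <- 1L
  mk <- function(v) matrix(100, nr, nr) + v * disk
  stack <- channel_stack(mk(0), mk(0), mk(0), mk(500))
  rec <- measure_cells(labs, stack)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$area, sum(disk))
  expect_equal(rec$mean_RED, 600)
  expect_equal(rec$centroid_row, 19, tolerance = 0.01)  # 0-based center
  expect_equal(c(rec$rel_CFP, rec$rel_GREEN, rec$rel_YFP, rec$rel_RED),
               c(0, 0, 0, 1))
  # all channels identical: symmetric quarter contributions
  st2 <- channel_stack(mk(500), mk(500), mk(500), mk(500))
  rec2 <- measure_cells(labs, st2)
  expect_equal(c(rec2$rel_CFP, rec2$rel_GREEN, rec2$rel_YFP, rec2$rel_RED),
               rep(0.25, 4))
  expect_equal(rec2$rel_CFP + rec2$rel_GREEN + rec2$rel_YFP + rec2$rel_RED, 1)
  # empty labeling: empty record list
  expect_equal(nrow(measure_cells(matrix(0L, nr, nr), stack)), 0)
  expect_error(measure_cells(matrix(0L, 8, 8), stack), "dimensions")
})

test_that("the full pipeline recovers a noise-free field deterministically", {
  sp <- scene_spec(field_size = c(360, 360), n_cells = 20, debris_count = 6,
                   noise_sd = 0, touching_pair_fraction = 0, seed = 51)
  pop <- fixed_population(rep("RFP", 20), rep(c("RFP", "eYFP"), 10))
  sc <- render_scene(sp, pop)
  res <- run_pipeline(sc$stack)
  expect_equal(nrow(res$cells), 20)
  # centroids within 2 px of ground truth
  truth <- sc$truth$cells
  for (i in seq_len(20)) {
    d <- sqrt((res$cells$centroid_row - truth$row[i])^2 +
                (res$cells$centroid_col - truth$col[i])^2)
    expect_lte(min(d), 2)
  }
  # determinism
  res2 <- run_pipeline(sc$stack)
  expect_identical(res$labels, res2$labels)
  expect_identical(res$cells, res2$cells)
  # QC records the stage trail
  expect_true(all(c("threshold", "n_objects_separated", "n_objects_final",
                    "config") %in% names(res$qc)))
  expect_gte(res$qc$n_objects_separated, res$qc$n_objects_final)
  # pure background field: constant composite, threshold error propagates
  bg <- render_scene(scene_spec(field_size = c(64, 64), n_cells = 0,
                                debris_count = 0, noise_sd = 0, seed = 52),
                     fixed_population(character(0), character(0)))
  expect_error(run_pipeline(bg$stack))
})
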