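test_that("detect_cells finds disjoint brown disks at their centers", {
  img <- array(1, c(120, 200, 3))  # white slide
  centers <- expand.grid(cx = c(25, 75, 125, 175), cy = c(30, 80))
  centers <- rbind(centers, data.frame(cx = c(25, 75), cy = c(55, 55)))
  for (i in seq_len(nrow(centers)))
    img <- draw_disk(img, centers$cx[i], centers$cy[i], radius = 5)
  det <- detect_cells(img, min_area_px2 = 30, max_area_px2 = 5000)
  expect_equal(nrow(det), 10L)
  found <- det[order(det$x_px, det$y_px), ]
  truth <- centers[order(centers$cx, centers$cy), ]
  expect_true(all(abs(found$x_px - truth$cx) <= 0.5))
  expect_true(all(abs(found$y_px - truth$cy) <= 0.5))
})

test_that("detect_cells applies the area window and input checks", {
  blank <- array(1, c(40, 40, 3))
  expect_equal(nrow(detect_cells(blank)), 0L)

  small <- draw_disk(blank, 20, 20, radius = 2)  # ~13 px < min area 30
  expect_equal(nrow(detect_cells(small, min_area_px2 = 30)), 0L)
  expect_equal(nrow(detect_cells(small, min_area_px2 = 5)), 1L)

  big <- draw_disk(blank, 20, 20, radius = 15)
  expect_equal(nrow(detect_cells(big, max_area_px2 = 100)), 0L)

  expect_error(detect_cells(matrix(1, 4, 4)), "RGB")
  expect_error(detect_cells(blank, min_area_px2 = 0), "min_area")
})

test_that("stroma area uses the stride footprint", {
  labs <- matrix(match("TUM", TISSUE_CLASSES), 20, 10)
  labs[1:10, ] <- match("STR", TISSUE_CLASSES)  # 100 STR cells
  seg <- segmentation_map(labs, slide_meta("s", 224L, 112L, 0.5, "IHC"))
  expect_equal(stroma_area_mm2(seg), 0.3136)  # 100 * (112 * 0.5 um)^2 / 1e6

  unit <- segmentation_map(matrix(match("STR", TISSUE_CLASSES), 1, 1),
                           slide_meta("u", 2000L, 2000L, 0.5, "IHC"))
  expect_equal(stroma_area_mm2(unit), 1.0)

  # linearity in the STR cell count
  labs2 <- labs; labs2[11:20, ] <- match("STR", TISSUE_CLASSES)
  seg2 <- segmentation_map(labs2, seg$meta)
  expect_equal(stroma_area_mm2(seg2), 2 * stroma_area_mm2(seg))

  expect_error(stroma_area_mm2(segmentation_map(
    matrix(match("TUM", TISSUE_CLASSES), 2, 2), seg$meta)), "no stroma ROI")
})

test_that("stroma_cd3_density counts centroids inside stroma grid cells", {
  labs <- matrix(match("TUM", TISSUE_CLASSES), 20, 10)
  labs[1:10, ] <- match("STR", TISSUE_CLASSES)
  seg <- segmentation_map(labs, slide_meta("s", 224L, 112L, 0.5, "IHC"))

  set.seed(21)
  in_str <- cell_detections(runif(157, 0, 10 * 112), runif(157, 0, 10 * 112), slide_id = "s")
  d <- stroma_cd3_density(in_str, seg)
  expect_equal(d$n_cells_in_stroma, 157L)
  expect_equal(d$density_cells_per_mm2, 157 / 0.3136, tolerance = 1e-12)

  # cells in the tumor half do not count; 2 in a 1 mm^2-equivalent stroma
  mixed <- cell_detections(c(100, 500, 300, 400, 200),
                           c(100, 500, 1500, 1800, 1300), slide_id = "s")
  d2 <- stroma_cd3_density(mixed, seg)
  expect_equal(d2$n_cells_in_stroma, 2L)

  none <- cell_detections(numeric(0), numeric(0), numeric(0), slide_id = "s")
  expect_equal(stroma_cd3_density(none, seg)$density_cells_per_mm2, 0)
})

test_that("density is invariant to stride-unit translation and slide rescaling", {
  labs <- matrix(match("TUM", TISSUE_CLASSES), 8, 8)
  labs[3:6, 3:6] <- match("STR", TISSUE_CLASSES)
  meta <- slide_meta("s", 224L, 112L, 0.5, "IHC")
  seg <- segmentation_map(labs, meta)
  set.seed(33)
  det <- cell_detections(runif(40, 0, 8 * 112), runif(40, 0, 8 * 112), slide_id = "s")
  base <- stroma_cd3_density(det, seg)$density_cells_per_mm2

  # translate both by 2 stride units (pad the segmentation with tumor)
  labs_t <- matrix(match("TUM", TISSUE_CLASSES), 10, 10)
  labs_t[3:10, 3:10] <- labs
  seg_t <- segmentation_map(labs_t, meta)
  det_t <- cell_detections(det$x_px + 2 * 112, det$y_px + 2 * 112, slide_id = "s")
  expect_equal(stroma_cd3_density(det_t, seg_t)$density_cells_per_mm2, base)

  # halve mpp, double pixel sizes: same physical scene
  meta2 <- slide_meta("s", 448L, 224L, 0.25, "IHC")
  seg2 <- segmentation_map(labs, meta2)
  det2 <- cell_detections(det$x_px * 2, det$y_px * 2, slide_id = "s")
  expect_equal(stroma_cd3_density(det2, seg2)$density_cells_per_mm2, base)
})

test_that("adding a detection inside stroma raises density; outside leaves it", {
  labs <- matrix(match(c("STR", "TUM"), TISSUE_CLASSES), 2, 2)
  seg <- segmentation_map(labs, slide_meta("s", 224L, 112L, 0.5, "IHC"))
  det <- cell_detections(c(50), c(50), slide_id = "s")  # in STR cell (1,1)
  base <- stroma_cd3_density(det, seg)$density_cells_per_mm2
  more_in <- cell_detections(c(50, 170), c(50, 50), slide_id = "s")  # (1,2) is STR
  expect_gt(stroma_cd3_density(more_in, seg)$density_cells_per_mm2, base)
  more_out <- cell_detections(c(50, 60), c(50, 170), slide_id = "s")  # (2,1) is TUM
  expect_equal(stroma_cd3_density(more_out, seg)$density_cells_per_mm2, base)
})

test_that("group_density_summary matches the closed-form Welch oracle", {
  res <- group_density_summary(c(1, 2, 3, 4, 5, 6),
                               c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$summary$mean, c(2, 5))
  # closed form: t = (2 - 5) / sqrt(1/3 + 1/3), Welch df = 4
  expect_equal(res$comparisons$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$comparisons$df, 4)
  expect_equal(res$comparisons$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  res2 <- group_density_summary(c(1, 2, 3, 1, 2, 3),
                                c("a", "a", "a", "b", "b", "b"))
  expect_equal(res2$comparisons$t, 0)
  expect_equal(res2$comparisons$p, 1)

  # group with < 2 patients is skipped with a warning
  expect_warning(res3 <- group_density_summary(c(1, 2, 3), c("a", "a", "b")),
                 "fewer than 2")
  expect_equal(nrow(res3$comparisons), 0L)
})

test_that("simulated group densities are recovered through the density pipeline", {
  set.seed(55)
  mu <- c(600, 1500)
  dens <- numeric(40); grp <- rep(1:2, each = 20)
  for (i in 1:40) {
    sim <- simulate_probability_map(0.5, 0.1, c(20, 20), alpha = Inf)
    area <- stroma_area_mm2(sim$seg)
    n <- rpois(1, mu[grp[i]] * area)
    det <- cell_detections(numeric(0), numeric(0), numeric(0))
    if (n > 0) {
      cells <- which(sim$seg$labels == match("STR", TISSUE_CLASSES))
      pick <- cells[sample.int(length(cells), n, replace = TRUE)]
      s <- sim$seg$meta$stride_px
      det <- cell_detections(((pick - 1) %/% 20) * s + runif(n, 0, s),
                             ((pick - 1) %% 20) * s + runif(n, 0, s))
    }
    dens[i] <- stroma_cd3_density(det, sim$seg)$density_cells_per_mm2
  }
  means <- group_density_summary(dens, grp)$summary$mean
  # Poisson counting error at ~750 cells/patient, 20 patients/group: ~1%
  expect_equal(means[1], 600, tolerance = 0.05)
  expect_equal(means[2], 1500, tolerance = 0.05)
})
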