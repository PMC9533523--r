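test_that("deep_tsr counts STR against STR+TUM and ignores other classes", {
  labs <- label_matrix(c("STR", "STR", "STR", "STR", "TUM", "TUM",
                         "NOR", "NOR", "NOR"), 3, 3)
  seg <- segment_map(pmap_from_labels(labs))
  expect_equal(deep_tsr(seg), 4 / 6)

  expect_equal(deep_tsr(segment_map(pmap_from_labels(label_matrix("TUM", 2, 2)))), 0)
  expect_equal(deep_tsr(segment_map(pmap_from_labels(label_matrix("STR", 2, 2)))), 1)
  expect_error(deep_tsr(segment_map(pmap_from_labels(label_matrix("NOR", 2, 2)))),
               "no tumor-bed tissue")

  # invariance to adding cells of other classes
  labs2 <- rbind(labs, label_matrix(c("ADI", "MUC", "DEB"), 1, 3))
  expect_equal(deep_tsr(segment_map(pmap_from_labels(labs2))), 4 / 6)
})

test_that("tsr_group applies the 50% cutoff with the boundary in the high group", {
  expect_equal(tsr_group(4 / 6), data.frame(group = "high", points = 0L))
  expect_equal(tsr_group(0.49), data.frame(group = "low", points = 1L))
  expect_equal(tsr_group(0.50), data.frame(group = "high", points = 0L))
  expect_equal(tsr_group(0.50, cutoff = 0.6)$group, "low")
  expect_error(tsr_group(0.5, cutoff = 1.2), "cutoff")
  expect_error(tsr_group(1.4), "fraction")
})

test_that("deep_til is the masked mean of P(LYM) over stroma cells", {
  labs <- label_matrix(c("STR", "STR", "TUM", "NOR"), 2, 2)
  pm <- pmap_from_labels(labs)
  pm <- set_lym(pm, list(c(1, 1), c(2, 1)), c(0.2, 0.4))
  seg <- segment_map(pm)
  expect_equal(deep_til(pm, seg), 0.3)

  # constant field
  labs_all <- label_matrix("STR", 3, 3)
  pm2 <- set_lym(pmap_from_labels(labs_all),
                 lapply(as.data.frame(t(expand.grid(1:3, 1:3))), identity),
                 rep(0.1, 9))
  expect_equal(deep_til(pm2, segment_map(pm2)), 0.1)

  # strict monotonicity in any stroma cell's P(LYM)
  pm3 <- set_lym(pm, list(c(1, 1)), 0.25)
  expect_gt(deep_til(pm3, segment_map(pm3)), deep_til(pm, seg))

  # permutation invariance: shuffling grid cells leaves the masked mean alone
  set.seed(3)
  perm <- sample(4)
  g <- pm$grid
  gp <- array(0, dim(g))
  for (k in 1:9) gp[, , k] <- matrix(as.vector(g[, , k])[perm], 2, 2)
  pmp <- probability_map(gp, pm$meta)
  expect_equal(deep_til(pmp, segment_map(pmp)), deep_til(pm, seg))

  expect_error(deep_til(pmap_from_labels(label_matrix("TUM", 2, 2)),
                        segment_map(pmap_from_labels(label_matrix("TUM", 2, 2)))),
               "no stroma mask")
})

test_that("calibrate_tertiles matches the linear-interpolation percentile oracle", {
  cal <- calibrate_tertiles(1:100, "primary")
  expect_equal(cal$t33, 33.67)
  expect_equal(cal$t66, 66.34)
  expect_false(cal$degenerate)
  expect_equal(cal$n_reference, 100L)

  # degenerate calibration
  cal2 <- calibrate_tertiles(c(0.3, 0.3, 0.3))
  expect_true(cal2$degenerate)
  expect_equal(cal2$t33, cal2$t66)

  # t33 <= t66 always
  set.seed(5)
  for (i in 1:20) {
    cal3 <- calibrate_tertiles(rexp(sample(3:50, 1)))
    expect_lte(cal3$t33, cal3$t66)
  }
  expect_error(calibrate_tertiles(c(1, 2)), "at least 3")
})

test_that("til_group uses lower-inclusive tertile boundaries", {
  cal <- structure(list(t33 = 0.2, t66 = 0.4, reference_cohort_id = "x",
                        n_reference = 10L, degenerate = FALSE),
                   class = "tertile_calibration")
  expect_equal(til_group(0.1, cal), data.frame(group = "low", points = 1L))
  expect_equal(til_group(0.2, cal)$group, "low")     # boundary inclusive
  expect_equal(til_group(0.3, cal)$group, "middle")
  expect_equal(til_group(0.4, cal)$group, "middle")  # boundary inclusive
  expect_equal(til_group(0.41, cal)$group, "high")

  # degenerate: middle group empty
  dcal <- structure(list(t33 = 0.3, t66 = 0.3, reference_cohort_id = "x",
                         n_reference = 3L, degenerate = TRUE),
                    class = "tertile_calibration")
  expect_equal(til_group(c(0.2, 0.3, 0.31), dcal)$group, c("low", "low", "high"))
})

test_that("regrouping a distinct reference cohort yields near-equal tertiles", {
  set.seed(17)
  for (n in c(30, 99, 100, 150)) {
    scores <- runif(n)
    cal <- calibrate_tertiles(scores)
    sizes <- table(til_group(scores, cal)$group)
    expect_true(all(abs(sizes - n / 3) <= 1),
                label = sprintf("tertile sizes within 1 of n/3 at n = %d", n))
  }
})

test_that("immune_score enumerates the six group combinations to {1,2,2,3,3,4}", {
  combos <- expand.grid(tsr = 0:1, til = 1:3)
  scores <- immune_score(combos$tsr, combos$til)
  expect_setequal(scores, c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(immune_score(1L, 3L), 4L)  # TSR-low + TIL-high
  expect_equal(immune_score(0L, 1L), 1L)  # TSR-high + TIL-low
  expect_error(immune_score(2L, 1L), "tsr_points")
  expect_error(immune_score(0L, 0L), "til_points")
})

test_that("score_cohort produces one record per patient covering all score levels", {
  # six constructed patients, one per (TSR group x TIL group) combination
  build <- function(frac_str, p_lym) {
    labs <- label_matrix(c(rep("STR", frac_str), rep("TUM", 10 - frac_str)), 10, 1)
    pm <- pmap_from_labels(labs)
    cells <- lapply(which(labs == "STR"), function(r) c(r, 1))
    pm <- set_lym(pm, cells, rep(p_lym, length(cells)))
    list(pmap = pm)
  }
  maps <- list(
    p1 = build(6, 0.05), p2 = build(4, 0.05),   # high/low TSR, low TIL
    p3 = build(6, 0.20), p4 = build(4, 0.20),   # middle TIL
    p5 = build(6, 0.40), p6 = build(4, 0.40))   # high TIL
  rec <- score_cohort(maps, "fit", "six")
  expect_equal(nrow(rec), 6L)
  expect_setequal(rec$immune_score, 1:4)
  expect_equal(sort(rec$immune_score), c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(nrow(attr(rec, "errors")), 0L)

  # determinism
  rec2 <- score_cohort(maps, "fit", "six")
  expect_identical(rec, rec2)

  # empty cohort warns and returns an empty table
  expect_warning(empty <- score_cohort(list()), "empty cohort")
  expect_equal(nrow(empty), 0L)
})

test_that("score_cohort collects per-patient failures instead of dropping them", {
  good <- list(pmap = set_lym(pmap_from_labels(label_matrix(c("STR", "TUM"), 2, 1)),
                              list(c(1, 1)), 0.3))
  bad <- list(pmap = pmap_from_labels(label_matrix("NOR", 2, 2)))
  expect_warning(rec <- score_cohort(list(a = good, b = bad, c = good, d = good)),
                 "could not be scored")
  expect_equal(nrow(rec), 3L)
  errs <- attr(rec, "errors")
  expect_equal(errs$patient_id, "b")
  expect_match(errs$error, "no tumor-bed tissue")
})

test_that("calibration serializes and applies unchanged to another cohort", {
  cal <- calibrate_tertiles(seq(0, 1, length.out = 50), "primary")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$t33, cal$t33)
  expect_equal(back$t66, cal$t66)
  expect_equal(til_group(c(0.1, 0.5, 0.9), back), til_group(c(0.1, 0.5, 0.9), cal))
})
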