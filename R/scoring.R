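# Deep-TSR, Deep-TIL, tertile calibration and the composite Deep-immune score.

#' Deep-TSR score: stroma fraction of the tumor bed
#'
#' The stroma fraction is the number of grid cells labeled stroma (STR)
#' divided by the number labeled stroma or tumor epithelium (STR + TUM).
#' All other tissue classes are ignored. Areas are counted in grid cells
#' (patch units): with overlapping strides both numerator and denominator
#' scale identically, so the ratio is unaffected by the stride.
#'
#' @param seg A [segmentation_map()].
#' @return Stroma fraction in [0, 1].
#' @export
deep_tsr <- function(seg) {
  if (!inherits(seg, "segmentation_map")) stop("seg must be a segmentation_map")
  n_str <- sum(seg$labels == class_index("STR"))
  n_tum <- sum(seg$labels == class_index("TUM"))
  if (n_str + n_tum == 0L) stop("no tumor-bed tissue on slide: zero STR and TUM cells")
  n_str / (n_str + n_tum)
}

#' Group a stroma fraction at a cutoff
#'
#' Fractions at or above the cutoff are stroma-high (0 points, the favorable
#' reference); below it stroma-low (1 point). The boundary fraction of exactly
#' the cutoff goes to the high group; the cutoff (default 50%) is configurable.
#'
#' @param fraction Stroma fraction(s) in [0, 1]; vectorized.
#' @param cutoff Cutoff in (0, 1), default 0.5.
#' @return data.frame with columns `group` ("high"/"low") and `points` (0/1).
#' @export
tsr_group <- function(fraction, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)")
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  high <- fraction >= cutoff
  data.frame(group = ifelse(high, "high", "low"),
             points = ifelse(high, 0L, 1L))
}

#' Deep-TIL score: mean lymphocyte probability in the stroma
#'
#' Using the stroma cells of the segmentation as a mask, returns the
#' unweighted mean of the lymphocyte-aggregate (LYM) class probability over
#' all grid cells labeled STR.
#'
#' @param pmap A [probability_map()].
#' @param seg The matching [segmentation_map()] (same shape and slide).
#' @return Mean P(LYM) over stroma cells, in [0, 1].
#' @export
deep_til <- function(pmap, seg) {
  if (!inherits(pmap, "probability_map")) stop("pmap must be a probability_map")
  if (!inherits(seg, "segmentation_map")) stop("seg must be a segmentation_map")
  if (!identical(dim(pmap$grid)[1:2], dim(seg$labels)))
    stop("pmap and seg must share the same grid shape")
  mask <- seg$labels == class_index("STR")
  if (!any(mask)) stop("no stroma mask; Deep-TIL undefined")
  lym <- pmap$grid[, , class_index("LYM")]
  mean(lym[mask])
}

#' Calibrate tertile thresholds on a reference cohort
#'
#' Computes the 33rd and 66th percentiles of the reference (primary) cohort's
#' Deep-TIL scores by linear interpolation between order statistics
#' (`stats::quantile` type 7). The calibration is fit once on the reference
#' cohort and applied unchanged to any other cohort. If all scores are equal
#' the calibration is flagged degenerate; grouping then collapses to
#' low/high around the single value (the middle group is empty).
#'
#' @param reference_scores Numeric vector of at least 3 finite scores.
#' @param cohort_id Identifier of the reference cohort.
#' @return An object of class `tertile_calibration` with fields `t33`, `t66`,
#'   `reference_cohort_id`, `n_reference`, `degenerate`.
#' @export
calibrate_tertiles <- function(reference_scores, cohort_id = "reference") {
  s <- reference_scores[is.finite(reference_scores)]
  if (length(s) < 3L) stop("need at least 3 finite reference scores")
  q <- stats::quantile(s, c(0.33, 0.66), type = 7, names = FALSE)
  structure(
    list(t33 = q[1], t66 = q[2], reference_cohort_id = cohort_id,
         n_reference = length(s), degenerate = q[1] == q[2]),
    class = "tertile_calibration"
  )
}

#' @export
print.tertile_calibration <- function(x, ...) {
  cat(sprintf("tertile_calibration on '%s' (n = %d): t33 = %.6g, t66 = %.6g%s\n",
              x$reference_cohort_id, x$n_reference, x$t33, x$t66,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Write / read a tertile calibration as JSON
#'
#' Serialized so that validation cohorts reuse identical thresholds.
#'
#' @param cal A [calibrate_tertiles()] result.
#' @param path JSON file path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration <- function(cal, path) {
  if (!inherits(cal, "tertile_calibration")) stop("cal must be a tertile_calibration")
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("t33", "t66", "reference_cohort_id", "n_reference")
  if (!all(needed %in% names(x)))
    stop("calibration file is missing keys: ",
         paste(setdiff(needed, names(x)), collapse = ", "))
  structure(list(t33 = x$t33, t66 = x$t66,
                 reference_cohort_id = x$reference_cohort_id,
                 n_reference = as.integer(x$n_reference),
                 degenerate = isTRUE(x$degenerate) || x$t33 == x$t66),
            class = "tertile_calibration")
}

#' Group a Deep-TIL score by a tertile calibration
#'
#' Boundaries are inclusive on the lower group: score <= t33 is low (1 point),
#' t33 < score <= t66 is middle (2 points), score > t66 is high (3 points).
#' Under a degenerate calibration (t33 == t66) scores <= t33 are low and the
#' rest high; the middle group is empty.
#'
#' @param score Numeric Deep-TIL score(s); vectorized.
#' @param cal A [calibrate_tertiles()] result.
#' @return data.frame with columns `group` ("low"/"middle"/"high") and
#'   `points` (1/2/3).
#' @export
til_group <- function(score, cal) {
  if (!inherits(cal, "tertile_calibration")) stop("cal must be a tertile_calibration")
  if (anyNA(score) || any(!is.finite(score))) stop("scores must be finite")
  if (cal$degenerate) {
    high <- score > cal$t33
    return(data.frame(group = ifelse(high, "high", "low"),
                      points = ifelse(high, 3L, 1L)))
  }
  points <- ifelse(score <= cal$t33, 1L, ifelse(score <= cal$t66, 2L, 3L))
  data.frame(group = c("low", "middle", "high")[points], points = points)
}

#' Composite Deep-immune score
#'
#' Sum of the stroma points (high = 0, low = 1) and the lymphocyte points
#' (low = 1, middle = 2, high = 3), giving a four-level score 1-4. The six
#' group combinations map to: (stroma-high, TIL-low) -> 1;
#' (stroma-low, TIL-low) and (stroma-high, TIL-middle) -> 2;
#' (stroma-low, TIL-middle) and (stroma-high, TIL-high) -> 3;
#' (stroma-low, TIL-high) -> 4.
#'
#' @param tsr_points 0 or 1; vectorized.
#' @param til_points 1, 2 or 3; vectorized.
#' @return Integer score(s) in 1..4.
#' @export
immune_score <- function(tsr_points, til_points) {
  if (anyNA(tsr_points) || !all(tsr_points %in% c(0L, 1L)))
    stop("tsr_points must be 0 or 1")
  if (anyNA(til_points) || !all(til_points %in% c(1L, 2L, 3L)))
    stop("til_points must be 1, 2 or 3")
  as.integer(tsr_points) + as.integer(til_points)
}

#' Score a cohort of per-patient map pairs
#'
#' Computes the Deep-TSR fraction, Deep-TIL score, their groups, and the
#' composite Deep-immune score for every patient. Calibration is either fit
#' on this cohort's Deep-TIL scores (`calibration = "fit"`, the primary-cohort
#' workflow) or a frozen [tertile_calibration] from a reference cohort (the
#' validation-cohort workflow). Per-patient failures (no tumor-bed tissue, no
#' stroma mask) are collected in the `errors` attribute, not silently dropped.
#'
#' @param maps Named list (names = patient ids); each element a list with a
#'   `pmap` ([probability_map()]) and optionally a `seg` (computed by
#'   [segment_map()] if absent).
#' @param calibration `"fit"` or a [calibrate_tertiles()] result.
#' @param cohort_id Cohort label recorded in a freshly fit calibration.
#' @param cutoff Stroma cutoff passed to [tsr_group()].
#' @return data.frame with one row per successfully scored patient and columns
#'   `patient_id, deep_tsr, tsr_group, tsr_points, deep_til, til_group,
#'   til_points, immune_score`; attributes `calibration` and `errors`.
#' @export
score_cohort <- function(maps, calibration = "fit", cohort_id = "cohort",
                         cutoff = 0.5) {
  if (length(maps) == 0L) {
    warning("empty cohort: no maps to score")
    out <- data.frame(patient_id = character(), deep_tsr = numeric(),
                      tsr_group = character(), tsr_points = integer(),
                      deep_til = numeric(), til_group = character(),
                      til_points = integer(), immune_score = integer())
    attr(out, "errors") <- data.frame(patient_id = character(), error = character())
    return(out)
  }
  ids <- names(maps)
  if (is.null(ids) || any(!nzchar(ids))) stop("maps must be a named list keyed by patient id")
  tsr <- til <- rep(NA_real_, length(ids))
  errs <- character(0); err_ids <- character(0)
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    res <- tryCatch({
      seg <- if (!is.null(m$seg)) m$seg else segment_map(m$pmap)
      c(deep_tsr(seg), deep_til(m$pmap, seg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err_ids <- c(err_ids, ids[k]); errs <- c(errs, conditionMessage(res))
    } else {
      tsr[k] <- res[1]; til[k] <- res[2]
    }
  }
  ok <- !is.na(tsr)
  cal <- if (identical(calibration, "fit")) {
    calibrate_tertiles(til[ok], cohort_id)
  } else if (inherits(calibration, "tertile_calibration")) {
    calibration
  } else stop("calibration must be \"fit\" or a tertile_calibration")
  tg <- tsr_group(tsr[ok], cutoff)
  lg <- til_group(til[ok], cal)
  out <- data.frame(patient_id = ids[ok], deep_tsr = tsr[ok],
                    tsr_group = tg$group, tsr_points = tg$points,
                    deep_til = til[ok], til_group = lg$group,
                    til_points = lg$points,
                    immune_score = immune_score(tg$points, lg$points))
  attr(out, "calibration") <- cal
  attr(out, "errors") <- data.frame(patient_id = err_ids, error = errs)
  if (length(err_ids))
    warning(sprintf("%d patient(s) could not be scored: %s",
                    length(err_ids), paste(err_ids, collapse = ", ")))
  out
}

#' Write a cohort scores table to CSV
#'
#' @param scores A [score_cohort()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores[, c("patient_id", "deep_tsr", "tsr_group",
                              "deep_til", "til_group", "immune_score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
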