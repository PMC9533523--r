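# Stroma CD3 density: reference blob detector, stroma area, density summary.

# 8-connected component labeling of a logical matrix by iterative flood fill.
# Adequate for the synthetic rasters this detector is meant for.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    stack <- start
    lab[start] <- current
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((v - 1L) %% nr) + 1L
      c <- ((v - 1L) %/% nr) + 1L
      rr <- r + nb_dr; cc <- c + nb_dc
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[keep] - 1L) * nr + rr[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- current
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Detect stained cells on an IHC-like RGB image
#'
#' A documented reference detector for synthetic images, standing in for
#' dedicated cell-segmentation software: it is adequate for color-coded
#' fixtures and makes no claim about real immunohistochemistry. Pixels whose
#' brown-likeness (a DAB-chromogen proxy, `min(R, G) - B` on a unit scale)
#' exceeds `intensity_threshold` are binarized; 8-connected components with
#' pixel area inside `[min_area_px2, max_area_px2]` become detections whose
#' centroid is the component's center of mass in slide pixel coordinates
#' (origin top-left, x rightward, y downward, 0-based).
#'
#' @param ihc_image RGB array `H x W x 3` in [0, 1] (values in 0..255 are
#'   rescaled).
#' @param min_area_px2,max_area_px2 Component area window in pixels squared;
#'   defaults 30 and 5000.
#' @param intensity_threshold Brown-likeness threshold on the unit scale,
#'   default 0.3.
#' @param slide_id Identifier attached to the detections.
#' @return An object of class `cell_detections`: a data.frame with columns
#'   `x_px`, `y_px`, `area_px2` and attribute `slide_id`.
#' @export
detect_cells <- function(ihc_image, min_area_px2 = 30L, max_area_px2 = 5000L,
                         intensity_threshold = 0.3, slide_id = "slide") {
  if (!is.array(ihc_image) || length(dim(ihc_image)) != 3L || dim(ihc_image)[3] != 3L)
    stop("ihc_image must be an H x W x 3 RGB array")
  if (min_area_px2 <= 0 || min_area_px2 > max_area_px2)
    stop("need 0 < min_area_px2 <= max_area_px2")
  img <- ihc_image
  if (max(img) > 1) img <- img / 255
  brown <- pmin(img[, , 1], img[, , 2]) - img[, , 3]
  lab <- label_components(brown > intensity_threshold)
  out <- data.frame(x_px = numeric(0), y_px = numeric(0), area_px2 = numeric(0))
  if (max(lab) > 0L) {
    px <- which(lab > 0L, arr.ind = TRUE)
    comp <- lab[lab > 0L]
    area <- tabulate(comp)
    keep <- which(area >= min_area_px2 & area <= max_area_px2)
    if (length(keep)) {
      # center of mass with pixel centers at integer coordinates (0-based)
      xs <- tapply(px[, "col"] - 1, comp, mean)[as.character(keep)]
      ys <- tapply(px[, "row"] - 1, comp, mean)[as.character(keep)]
      out <- data.frame(x_px = as.numeric(xs), y_px = as.numeric(ys),
                        area_px2 = as.numeric(area[keep]))
      out <- out[order(out$y_px, out$x_px), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, slide_id = slide_id, class = c("cell_detections", "data.frame"))
}

#' Construct a detections table from coordinates
#'
#' @param x_px,y_px Centroids in slide pixel coordinates.
#' @param area_px2 Component areas (> 0).
#' @param slide_id Identifier.
#' @return A `cell_detections` data.frame.
#' @export
cell_detections <- function(x_px, y_px, area_px2 = rep(50, length(x_px)),
                            slide_id = "slide") {
  if (any(area_px2 <= 0)) stop("areas must be > 0")
  if (length(x_px) != length(y_px)) stop("x_px and y_px lengths differ")
  structure(data.frame(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                       area_px2 = as.numeric(area_px2)),
            slide_id = slide_id, class = c("cell_detections", "data.frame"))
}

#' Stroma area of a segmentation in square millimetres
#'
#' Each stroma-labeled grid cell contributes the *stride* footprint
#' `(stride_px * microns_per_pixel)^2`, not the patch footprint, so
#' overlapping patches do not double-count area.
#'
#' @param seg A [segmentation_map()] whose metadata carries the stride and
#'   microns-per-pixel scale.
#' @return Stroma area in mm^2 (> 0).
#' @export
stroma_area_mm2 <- function(seg) {
  if (!inherits(seg, "segmentation_map")) stop("seg must be a segmentation_map")
  n_str <- sum(seg$labels == class_index("STR"))
  if (n_str == 0L) stop("no stroma ROI")
  n_str * (seg$meta$stride_px * seg$meta$microns_per_pixel)^2 / 1e6
}

#' Stroma CD3 density in cells per square millimetre
#'
#' A detection counts as in-stroma iff its centroid falls inside a
#' stroma-labeled grid cell; cell (r, c) covers the pixel block
#' `[(r-1)*stride, r*stride) x [(c-1)*stride, c*stride)`. The density is the
#' in-stroma count divided by the stroma area of [stroma_area_mm2()].
#'
#' @param detections A `cell_detections` table in the same pixel frame as `seg`.
#' @param seg The slide's [segmentation_map()].
#' @return An object of class `density_result`: list with `slide_id`,
#'   `n_cells_in_stroma`, `stroma_area_mm2`, `density_cells_per_mm2`.
#' @export
stroma_cd3_density <- function(detections, seg) {
  if (!inherits(detections, "cell_detections")) stop("detections must be cell_detections")
  area <- stroma_area_mm2(seg)
  s <- seg$meta$stride_px
  r <- floor(detections$y_px / s) + 1L
  c <- floor(detections$x_px / s) + 1L
  inside <- r >= 1L & r <= nrow(seg$labels) & c >= 1L & c <= ncol(seg$labels)
  in_stroma <- inside
  in_stroma[inside] <- seg$labels[cbind(r[inside], c[inside])] == class_index("STR")
  n <- sum(in_stroma)
  structure(list(slide_id = attr(detections, "slide_id"),
                 n_cells_in_stroma = n, stroma_area_mm2 = area,
                 density_cells_per_mm2 = n / area),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("stroma-CD3 density '%s': %d cells / %.4f mm^2 = %.1f cells/mm^2\n",
              x$slide_id, x$n_cells_in_stroma, x$stroma_area_mm2,
              x$density_cells_per_mm2))
  invisible(x)
}

#' Per-group density summary with Welch comparisons
#'
#' Summarizes per-patient stroma-CD3 densities by group (mean, sd, n) and
#' runs a two-sided Welch t-test for each requested group pair. Pairs in
#' which either group has fewer than 2 patients are skipped with a warning.
#'
#' @param densities Numeric per-patient densities.
#' @param groups Parallel vector of group labels.
#' @param pairs Optional list of length-2 vectors of group labels to compare;
#'   default all unordered pairs of observed groups.
#' @return List with `summary` (data.frame: group, n, mean, sd) and
#'   `comparisons` (data.frame: group1, group2, t, df, p).
#' @export
group_density_summary <- function(densities, groups, pairs = NULL) {
  if (length(densities) != length(groups)) stop("densities and groups lengths differ")
  g <- factor(groups)
  summary <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(densities, g, mean)),
    sd = as.numeric(tapply(densities, g, stats::sd))
  )
  if (is.null(pairs)) {
    lv <- levels(g)
    pairs <- if (length(lv) >= 2) utils::combn(lv, 2, simplify = FALSE) else list()
  }
  comps <- data.frame(group1 = character(), group2 = character(),
                      t = numeric(), df = numeric(), p = numeric())
  for (pr in pairs) {
    a <- densities[g == pr[1]]; b <- densities[g == pr[2]]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("skipping pair %s vs %s: fewer than 2 patients in a group",
                      pr[1], pr[2]))
      next
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    comps <- rbind(comps, data.frame(group1 = pr[1], group2 = pr[2],
                                     t = unname(tt$statistic),
                                     df = unname(tt$parameter),
                                     p = tt$p.value))
  }
  list(summary = summary, comparisons = comps)
}
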