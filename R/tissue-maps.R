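# Patch-grid tissue probability maps: data model, tiling, segmentation, I/O.

#' The nine tissue classes
#'
#' Fixed, alphabetically ordered class vocabulary shared by every probability
#' map, segmentation map and on-disk artifact: adipose (ADI), slide background
#' (BAC), debris (DEB), lymphocyte aggregates (LYM), mucus (MUC), smooth
#' muscle (MUS), normal mucosa (NOR), stroma (STR) and tumor epithelium (TUM).
#' Class indices 1..9 follow this order everywhere; files that declare a
#' different order are rejected at read time.
#'
#' @format Character vector of length 9.
#' @export
TISSUE_CLASSES <- c("ADI", "BAC", "DEB", "LYM", "MUC", "MUS", "NOR", "STR", "TUM")

N_CLASSES <- 9L

class_index <- function(label) {
  idx <- match(label, TISSUE_CLASSES)
  if (anyNA(idx)) stop("unknown tissue class: ", paste(label[is.na(idx)], collapse = ", "))
  idx
}

#' Slide metadata
#'
#' Physical and tiling metadata attached to every map derived from one slide.
#'
#' @param slide_id Character identifier.
#' @param patch_size_px Patch side length in pixels (224 at 20x by default).
#' @param stride_px Tiling stride in pixels; must satisfy
#'   `0 < stride_px <= patch_size_px`. Default 112 (50% overlap).
#' @param microns_per_pixel Physical scale, microns per pixel (> 0).
#'   Default 0.5, a typical 20x scan.
#' @param stain Either `"HE"` or `"IHC"`.
#' @return An object of class `slide_meta`.
#' @export
slide_meta <- function(slide_id,
                       patch_size_px = 224L,
                       stride_px = 112L,
                       microns_per_pixel = 0.5,
                       stain = c("HE", "IHC")) {
  stain <- match.arg(stain)
  patch_size_px <- as.integer(patch_size_px)
  stride_px <- as.integer(stride_px)
  if (!is.character(slide_id) || length(slide_id) != 1L || !nzchar(slide_id))
    stop("slide_id must be a non-empty string")
  if (patch_size_px < 1L) stop("patch_size_px must be >= 1")
  if (stride_px < 1L || stride_px > patch_size_px)
    stop("stride_px must satisfy 0 < stride_px <= patch_size_px")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be > 0")
  structure(
    list(slide_id = slide_id, patch_size_px = patch_size_px,
         stride_px = stride_px, microns_per_pixel = microns_per_pixel,
         stain = stain),
    class = "slide_meta"
  )
}

#' @export
print.slide_meta <- function(x, ...) {
  cat(sprintf("slide_meta '%s': patch %d px, stride %d px, %.3g um/px, stain %s\n",
              x$slide_id, x$patch_size_px, x$stride_px, x$microns_per_pixel, x$stain))
  invisible(x)
}

#' Construct a patch-grid probability map
#'
#' A `probability_map` holds, for every grid cell (r, c), the 9-class
#' probability vector of the patch anchored at pixel
#' ((r-1) * stride, (c-1) * stride). Each cell's probabilities must sum to 1
#' within 1e-6.
#'
#' @param grid Numeric array `rows x cols x 9`; third dimension follows
#'   [TISSUE_CLASSES].
#' @param meta A [slide_meta()].
#' @return An object of class `probability_map` with elements `grid` and `meta`.
#' @export
probability_map <- function(grid, meta) {
  if (!inherits(meta, "slide_meta")) stop("meta must be a slide_meta")
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a rows x cols x 9 array")
  d <- dim(grid)
  if (d[3] != N_CLASSES) stop("grid must have 9 class planes, got ", d[3])
  if (d[1] < 1L || d[2] < 1L) stop("grid must have at least one cell")
  if (anyNA(grid) || any(grid < -1e-12) || any(grid > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]")
  sums <- apply(grid, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("each grid cell's probabilities must sum to 1 within 1e-6")
  dimnames(grid) <- list(NULL, NULL, TISSUE_CLASSES)
  structure(list(grid = grid, meta = meta), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("probability_map '%s': %d x %d grid, 9 classes\n",
              x$meta$slide_id, d[1], d[2]))
  invisible(x)
}

#' Construct a segmentation map
#'
#' Per-cell tissue labels (integer indices into [TISSUE_CLASSES]) on the same
#' grid as the source probability map.
#'
#' @param labels Integer matrix of class indices in 1..9.
#' @param meta A [slide_meta()].
#' @return An object of class `segmentation_map`.
#' @export
segmentation_map <- function(labels, meta) {
  if (!inherits(meta, "slide_meta")) stop("meta must be a slide_meta")
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 1L) || any(labels > N_CLASSES))
    stop("labels must be valid class indices in 1..9")
  structure(list(labels = labels, meta = meta), class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("segmentation_map '%s': %d x %d grid\n",
              x$meta$slide_id, nrow(x$labels), ncol(x$labels)))
  tab <- table(factor(TISSUE_CLASSES[x$labels], levels = TISSUE_CLASSES))
  print(tab[tab > 0])
  invisible(x)
}

#' Tile an image into a patch grid
#'
#' Computes the anchors of overlapping `patch_size_px`-sided patches laid out
#' left-to-right, top-to-bottom with the given stride. Incomplete right and
#' bottom margins are dropped: every returned patch lies fully inside the
#' image, and the grid has `floor((H - patch) / stride) + 1` rows (columns
#' likewise).
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param patch_size_px,stride_px Patch side and stride (see [slide_meta()]).
#' @return A data.frame with one row per patch: `row`, `col` (1-based grid
#'   indices) and `y_px`, `x_px` (0-based pixel offsets of the patch's
#'   top-left corner).
#' @export
tile_grid <- function(image_height_px, image_width_px,
                      patch_size_px = 224L, stride_px = 112L) {
  H <- as.integer(image_height_px); W <- as.integer(image_width_px)
  p <- as.integer(patch_size_px); s <- as.integer(stride_px)
  if (s < 1L || s > p) stop("stride_px must satisfy 0 < stride_px <= patch_size_px")
  if (H < p || W < p) stop("slide too small to tile: image is smaller than one patch")
  rows <- (H - p) %/% s + 1L
  cols <- (W - p) %/% s + 1L
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  data.frame(row = g$row, col = g$col,
             y_px = (g$row - 1L) * s, x_px = (g$col - 1L) * s)
}

#' Classify every patch of an image into a probability map
#'
#' Applies a pluggable patch classifier over a tiling grid. The classifier
#' receives one RGB patch (array `patch x patch x 3`, values in [0, 1]) and
#' must return 9 non-negative values (one per class in [TISSUE_CLASSES]
#' order); the vector is renormalized to sum to 1. This is the contract any
#' patch classifier must satisfy; the mock color-lookup classifier from the
#' synthetic-data module is one implementation, a trained network would be
#' another.
#'
#' @param image RGB array `H x W x 3`, values in [0, 1].
#' @param classifier Function patch -> numeric(9).
#' @param meta A [slide_meta()]; its patch size and stride define the grid.
#' @return A [probability_map()].
#' @export
classify_patches <- function(image, classifier, meta) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 RGB array")
  anchors <- tile_grid(dim(image)[1], dim(image)[2],
                       meta$patch_size_px, meta$stride_px)
  rows <- max(anchors$row); cols <- max(anchors$col)
  grid <- array(NA_real_, c(rows, cols, N_CLASSES))
  p <- meta$patch_size_px
  for (k in seq_len(nrow(anchors))) {
    r <- anchors$row[k]; c <- anchors$col[k]
    patch <- image[anchors$y_px[k] + seq_len(p), anchors$x_px[k] + seq_len(p), , drop = FALSE]
    v <- classifier(patch)
    if (!is.numeric(v) || length(v) != N_CLASSES)
      stop(sprintf("classifier returned %d values (expected 9) for patch (%d, %d)",
                   length(v), r, c))
    if (anyNA(v) || any(v < 0))
      stop(sprintf("classifier returned negative or missing values for patch (%d, %d)", r, c))
    s <- sum(v)
    if (s <= 0)
      stop(sprintf("classifier returned an all-zero vector for patch (%d, %d)", r, c))
    grid[r, c, ] <- v / s
  }
  probability_map(grid, meta)
}

#' Segment a probability map by per-cell max probability
#'
#' Each grid cell is labeled with the tissue class of maximum probability.
#' Exact ties are broken toward the lowest class index, deterministically.
#'
#' @param pmap A [probability_map()].
#' @return A [segmentation_map()] of the same shape.
#' @export
segment_map <- function(pmap) {
  if (!inherits(pmap, "probability_map")) stop("pmap must be a probability_map")
  d <- dim(pmap$grid)
  flat <- matrix(pmap$grid, d[1] * d[2], N_CLASSES)
  lab <- max.col(flat, ties.method = "first")
  segmentation_map(matrix(as.integer(lab), d[1], d[2]), pmap$meta)
}

meta_to_list <- function(meta, rows, cols) {
  list(slide_id = meta$slide_id, patch_size_px = meta$patch_size_px,
       stride_px = meta$stride_px, microns_per_pixel = meta$microns_per_pixel,
       stain = meta$stain, class_order = as.list(TISSUE_CLASSES),
       rows = rows, cols = cols)
}

#' Write a probability map to a per-slide directory
#'
#' The on-disk layout is a directory holding `meta.json` (slide id, patch
#' size, stride, microns per pixel, stain, class order, grid shape) and the
#' probabilities in one of two plain-text dialects: `"long"` writes
#' `probs.csv` with columns `row,col,ADI,...,TUM` (0-based row/col, one line
#' per grid cell); `"dense"` writes `probs_dense.csv` with the 9 probability
#' columns only, cells in row-major order, shape taken from the metadata.
#' [read_map()] accepts either dialect.
#'
#' @param pmap A [probability_map()].
#' @param path Directory to create/write into.
#' @param format `"long"` (default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(pmap, path, format = c("long", "dense")) {
  format <- match.arg(format)
  if (!inherits(pmap, "probability_map")) stop("pmap must be a probability_map")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(pmap$grid)
  jsonlite::write_json(meta_to_list(pmap$meta, d[1], d[2]),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(pmap$grid, c(2, 1, 3)), d[1] * d[2], N_CLASSES)  # row-major
  colnames(flat) <- TISSUE_CLASSES
  if (format == "long") {
    g <- expand.grid(col = 0:(d[2] - 1L), row = 0:(d[1] - 1L))
    out <- data.frame(row = g$row, col = g$col, flat, check.names = FALSE)
    utils::write.csv(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                     file.path(path, "probs.csv"), row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(format(as.data.frame(flat), digits = 17, scientific = FALSE, trim = TRUE),
                     file.path(path, "probs_dense.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a probability map written by [write_map()]
#'
#' Detects the dialect from the files present, validates the declared class
#' order against [TISSUE_CLASSES] and the cell count against the declared
#' grid shape, and rebuilds the map.
#'
#' @param path Per-slide directory.
#' @return A [probability_map()].
#' @export
read_map <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", path)
  m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  needed <- c("slide_id", "patch_size_px", "stride_px", "microns_per_pixel",
              "stain", "class_order", "rows", "cols")
  missing <- setdiff(needed, names(m))
  if (length(missing))
    stop("meta.json is missing required keys: ", paste(missing, collapse = ", "))
  if (!identical(as.character(m$class_order), TISSUE_CLASSES))
    stop("class order mismatch: file declares a different tissue-class order")
  meta <- slide_meta(m$slide_id, m$patch_size_px, m$stride_px,
                     m$microns_per_pixel, m$stain)
  rows <- as.integer(m$rows); cols <- as.integer(m$cols)
  long_path <- file.path(path, "probs.csv")
  dense_path <- file.path(path, "probs_dense.csv")
  if (file.exists(long_path)) {
    tab <- utils::read.csv(long_path, check.names = FALSE)
    if (!all(c("row", "col", TISSUE_CLASSES) %in% names(tab)))
      stop("probs.csv lacks the required row,col,ADI..TUM columns")
    if (nrow(tab) != rows * cols)
      stop(sprintf("shape mismatch: meta declares %d cells, probs.csv has %d",
                   rows * cols, nrow(tab)))
    grid <- array(NA_real_, c(rows, cols, N_CLASSES))
    r <- tab$row + 1L; c <- tab$col + 1L
    if (any(r < 1L | r > rows | c < 1L | c > cols))
      stop("probs.csv contains row/col indices outside the declared grid")
    for (k in seq_len(N_CLASSES))
      grid[cbind(r, c, k)] <- tab[[TISSUE_CLASSES[k]]]
    if (anyNA(grid)) stop("probs.csv does not cover every grid cell")
  } else if (file.exists(dense_path)) {
    tab <- utils::read.csv(dense_path, check.names = FALSE)
    if (!identical(names(tab), TISSUE_CLASSES))
      stop("probs_dense.csv must have exactly the 9 class columns in order")
    if (nrow(tab) != rows * cols)
      stop(sprintf("shape mismatch: meta declares %d cells, probs_dense.csv has %d",
                   rows * cols, nrow(tab)))
    grid <- aperm(array(as.matrix(tab), c(cols, rows, N_CLASSES)), c(2, 1, 3))
  } else {
    stop("no probs.csv or probs_dense.csv in ", path)
  }
  probability_map(grid, meta)
}
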