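#' Calibrated bright-field RGB tile
#'
#' The unit of image work in seqstain: an in-memory 8-bit RGB crop of a
#' whole-slide scan from one staining round, together with its spatial
#' calibration. Pixel coordinates are 0-based and pixel-centered, with x
#' increasing rightwards (columns) and y downwards (rows); the pixel at
#' array position `[i, j, ]` has centre `(x, y) = (j - 1, i - 1)`.
#'
#' @param pixels numeric H x W x 3 array of intensities in `[0, 255]`.
#' @param mpp microns per pixel (scalar > 0).
#' @param round_id staining-round label.
#' @param name free-text description.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, mpp, round_id = "round1", name = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image must have H >= 1 and W >= 1")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("intensities must lie in [0, 255]")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a positive scalar")
  structure(
    list(pixels = pixels, mpp = mpp,
         round_id = as.character(round_id), name = as.character(name)),
    class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %.4g um/px, round '%s'%s\n",
              d[1], d[2], x$mpp, x$round_id,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else ""))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Ordered reference-mark set for one staining round
#'
#' Registration landmarks clicked on one round. Order defines correspondence:
#' the i-th point of one round corresponds to the i-th point of any other.
#'
#' @param points numeric n x 2 matrix of (x, y) pixel coordinates, n >= 2.
#' @param round_id staining-round label.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, round_id = "round1") {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must be an n x 2 matrix of (x, y) coordinates")
  if (nrow(points) < 2L)
    stop("at least 2 landmarks required")
  if (anyNA(points) || !all(is.finite(points)))
    stop("landmark coordinates must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, round_id = as.character(round_id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, round '%s'\n",
              nrow(x$points), x$round_id))
  invisible(x)
}

REGION_CLASSES <- c("tumor", "stroma", "necrosis", "artifact")

#' Region annotation set (tumor / stroma / necrosis / artifact polygons)
#'
#' Expert annotations delimiting the analysis region. The analysis mask used
#' for quantification is the union of `tumor` polygons minus the union of
#' `stroma`, `necrosis` and `artifact` polygons.
#'
#' @param polygons list; each element a list with `vertices` (numeric k x 2
#'   matrix, k >= 3, x/y pixel coordinates), `class` (one of `"tumor"`,
#'   `"stroma"`, `"necrosis"`, `"artifact"`), and optionally `name`.
#' @param mpp microns per pixel.
#' @return An object of class `region_annotation_set`.
#' @export
region_annotation_set <- function(polygons, mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a positive scalar")
  if (!length(polygons)) stop("at least one polygon required")
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    nm <- if (!is.null(p$name)) p$name else paste0("feature_", i)
    v <- as.matrix(p$vertices)
    if (ncol(v) != 2L || nrow(v) < 3L)
      stop(sprintf("polygon '%s' must have >= 3 (x, y) vertices", nm))
    if (anyNA(v) || !all(is.finite(v)))
      stop(sprintf("polygon '%s' has non-finite vertices", nm))
    # drop an explicitly closed last vertex
    if (nrow(v) > 3L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    if (.self_intersects(v))
      stop(sprintf("polygon '%s' is self-intersecting", nm))
    if (abs(.shoelace_area(v)) <= .Machine$double.eps)
      stop(sprintf("polygon '%s' has zero area", nm))
    if (!is.character(p$class) || length(p$class) != 1L ||
        !(p$class %in% REGION_CLASSES))
      stop(sprintf(
        "polygon '%s' has unknown class '%s' (allowed: %s)", nm,
        as.character(p$class)[1], paste(REGION_CLASSES, collapse = ", ")))
    storage.mode(v) <- "double"
    dimnames(v) <- list(NULL, c("x", "y"))
    list(vertices = v, class = p$class, name = nm)
  })
  structure(list(polygons = polygons, mpp = mpp),
            class = "region_annotation_set")
}

#' @export
print.region_annotation_set <- function(x, ...) {
  cls <- vapply(x$polygons, `[[`, "", "class")
  cat(sprintf("<region_annotation_set> %d polygons (%s), %.4g um/px, analysis area %.4g mm^2\n",
              length(cls), paste(names(table(cls)), table(cls), sep = ":",
                                 collapse = ", "),
              x$mpp, mask_area_mm2(x)))
  invisible(x)
}

# signed shoelace area in px^2
.shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# proper-crossing test for two closed segments p1-p2 and p3-p4
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# edge self-intersection among non-adjacent edges of a simple ring
.self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}
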