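#' Analysis-mask geometry
#'
#' Quantification is restricted to the *analysis mask*: the union of all
#' `tumor` polygons minus the union of every `stroma`, `necrosis` and
#' `artifact` polygon. Areas are computed by exact polygon boolean algebra
#' (not rasterization), then converted to mm^2 with the annotation's
#' microns-per-pixel calibration.
#'
#' @param annot a [region_annotation_set()].
#' @return `analysis_mask_paths()`: a list of closed paths (each a list with
#'   `x`, `y`) delimiting the mask; outer boundaries and holes are
#'   distinguished by orientation. `mask_area_mm2()`: scalar area in mm^2.
#' @export
analysis_mask_paths <- function(annot) {
  stopifnot(inherits(annot, "region_annotation_set"))
  paths <- function(classes) {
    keep <- Filter(function(p) p$class %in% classes, annot$polygons)
    lapply(keep, function(p) list(x = p$vertices[, 1], y = p$vertices[, 2]))
  }
  tum <- paths("tumor")
  if (!length(tum)) return(list())
  mask <- Reduce(function(a, b) polyclip::polyclip(a, list(b), op = "union"),
                 tum[-1], init = tum[1])
  excl <- paths(c("stroma", "necrosis", "artifact"))
  if (length(excl))
    mask <- polyclip::polyclip(mask, excl, op = "minus")
  mask
}

#' @rdname analysis_mask_paths
#' @export
mask_area_mm2 <- function(annot) {
  mask <- analysis_mask_paths(annot)
  if (!length(mask)) return(0)
  a_px2 <- abs(sum(vapply(
    mask, function(p) .shoelace_area(cbind(p$x, p$y)), 0)))
  a_px2 * (annot$mpp / 1000)^2
}

#' Test points against the analysis mask
#'
#' Even-odd point-in-polygon test of each point against the mask polygons
#' (inside any tumor polygon and not inside any exclusion polygon). Points
#' exactly on a boundary are treated as inside.
#'
#' @param annot a [region_annotation_set()].
#' @param xy numeric n x 2 matrix of (x, y) pixel coordinates.
#' @return logical vector of length n.
#' @export
points_in_mask <- function(annot, xy) {
  stopifnot(inherits(annot, "region_annotation_set"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  inside_any <- function(classes) {
    keep <- Filter(function(p) p$class %in% classes, annot$polygons)
    if (!length(keep)) return(rep(FALSE, nrow(xy)))
    Reduce(`|`, lapply(keep, function(p) .points_in_ring(p$vertices, xy)))
  }
  inside_any("tumor") & !inside_any(c("stroma", "necrosis", "artifact"))
}

# even-odd crossing test, boundary counted as inside; vectorized over points
.points_in_ring <- function(v, xy) {
  n <- nrow(v)
  px <- xy[, 1]; py <- xy[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary: point collinear with edge and within its bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on <- abs(cr) < 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
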