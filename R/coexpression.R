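#' Map cell centroids into another round's frame
#'
#' Applies a registration transform to the centroids of a cell table,
#' leaving every measurement unchanged, so that detections from different
#' staining rounds can be compared in the common reference frame.
#'
#' @param cells a `cell_table`.
#' @param t a [transform2d()].
#' @return The transformed `cell_table`.
#' @export
transfer_coordinates <- function(cells, t) {
  stopifnot(inherits(t, "transform2d"))
  xy <- apply_transform(t, cbind(cells$x, cells$y))
  cells$x <- xy[, 1]
  cells$y <- xy[, 2]
  cells
}

#' Match cells across staining rounds
#'
#' Mutual-nearest-neighbor matching of two cell tables in a common frame:
#' cell i of `a` and cell j of `b` are paired iff each is the other's
#' nearest neighbor and their distance is at most `radius` (microns,
#' converted with the tables' mpp). Ties are broken deterministically by
#' (distance, id). The default radius of 6 um is about one nucleus
#' diameter, a surrogate for the visual co-localization call made on
#' pseudo-fluorescence overlays.
#'
#' @param a,b `cell_table`s in the same frame.
#' @param radius matching radius in microns (default 6).
#' @return An object of class `match_set`: `pairs` (data frame `id_a`,
#'   `id_b`, `distance_px`), `unmatched_a`, `unmatched_b`, `radius_px`.
#' @export
match_cells <- function(a, b, radius = 6) {
  if (radius <= 0) stop("`radius` must be > 0")
  mpp <- attr(a, "mpp")
  if (is.null(mpp)) mpp <- attr(b, "mpp")
  if (is.null(mpp)) stop("cell tables carry no mpp calibration")
  radius_px <- radius / mpp
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    return(structure(list(
      pairs = data.frame(id_a = integer(0), id_b = integer(0),
                         distance_px = numeric(0)),
      unmatched_a = a$id, unmatched_b = b$id, radius_px = radius_px),
      class = "match_set"))
  }
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  D <- sqrt(dx^2 + dy^2)
  # deterministic nearest neighbor with tie-break by (distance, id)
  nn_of_a <- apply(D, 1, which.min)
  nn_of_b <- apply(D, 2, which.min)
  i <- seq_len(na)
  mutual <- nn_of_b[nn_of_a[i]] == i & D[cbind(i, nn_of_a[i])] <= radius_px
  pairs <- data.frame(id_a = a$id[i[mutual]],
                      id_b = b$id[nn_of_a[i[mutual]]],
                      distance_px = D[cbind(i[mutual], nn_of_a[i[mutual]])])
  pairs <- pairs[order(pairs$distance_px, pairs$id_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(a$id, pairs$id_a),
                 unmatched_b = setdiff(b$id, pairs$id_b),
                 radius_px = radius_px),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d pairs (radius %.3g px), %d/%d unmatched in a/b\n",
              nrow(x$pairs), x$radius_px,
              length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

.marker_state <- function(cells, marker, ids) {
  col <- paste0("marker_", marker)
  if (!col %in% names(cells)) return(NULL)
  cells[[col]][match(ids, cells$id)]
}

#' Co-expression phenotype counts and marker ratios
#'
#' Counts matched cells satisfying boolean phenotype rules across two
#' rounds (e.g. CD8+GZMB+ activated cytotoxic T cells vs GZMB+CD8- NK
#' cells), and computes slide-level marker ratios from the per-table
#' positive counts. The `gzmb_cd8_ratio` of the study is such a slide-level
#' ratio: number of GZMB-positive cells divided by number of CD8-positive
#' cells, undefined (`NA`) when there are no CD8-positive cells.
#'
#' @param matches a [match_cells()] result.
#' @param cells_a,cells_b the classified `cell_table`s that were matched.
#' @param rules named list of phenotype rules; each rule is a named
#'   character vector `c(<marker> = "positive"|"negative", ...)`. Markers
#'   are looked up in `cells_a` first, then `cells_b`; a rule naming an
#'   absent marker is an error.
#' @param ratios named list of slide-level ratios, each
#'   `c(num = <marker>, den = <marker>)`; defaults to `gzmb_cd8_ratio`
#'   when markers `GZMB` and `CD8` are present.
#' @return An object of class `phenotype_summary` with `n_matched`,
#'   `counts` (named integer vector per rule), and `ratios` (named numeric,
#'   `NA` for zero denominators).
#' @export
phenotype_counts <- function(matches, cells_a, cells_b, rules,
                             ratios = NULL) {
  stopifnot(inherits(matches, "match_set"))
  all_markers <- union(attr(cells_a, "markers"), attr(cells_b, "markers"))
  if (is.null(ratios) && all(c("GZMB", "CD8") %in% all_markers))
    ratios <- list(gzmb_cd8_ratio = c(num = "GZMB", den = "CD8"))
  p <- matches$pairs
  state_of <- function(marker) {
    sa <- .marker_state(cells_a, marker, p$id_a)
    if (!is.null(sa)) return(sa)
    sb <- .marker_state(cells_b, marker, p$id_b)
    if (!is.null(sb)) return(sb)
    stop(sprintf("rule references absent marker '%s'", marker))
  }
  counts <- vapply(rules, function(rule) {
    ok <- rep(TRUE, nrow(p))
    for (m in names(rule)) ok <- ok & (state_of(m) == rule[[m]])
    sum(ok)
  }, integer(1))
  slide_pos <- function(marker) {
    col <- paste0("marker_", marker)
    n <- 0L; found <- FALSE
    for (tab in list(cells_a, cells_b)) {
      if (col %in% names(tab)) { n <- n + sum(tab[[col]] == "positive"); found <- TRUE }
    }
    if (!found) stop(sprintf("ratio references absent marker '%s'", marker))
    n
  }
  ratio_vals <- vapply(ratios, function(r) {
    num <- slide_pos(r[["num"]]); den <- slide_pos(r[["den"]])
    if (den == 0L) NA_real_ else num / den
  }, numeric(1))
  structure(list(n_matched = nrow(p), counts = counts, ratios = ratio_vals),
            class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat(sprintf("<phenotype_summary> %d matched cells\n", x$n_matched))
  for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  for (nm in names(x$ratios)) cat(sprintf("  %s = %.4g\n", nm, x$ratios[[nm]]))
  invisible(x)
}
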