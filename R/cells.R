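#' Cell detection parameters
#'
#' Detection is nucleus-driven: the detection channel is thresholded after
#' Gaussian smoothing, touching nuclei are split by distance-transform
#' watershed, implausible nuclei are removed by area, and each nucleus is
#' expanded radially (constrained by its neighbors) to define the cell and
#' cytoplasm compartments. Two detection channels are supported:
#' `"hematoxylin_od"` (deconvolved hematoxylin concentration; avoids
#' counting background artifacts) and `"od_sum"` (sum of the three RGB
#' optical densities; robust to weak counterstain where the chromogen
#' itself marks the cell).
#'
#' @param detection_channel `"hematoxylin_od"` (default) or `"od_sum"`.
#' @param nucleus_threshold OD threshold for nucleus detection (default 0.1).
#' @param min_nucleus_area,max_nucleus_area nucleus area bounds in square
#'   microns (defaults 10 and 400).
#' @param cell_expansion radial expansion from the nucleus boundary defining
#'   the cell compartment, in microns (default 5).
#' @param smoothing_sigma Gaussian smoothing sigma in microns (default 1.5).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(detection_channel = c("hematoxylin_od", "od_sum"),
                             nucleus_threshold = 0.1,
                             min_nucleus_area = 10, max_nucleus_area = 400,
                             cell_expansion = 5, smoothing_sigma = 1.5) {
  detection_channel <- match.arg(detection_channel)
  if (nucleus_threshold <= 0) stop("`nucleus_threshold` must be > 0")
  if (!(min_nucleus_area > 0 && min_nucleus_area < max_nucleus_area))
    stop("need 0 < min_nucleus_area < max_nucleus_area")
  if (cell_expansion < 0) stop("`cell_expansion` must be >= 0")
  structure(list(detection_channel = detection_channel,
                 nucleus_threshold = nucleus_threshold,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 cell_expansion = cell_expansion,
                 smoothing_sigma = smoothing_sigma),
            class = "detection_params")
}

.empty_cell_table <- function(mpp) {
  cols <- c("id", "x", "y", "nucleus_area_um2")
  stats <- as.vector(outer(
    c("nucleus", "cell", "cytoplasm"),
    as.vector(outer(c("hematoxylin", "chromogen"), c("mean", "max"),
                    paste, sep = "_")),
    paste, sep = "_"))
  df <- as.data.frame(matrix(numeric(0), 0, length(cols) + length(stats)))
  names(df) <- c(cols, stats)
  structure(df, mpp = mpp, markers = character(0),
            class = c("cell_table", "data.frame"))
}

# Split a binary nucleus mask into labelled nuclei: seeds are the local
# maxima of the Euclidean distance transform, seeds closer than `sep_px`
# (twice the radius of the smallest admissible nucleus) are merged, and
# labels grow from the seeds by distance-constrained propagation within the
# mask, so touching nuclei split along their equidistance line.
.split_nuclei <- function(binary, sep_px) {
  dmap <- as.matrix(EBImage::distmap(binary))
  brush <- EBImage::makeBrush(2L * as.integer(floor(sep_px / 2)) + 1L, "disc")
  local_max <- as.matrix(EBImage::dilate(dmap, brush))
  seed_mask <- binary & (dmap >= local_max - 1e-6) & dmap >= 1
  if (!any(seed_mask)) return(matrix(0L, nrow(binary), ncol(binary)))
  seed_lab <- matrix(as.integer(EBImage::bwlabel(seed_mask)),
                     nrow(binary), ncol(binary))
  ns <- max(seed_lab)
  idx <- which(seed_lab > 0)
  lab <- seed_lab[idx]
  ys <- (idx - 1L) %% nrow(binary); xs <- (idx - 1L) %/% nrow(binary)
  cx <- rowsum(as.numeric(xs), lab)[, 1] / tabulate(lab, ns)
  cy <- rowsum(as.numeric(ys), lab)[, 1] / tabulate(lab, ns)
  # single-linkage merge of seed clusters closer than the separation floor
  grp <- seq_len(ns)
  if (ns > 1L) {
    D <- as.matrix(stats::dist(cbind(cx, cy)))
    diag(D) <- Inf
    repeat {
      close <- which(D < sep_px & outer(grp, grp, "!="), arr.ind = TRUE)
      if (!nrow(close)) break
      grp[grp == grp[close[1, 2]]] <- grp[close[1, 1]]
    }
  }
  seed_img <- matrix(0L, nrow(binary), ncol(binary))
  seed_img[idx] <- match(grp, unique(grp))[lab]
  nuc <- EBImage::propagate(dmap, seeds = seed_img, mask = binary,
                            lambda = 1e4)
  matrix(as.integer(nuc), nrow(binary), ncol(binary))
}

# per-label mean and max of a value vector
.label_stat <- function(vals, labs, n_labels) {
  means <- maxs <- rep(0, n_labels)
  if (length(vals)) {
    sums <- rowsum(vals, labs)
    cnts <- rowsum(rep(1, length(vals)), labs)
    ids <- as.integer(rownames(sums))
    means[ids] <- sums[, 1] / cnts[, 1]
    mx <- vapply(split(vals, labs), max, 0)
    maxs[as.integer(names(mx))] <- mx
  }
  list(mean = means, max = maxs)
}

#' Detect cells in a stained bright-field tile
#'
#' Runs nucleus-driven positive-cell detection inside the analysis mask of
#' `annot`: stain deconvolution, Gaussian smoothing of the detection
#' channel, OD thresholding, distance-transform watershed splitting of
#' touching nuclei, nucleus-area filtering, neighbor-constrained radial
#' expansion into cell and cytoplasm compartments, and per-compartment
#' mean/max concentration statistics for the hematoxylin and chromogen
#' channels (negative concentrations clipped at zero). Only cells whose
#' nucleus centroid falls inside the analysis mask are kept.
#'
#' @param img an [rgb_image()].
#' @param sm a [stain_matrix()].
#' @param params a [detection_params()].
#' @param annot a [region_annotation_set()] with positive analysis area.
#' @return A `cell_table` data frame (one row per cell) with attributes
#'   `mpp` and `markers`; columns `id`, centroid `x`/`y` (pixels),
#'   `nucleus_area_um2`, and `<compartment>_<stain>_<stat>` statistics.
#' @export
detect_cells <- function(img, sm, params = detection_params(), annot) {
  stopifnot(inherits(img, "rgb_image"), inherits(params, "detection_params"),
            inherits(annot, "region_annotation_set"))
  if (mask_area_mm2(annot) <= 0) stop("empty analysis mask")
  mpp <- img$mpp
  od <- rgb_to_od(img)
  ch <- deconvolve(od, sm)
  hem <- pmax(ch$conc[, , "hematoxylin"], 0)
  chrom <- pmax(ch$conc[, , "chromogen"], 0)
  detect <- switch(params$detection_channel,
                   hematoxylin_od = hem,
                   od_sum = od$od[, , 1] + od$od[, , 2] + od$od[, , 3])
  sigma_px <- params$smoothing_sigma / mpp
  sm_img <- if (sigma_px > 0)
    as.matrix(EBImage::gblur(detect, sigma = sigma_px)) else detect
  binary <- sm_img >= params$nucleus_threshold
  if (!any(binary)) return(.empty_cell_table(mpp))
  sep_px <- 2 * sqrt((params$min_nucleus_area / mpp^2) / pi)
  nuclei <- .split_nuclei(binary, sep_px)
  # nucleus area filter (um^2)
  counts <- tabulate(nuclei[nuclei > 0])
  areas_um2 <- counts * mpp^2
  keep <- which(areas_um2 >= params$min_nucleus_area &
                areas_um2 <= params$max_nucleus_area)
  if (!length(keep)) return(.empty_cell_table(mpp))
  relabel <- integer(length(counts))
  relabel[keep] <- seq_along(keep)
  nuclei <- array(ifelse(nuclei > 0, relabel[pmax(nuclei, 1L)], 0L), dim(nuclei))
  n_cells <- length(keep)
  # cell compartment: radial expansion constrained by neighbors (Voronoi-like
  # propagation restricted to a disc dilation of the nuclei)
  exp_px <- params$cell_expansion / mpp
  if (exp_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(ceiling(exp_px)) + 1L, "disc")
    grow_mask <- EBImage::dilate(nuclei > 0, brush)
    cells_lab <- EBImage::propagate(sm_img, seeds = nuclei,
                                    mask = grow_mask, lambda = 1e4)
    cells_lab <- matrix(as.integer(cells_lab), nrow(binary), ncol(binary))
  } else cells_lab <- nuclei
  # centroids (0-based pixel-centre coordinates)
  idx_n <- which(nuclei > 0)
  lab_n <- nuclei[idx_n]
  rows <- (idx_n - 1L) %% nrow(nuclei)      # y
  cols <- (idx_n - 1L) %/% nrow(nuclei)     # x
  cx <- rowsum(as.numeric(cols), lab_n)[, 1] / tabulate(lab_n, n_cells)
  cy <- rowsum(as.numeric(rows), lab_n)[, 1] / tabulate(lab_n, n_cells)
  df <- data.frame(id = seq_len(n_cells), x = cx, y = cy,
                   nucleus_area_um2 = tabulate(lab_n, n_cells) * mpp^2)
  idx_c <- which(cells_lab > 0)
  lab_c <- cells_lab[idx_c]
  cyto <- cells_lab > 0 & nuclei == 0
  idx_y <- which(cyto)
  lab_y <- cells_lab[idx_y]
  for (stain in c("hematoxylin", "chromogen")) {
    vals <- if (stain == "hematoxylin") hem else chrom
    comp <- list(nucleus = list(vals[idx_n], lab_n),
                 cell = list(vals[idx_c], lab_c),
                 cytoplasm = list(vals[idx_y], lab_y))
    for (cn in names(comp)) {
      st <- .label_stat(comp[[cn]][[1]], comp[[cn]][[2]], n_cells)
      df[[paste(cn, stain, "mean", sep = "_")]] <- st$mean
      df[[paste(cn, stain, "max", sep = "_")]] <- st$max
    }
  }
  inside <- points_in_mask(annot, cbind(df$x, df$y))
  df <- df[inside, , drop = FALSE]
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, mpp = mpp, markers = character(0),
            class = c("cell_table", "data.frame"))
}

#' Classify marker positivity by compartment OD threshold
#'
#' Labels each cell positive for `marker` iff the chosen compartment
#' statistic of the chromogen concentration is at or above `threshold`
#' (e.g. nucleus mean for nuclear markers such as Foxp3, cell or cytoplasm
#' mean for surface/cytoplasmic markers such as CD8 or GZMB). Idempotent;
#' the labels are stored in column `marker_<marker>`.
#'
#' @param cells a `cell_table` from [detect_cells()].
#' @param marker marker name (e.g. `"CD8"`).
#' @param compartment `"nucleus"`, `"cell"` or `"cytoplasm"`.
#' @param stat `"mean"` or `"max"`.
#' @param threshold concentration threshold in OD units.
#' @return The `cell_table` with the marker label column added.
#' @export
classify_positive <- function(cells, marker,
                              compartment = c("nucleus", "cell", "cytoplasm"),
                              stat = c("mean", "max"), threshold) {
  compartment <- match.arg(compartment)
  stat <- match.arg(stat)
  col <- paste(compartment, "chromogen", stat, sep = "_")
  if (!col %in% names(cells))
    stop(sprintf("statistic '%s' not present in cell table", col))
  lab <- ifelse(cells[[col]] >= threshold, "positive", "negative")
  cells[[paste0("marker_", marker)]] <- lab
  attr(cells, "markers") <- union(attr(cells, "markers"), marker)
  cells
}

#' Marker density and percent-positive within the analysis mask
#'
#' The two standard slide-level readouts: the number of positive cells per
#' mm^2 of analysis area (used for CD4/CD8/Foxp3/GZMB densities), and the
#' percentage of positive cells over all detected cells (used for PDL1).
#' With zero detected cells the percentage is undefined (`NA`) and the
#' density 0.
#'
#' @param cells a classified `cell_table`.
#' @param marker marker name previously passed to [classify_positive()].
#' @param annot the [region_annotation_set()] defining the analysis area.
#' @return An object of class `marker_summary` with `marker`,
#'   `n_total_cells`, `n_positive`, `density_positive` (cells/mm^2),
#'   `percent_positive`, `analysis_area_mm2`.
#' @export
summarize_region <- function(cells, marker, annot) {
  col <- paste0("marker_", marker)
  if (!col %in% names(cells))
    stop(sprintf("no labels for marker '%s'; run classify_positive first", marker))
  area <- mask_area_mm2(annot)
  n_total <- nrow(cells)
  n_pos <- sum(cells[[col]] == "positive")
  structure(list(
    marker = marker,
    n_total_cells = n_total,
    n_positive = n_pos,
    density_positive = if (area > 0) n_pos / area else NA_real_,
    percent_positive = if (n_total > 0) 100 * n_pos / n_total else NA_real_,
    analysis_area_mm2 = area), class = "marker_summary")
}

#' @export
print.marker_summary <- function(x, ...) {
  cat(sprintf("%s: %d/%d positive, %.4g cells/mm^2, %.4g%% of total, area %.4g mm^2\n",
              x$marker, x$n_positive, x$n_total_cells, x$density_positive,
              x$percent_positive, x$analysis_area_mm2))
  invisible(x)
}

#' Mark-up image of detected cells
#'
#' Overlays a circular outline at each detected cell for visual
#' verification: positives in red, negatives in cyan. Deterministic; with
#' zero cells the image is returned unchanged.
#'
#' @param img the [rgb_image()] the cells were detected in.
#' @param cells a classified `cell_table`.
#' @param marker marker whose labels color the outlines.
#' @return An `rgb_image`.
#' @export
render_markup <- function(img, cells, marker) {
  col_lab <- paste0("marker_", marker)
  if (!col_lab %in% names(cells))
    stop(sprintf("no labels for marker '%s'", marker))
  out <- img$pixels
  H <- dim(out)[1]; W <- dim(out)[2]
  pos_col <- c(255, 0, 0); neg_col <- c(0, 255, 255)
  for (i in seq_len(nrow(cells))) {
    r_px <- sqrt(cells$nucleus_area_um2[i] / pi) / img$mpp + 1
    # analytic ring of ~1.5 px thickness (stays 4-connected)
    x0 <- cells$x[i]; y0 <- cells$y[i]
    xs <- max(0, floor(x0 - r_px - 1)):min(W - 1, ceiling(x0 + r_px + 1))
    ys <- max(0, floor(y0 - r_px - 1)):min(H - 1, ceiling(y0 + r_px + 1))
    if (!length(xs) || !length(ys)) next
    d <- sqrt(outer((ys - y0)^2, (xs - x0)^2, "+"))
    on_ring <- which(abs(d - r_px) <= 0.75, arr.ind = TRUE)
    if (!nrow(on_ring)) next
    colr <- if (cells[[col_lab]][i] == "positive") pos_col else neg_col
    for (k in 1:3)
      out[cbind(ys[on_ring[, 1]] + 1, xs[on_ring[, 2]] + 1, k)] <- colr[k]
  }
  rgb_image(out, mpp = img$mpp, round_id = img$round_id,
            name = paste0(img$name, "_markup_", marker))
}
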