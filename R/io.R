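# fixed cohort-table columns; marker measurements are matched by pattern
.COHORT_FIXED_COLS <- c(
  "patient_id", "braf_status", "vax_protocol", "site_baseline",
  "site_postvax", "months_surgery_to_vax", "months_vax_to_biopsy",
  "biopsy_timing_printed", "sampling", "bor_recist", "os_months",
  "lesion_response", "dth", "prior_treatments", "following_treatments",
  "group")
.COHORT_NUMERIC_FIXED <- c("months_surgery_to_vax", "months_vax_to_biopsy")

.is_marker_col <- function(nm)
  grepl("^[a-z0-9]+_(pre|post)$", nm) | grepl("^[a-z0-9]+_ratio_post_pre$", nm)

# strict locale-explicit numeric parser; "na" (any case) and "" are missing
.parse_numeric_cells <- function(cells, decimal, col) {
  out <- rep(NA_real_, length(cells))
  cells <- trimws(cells)
  miss <- is.na(cells) | cells == "" | tolower(cells) == "na"
  pat <- if (decimal == "comma") "^-?[0-9]+(,[0-9]+)?$" else
    "^-?[0-9]+(\\.[0-9]+)?$"
  bad <- !miss & !grepl(pat, cells)
  if (any(bad))
    stop(sprintf("unparseable numeric cell '%s' (row %d, column '%s')",
                 cells[which(bad)[1]], which(bad)[1], col))
  ok <- !miss
  vals <- cells[ok]
  if (decimal == "comma") vals <- gsub(",", ".", vals, fixed = TRUE)
  out[ok] <- as.numeric(vals)
  out
}

.format_numeric_cells <- function(x, decimal) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("na")
    s <- formatC(v, format = "f", digits = 12)
    s <- sub("0+$", "", s)
    s <- sub("\\.$", ".0", s)
    s
  }, character(1))
  if (decimal == "comma") out <- gsub(".", ",", out, fixed = TRUE)
  out
}

#' Read a paired-cohort table
#'
#' Reads a delimited per-patient table of pre/post marker measurements in the
#' layout of the study's patient-characteristics table. The decimal
#' convention is explicit and strictly enforced: with `decimal = "comma"`
#' the cell `"7,836"` parses to 7.836 and a dotted cell is an error (no
#' locale guessing). `"na"` cells become missing values; the record is
#' retained. Marker measurement columns are recognized by name pattern
#' (`<marker>_pre`, `<marker>_post`, `<marker>_ratio_post_pre`); any other
#' column outside the fixed set is an error. The treatment group
#' (`naive_ct_rt` / `immuno_treated`) is always derived from the
#' `prior_treatments` column via [assign_cohort_group()], never read.
#'
#' @param path file path.
#' @param decimal `"comma"` (default; field separator `";"`) or `"point"`
#'   (separator `","`).
#' @param sep field separator override.
#' @return A `paired_cohort` data frame (one row per patient).
#' @export
read_cohort_table <- function(path, decimal = c("comma", "point"), sep = NULL) {
  decimal <- match.arg(decimal)
  if (is.null(sep)) sep <- if (decimal == "comma") ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  unknown <- setdiff(names(raw), .COHORT_FIXED_COLS)
  unknown <- unknown[!.is_marker_col(unknown)]
  if (length(unknown))
    stop(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  required <- c("patient_id", "prior_treatments", "sampling")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_req, collapse = ", ")))
  out <- raw
  num_cols <- c(intersect(.COHORT_NUMERIC_FIXED, names(raw)),
                names(raw)[.is_marker_col(names(raw))])
  for (cl in num_cols) out[[cl]] <- .parse_numeric_cells(raw[[cl]], decimal, cl)
  bad_samp <- !out$sampling %in% c("on_treatment", "post_treatment")
  if (any(bad_samp))
    stop(sprintf("invalid sampling value '%s' (row %d)",
                 out$sampling[which(bad_samp)[1]], which(bad_samp)[1]))
  prepost <- names(out)[grepl("^[a-z0-9]+_(pre|post)$", names(out))]
  for (cl in prepost)
    if (any(out[[cl]] < 0, na.rm = TRUE))
      stop(sprintf("negative value in column '%s'", cl))
  out$group <- assign_cohort_group(out$prior_treatments)
  class(out) <- c("paired_cohort", "data.frame")
  out
}

#' Write a paired-cohort table
#'
#' Inverse of [read_cohort_table()]: numeric cells are rendered under the
#' declared decimal convention, missing values as `"na"`. A write/read
#' round trip preserves values to better than 1e-12, groups, and
#' missingness.
#'
#' @param cohort a `paired_cohort` data frame.
#' @param path output path.
#' @inheritParams read_cohort_table
#' @export
write_cohort_table <- function(cohort, path, decimal = c("comma", "point"),
                               sep = NULL) {
  decimal <- match.arg(decimal)
  if (is.null(sep)) sep <- if (decimal == "comma") ";" else ","
  out <- as.data.frame(cohort)
  num_cols <- c(intersect(.COHORT_NUMERIC_FIXED, names(out)),
                names(out)[.is_marker_col(names(out))])
  for (cl in num_cols) out[[cl]] <- .format_numeric_cells(out[[cl]], decimal)
  # character fields may contain either separator; always quote
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Packaged patient-characteristics fixture
#'
#' Returns the path of (or parses) the cohort table shipped with the package:
#' 16 metastatic-melanoma patients with pre/post-vaccine PDL1 percent
#' positivity, CD8 post/pre density ratios, prior/following treatments and
#' biopsy timing, using comma decimal separators and `"na"` missing codes.
#' Patient 6's pre-treatment PDL1 is ambiguous in the source table; the
#' primary fixture carries 0 (the value consistent with the published group
#' means) and `variant = "pt6_printed"` carries the printed 0.9748. The
#' `sampling` column follows the narrative assignment (patients 2, 6, 10
#' sampled post-treatment); the `biopsy_timing_printed` column preserves the
#' table's own on/post labels.
#'
#' @param variant `"primary"` or `"pt6_printed"`.
#' @return `table1_path()`: the file path. `table1_cohort()`: the parsed
#'   `paired_cohort`.
#' @export
table1_path <- function(variant = c("primary", "pt6_printed")) {
  variant <- match.arg(variant)
  fn <- if (variant == "primary") "table1.csv" else "table1_pt6_printed.csv"
  system.file("extdata", fn, package = "seqstain", mustWork = TRUE)
}

#' @rdname table1_path
#' @export
table1_cohort <- function(variant = c("primary", "pt6_printed")) {
  read_cohort_table(table1_path(variant), decimal = "comma")
}

#' Read registration landmarks
#'
#' Reads a comma-separated file with header `round_id,index,x,y` into one
#' [landmark_set()] per round, points ordered by `index` within a round.
#' Equal `index` across rounds defines correspondence, so all rounds must
#' contain the same number of points.
#'
#' @param path file path.
#' @return Named list of `landmark_set`, one per round.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round_id", "index", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns round_id,index,x,y")
  rounds <- split(df, df$round_id)
  counts <- vapply(rounds, nrow, 0L)
  if (length(unique(counts)) > 1L)
    stop(sprintf("unequal landmark counts across rounds (%s)",
                 paste(names(counts), counts, sep = "=", collapse = ", ")))
  if (counts[1] < 2L) stop("at least 2 landmarks required per round")
  lapply(rounds, function(r) {
    r <- r[order(r$index), , drop = FALSE]
    landmark_set(cbind(r$x, r$y), round_id = r$round_id[1])
  })
}

#' @rdname read_landmarks
#' @param sets list of `landmark_set`.
#' @export
write_landmarks <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s)
    data.frame(round_id = s$round_id, index = seq_len(nrow(s$points)),
               x = s$points[, 1], y = s$points[, 2])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon features, each carrying a
#' property `class` in `{tumor, stroma, necrosis, artifact}`, into a
#' [region_annotation_set()]. Coordinates are pixel coordinates in the image
#' frame. Polygon holes (inner rings) are not supported; annotate excluded
#' areas as separate `stroma`/`necrosis`/`artifact` features instead.
#'
#' @param path file path.
#' @param mpp microns per pixel of the image the annotations refer to.
#' @return A `region_annotation_set`.
#' @export
read_annotations <- function(path, mpp) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("annotation file must be a GeoJSON FeatureCollection")
  polys <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    nm <- if (!is.null(f$properties$name)) f$properties$name else
      paste0("feature_", i)
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon")
      stop(sprintf("feature '%s': only Polygon geometries are supported", nm))
    rings <- f$geometry$coordinates
    if (length(rings) > 1L)
      stop(sprintf("feature '%s': polygon holes are not supported", nm))
    v <- do.call(rbind, lapply(rings[[1]], function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    cls <- f$properties$class
    if (is.null(cls)) stop(sprintf("feature '%s': missing 'class' property", nm))
    list(vertices = v, class = as.character(cls), name = nm)
  })
  region_annotation_set(polys, mpp = mpp)
}

#' @rdname read_annotations
#' @param annot a `region_annotation_set`.
#' @export
write_annotations <- function(annot, path) {
  features <- lapply(annot$polygons, function(p) {
    ring <- lapply(seq_len(nrow(p$vertices)), function(i)
      c(p$vertices[i, 1], p$vertices[i, 2]))
    ring <- c(ring, ring[1])  # close the ring
    list(type = "Feature",
         properties = list(class = p$class, name = p$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write 8-bit RGB image tiles
#'
#' TIFF and PNG, chosen by file extension. Grayscale images are replicated
#' to three channels, alpha channels dropped. The spatial calibration is
#' supplied by the caller, never read from metadata.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param mpp microns per pixel.
#' @param round_id,name passed to [rgb_image()].
#' @return `read_image()`: an `rgb_image`.
#' @export
read_image <- function(path, mpp, round_id = "round1", name = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '.%s'", ext)))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 1L) arr <- array(arr[, , 1], c(dim(arr)[1:2], 3L))
  rgb_image(round(arr * 255), mpp = mpp, round_id = round_id, name = name)
}

#' @rdname read_image
#' @param img an `rgb_image`.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    stop(sprintf("unsupported image format '.%s'", ext)))
  invisible(path)
}
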