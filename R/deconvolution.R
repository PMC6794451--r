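# Ruifrok-Johnston OD-space stain vectors (RGB order), unit-normalized on use
.STAIN_VECTORS <- list(
  hematoxylin = c(0.650, 0.704, 0.286),
  DAB = c(0.268, 0.570, 0.776),
  AEC = c(0.2743, 0.6796, 0.6803))

#' Stain matrix for hematoxylin + chromogen deconvolution
#'
#' Builds the 3 x 3 matrix of unit OD-space stain vectors used for color
#' deconvolution: hematoxylin (nuclear counterstain), the chromogen (AEC,
#' red, or DAB, brown), and a residual row completing the basis (cross
#' product of the first two, normalized). Default vectors are the standard
#' Ruifrok-Johnston values; both stain rows can be overridden.
#'
#' @param chromogen `"AEC"` or `"DAB"`.
#' @param hematoxylin,chromogen_vector optional length-3 replacement OD
#'   vectors (any positive scale; normalized internally).
#' @return An object of class `stain_matrix`: list with `vectors` (3 x 3
#'   matrix, rows hematoxylin/chromogen/residual) and `chromogen_kind`.
#' @export
stain_matrix <- function(chromogen = c("AEC", "DAB"),
                         hematoxylin = NULL, chromogen_vector = NULL) {
  chromogen <- match.arg(chromogen)
  h <- if (is.null(hematoxylin)) .STAIN_VECTORS$hematoxylin else hematoxylin
  c_ <- if (is.null(chromogen_vector)) .STAIN_VECTORS[[chromogen]] else
    chromogen_vector
  unit <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || !all(is.finite(v)) || sum(v^2) == 0)
      stop("stain vectors must be finite length-3 vectors")
    v / sqrt(sum(v^2))
  }
  h <- unit(h); c_ <- unit(c_)
  r <- c(h[2] * c_[3] - h[3] * c_[2],
         h[3] * c_[1] - h[1] * c_[3],
         h[1] * c_[2] - h[2] * c_[1])
  if (sqrt(sum(r^2)) < 1e-9)
    stop("hematoxylin and chromogen vectors are collinear")
  m <- rbind(hematoxylin = h, chromogen = c_, residual = unit(r))
  colnames(m) <- c("R", "G", "B")
  structure(list(vectors = m, chromogen_kind = chromogen),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("<stain_matrix> H-%s\n", x$chromogen_kind))
  print(round(x$vectors, 4))
  invisible(x)
}

#' Convert bright-field RGB to optical density
#'
#' Per channel, `OD = -log10(max(I, 1) / i0)` (Beer-Lambert with incident
#' intensity `i0`); the one-intensity-level floor bounds the OD of fully
#' saturated pixels at `log10(i0) ~ 2.4065` for `i0 = 255`. White pixels
#' have OD 0; OD is antitone in intensity.
#'
#' @param img an [rgb_image()].
#' @param i0 incident (background) intensity, default 255.
#' @return An object of class `od_image`: list with `od` (H x W x 3
#'   non-negative array) and `mpp`.
#' @export
rgb_to_od <- function(img, i0 = 255) {
  stopifnot(inherits(img, "rgb_image"))
  if (i0 <= 0) stop("`i0` must be > 0")
  od <- -log10(pmax(img$pixels, 1) / i0)
  od <- pmax(od, 0)
  structure(list(od = od, mpp = img$mpp), class = "od_image")
}

#' @rdname rgb_to_od
#' @param od an `od_image`.
#' @param mpp,round_id,name metadata for the reconstructed image.
#' @export
od_to_rgb <- function(od, i0 = 255, round_id = "round1", name = "") {
  arr <- if (inherits(od, "od_image")) od$od else od
  mpp <- if (inherits(od, "od_image")) od$mpp else
    stop("`od` must be an od_image")
  px <- i0 * 10^(-arr)
  rgb_image(pmin(pmax(round(px), 0), 255), mpp = mpp,
            round_id = round_id, name = name)
}

#' Separate an OD image into stain concentration channels
#'
#' Per pixel, solves `od = conc %*% M` for the concentration of each stain
#' along its OD vector (rows of the stain matrix `M`), i.e.
#' `conc = od %*% solve(M)`. Concentrations are in OD units along each
#' stain vector; negative values (pixels outside the stain span) are
#' retained here to preserve exact invertibility and clipped at zero only
#' when measured.
#'
#' @param od an [rgb_to_od()] result.
#' @param sm a [stain_matrix()].
#' @return An object of class `stain_channels`: list with `conc`
#'   (H x W x 3 array, slices hematoxylin/chromogen/residual) and `mpp`.
#' @export
deconvolve <- function(od, sm) {
  stopifnot(inherits(od, "od_image"), inherits(sm, "stain_matrix"))
  M <- sm$vectors
  if (abs(det(M)) < 1e-9) stop("stain matrix is singular")
  d <- dim(od$od)
  flat <- matrix(od$od, d[1] * d[2], 3)
  conc <- flat %*% solve(M)
  conc <- array(conc, d)
  dimnames(conc) <- list(NULL, NULL, rownames(M))
  structure(list(conc = conc, mpp = od$mpp), class = "stain_channels")
}

#' Recompose OD from stain channels
#'
#' `od = sum over subset of conc_k * vector_k`. With the full subset this
#' exactly inverts [deconvolve()].
#'
#' @param ch a [deconvolve()] result.
#' @param sm the [stain_matrix()] used for deconvolution.
#' @param subset character vector of stain roles among
#'   `c("hematoxylin", "chromogen", "residual")`.
#' @return An `od_image`.
#' @export
recompose <- function(ch, sm,
                      subset = c("hematoxylin", "chromogen", "residual")) {
  stopifnot(inherits(ch, "stain_channels"), inherits(sm, "stain_matrix"))
  if (!length(subset)) stop("`subset` must be non-empty")
  unknown <- setdiff(subset, rownames(sm$vectors))
  if (length(unknown))
    stop(sprintf("unknown stain role(s): %s", paste(unknown, collapse = ", ")))
  d <- dim(ch$conc)
  flat <- matrix(ch$conc, d[1] * d[2], 3)
  keep <- match(subset, rownames(sm$vectors))
  od <- flat[, keep, drop = FALSE] %*% sm$vectors[keep, , drop = FALSE]
  structure(list(od = array(od, d), mpp = ch$mpp), class = "od_image")
}

#' Pseudo-colored composite of stain channels
#'
#' Additive blending of per-channel concentration maps into display colors,
#' emulating a pseudo-fluorescence overlay of chromogen channels from
#' different rounds. Each channel is scaled by `1 / max` (when `normalize`)
#' so its brightest pixel shows exactly the display color; contributions
#' are summed and clipped to `[0, 255]`.
#'
#' @param channels list of H x W concentration matrices (negative values
#'   clipped at 0).
#' @param colors list/matrix of RGB display colors in `[0, 255]`, one per
#'   channel.
#' @param mpp microns per pixel of the output.
#' @param normalize scale each channel to unit maximum (default TRUE).
#' @return An [rgb_image()].
#' @export
pseudo_composite <- function(channels, colors, mpp, normalize = TRUE) {
  if (!length(channels)) stop("at least one channel required")
  d <- dim(channels[[1]])
  out <- array(0, c(d, 3))
  for (i in seq_along(channels)) {
    chan <- pmax(channels[[i]], 0)
    if (!identical(dim(chan), d)) stop("channel shape mismatch")
    if (normalize && max(chan) > 0) chan <- chan / max(chan)
    col <- as.numeric(if (is.list(colors)) colors[[i]] else colors[i, ])
    for (k in 1:3) out[, , k] <- out[, , k] + chan * col[k]
  }
  rgb_image(pmin(pmax(out, 0), 255), mpp = mpp, name = "pseudo_composite")
}
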