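#' Parameters of the synthetic slide simulator
#'
#' The simulator emulates the inputs of sequential chromogenic IHC: one
#' tissue scene of disk-like hematoxylin-stained nuclei on a pale
#' background, re-stained over several rounds (one chromogen marker per
#' round), with each round's coordinate frame displaced from the reference
#' by a similarity transform (rotation, uniform scale, translation —
#' emulating the tissue dilation/shrink of staining/destaining/stripping
#' cycles) and corrupted by additive Gaussian intensity noise. Marker
#' positivity is sampled per cell with configurable marginal fractions and
#' pairwise co-expression `P(B+ | A+)` (e.g. GZMB within CD8+ cells).
#' Rendering uses the Beer-Lambert forward model with the same stain
#' vectors as [stain_matrix()], so stain deconvolution of a noiseless,
#' unquantized render is exact on cell interiors.
#'
#' @param shape `c(H, W)` tile shape in pixels.
#' @param mpp microns per pixel.
#' @param n_cells number of nuclei to place (non-overlapping).
#' @param nucleus_radius_um,nucleus_radius_sd_um nucleus radius mean and sd
#'   in microns.
#' @param markers named numeric vector of marginal positive fractions, one
#'   chromogen round per marker (lower-case names).
#' @param coexpression named list `list("A>B" = p)` giving `P(B+ | A+)`;
#'   unlisted pairs are independent.
#' @param compartments named character vector per marker, `"nucleus"` or
#'   `"cytoplasm"`.
#' @param round_transforms named list per marker round of
#'   `c(scale, theta, tx, ty)` mapping that round into the reference frame;
#'   the first round defaults to identity.
#' @param hematoxylin_od,chromogen_od peak stain concentrations (OD units).
#' @param noise_sd additive Gaussian intensity noise sd (0-255 scale).
#' @param background background intensity level (pale, near-white).
#' @param quantize round rendered intensities to integers (default TRUE).
#' @param seed integer seed; the single source of randomness.
#' @return An object of class `slide_sim_params`.
#' @export
slide_sim_params <- function(shape = c(384, 384), mpp = 0.5, n_cells = 120,
                             nucleus_radius_um = 3.5,
                             nucleus_radius_sd_um = 0.4,
                             markers = c(cd8 = 0.4, gzmb = 0.3),
                             coexpression = list("cd8>gzmb" = 0.6),
                             compartments = NULL,
                             round_transforms = NULL,
                             hematoxylin_od = 0.7, chromogen_od = 0.9,
                             noise_sd = 2, background = 250,
                             quantize = TRUE, seed = 1L) {
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("`markers` must be a named vector of positive fractions")
  names(markers) <- tolower(names(markers))
  if (any(markers < 0 | markers > 1)) stop("positive fractions must be in [0, 1]")
  for (p in unlist(coexpression))
    if (p < 0 || p > 1) stop("co-expression probabilities must be in [0, 1]")
  if (is.null(compartments))
    compartments <- stats::setNames(rep("cytoplasm", length(markers)),
                                    names(markers))
  if (is.null(round_transforms)) {
    round_transforms <- stats::setNames(
      rep(list(c(scale = 1, theta = 0, tx = 0, ty = 0)), length(markers)),
      names(markers))
  }
  for (tr in round_transforms)
    if (tr[["scale"]] <= 0) stop("round transform scale must be > 0")
  structure(list(shape = shape, mpp = mpp, n_cells = n_cells,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_radius_sd_um = nucleus_radius_sd_um,
                 markers = markers, coexpression = coexpression,
                 compartments = compartments,
                 round_transforms = round_transforms,
                 hematoxylin_od = hematoxylin_od,
                 chromogen_od = chromogen_od,
                 noise_sd = noise_sd, background = background,
                 quantize = quantize, seed = as.integer(seed)),
            class = "slide_sim_params")
}

# place n non-overlapping disk centres by rejection sampling
.place_cells <- function(n, H, W, r_px, margin, retry_budget = 300L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- retry_budget * n
  while (placed < n) {
    if (attempts >= max_attempts)
      stop("cell density too high: could not place non-overlapping nuclei within the retry budget")
    attempts <- attempts + 1L
    x <- stats::runif(1, margin, W - 1 - margin)
    y <- stats::runif(1, margin, H - 1 - margin)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < (2.4 * r_px)^2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  cbind(x = xs, y = ys)
}

# sample per-cell marker labels honoring marginals and P(B+ | A+) chains
.sample_labels <- function(n, markers, coexpression) {
  labs <- matrix(FALSE, n, length(markers),
                 dimnames = list(NULL, names(markers)))
  if (n == 0L) return(labs)
  for (j in seq_along(markers)) {
    m <- names(markers)[j]
    f <- markers[[j]]
    cond <- NULL
    for (key in names(coexpression)) {
      parts <- strsplit(key, ">", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[2] == m && parts[1] %in% colnames(labs))
        cond <- list(on = parts[1], p = coexpression[[key]])
    }
    if (is.null(cond)) {
      labs[, j] <- stats::runif(n) < f
    } else {
      a <- labs[, cond$on]
      fa <- mean(a)
      # conditional on A- chosen so the marginal stays f where feasible
      p_neg <- if (fa < 1) max(0, min(1, (f - fa * cond$p) / (1 - fa))) else 0
      p <- ifelse(a, cond$p, p_neg)
      labs[, j] <- stats::runif(n) < p
    }
  }
  labs
}

#' Generate a ground-truthed multi-round synthetic slide
#'
#' Renders one staining round per marker (hematoxylin counterstain on every
#' round plus that marker's chromogen in its compartment), each in its own
#' displaced frame, and emits noiseless landmark sets at four fiducial
#' positions plus the full ground truth. Fully deterministic given
#' `params$seed`.
#'
#' @param params a [slide_sim_params()].
#' @return A list with `rounds` (named list of [rgb_image()]), `landmarks`
#'   (named list of [landmark_set()], first entry the reference round),
#'   and `truth`: list with `cells` (data frame of reference-frame
#'   centroids `x`, `y`, radius, and logical `<marker>_positive` columns),
#'   `transforms` (named list of true [transform2d()]s into the reference
#'   frame), and `params`.
#' @export
generate_multiround_slide <- function(params) {
  stopifnot(inherits(params, "slide_sim_params"))
  set.seed(params$seed)
  H <- params$shape[1]; W <- params$shape[2]
  mpp <- params$mpp
  r_mean_px <- params$nucleus_radius_um / mpp
  centres <- .place_cells(params$n_cells, H, W, r_mean_px,
                          margin = 2 * r_mean_px + 2)
  n <- nrow(centres)
  radii <- pmax(stats::rnorm(n, r_mean_px,
                             params$nucleus_radius_sd_um / mpp),
                0.5 * r_mean_px)
  labs <- .sample_labels(n, params$markers, params$coexpression)
  sm_by_marker <- lapply(names(params$markers), function(m) stain_matrix("AEC"))
  names(sm_by_marker) <- names(params$markers)
  # fiducial marks inset from the corners, reference frame
  inset <- 6
  fid <- cbind(x = c(inset, W - 1 - inset, inset, W - 1 - inset),
               y = c(inset, inset, H - 1 - inset, H - 1 - inset))
  transforms <- lapply(params$round_transforms, function(tr)
    similarity_transform(tr[["scale"]], tr[["theta"]], tr[["tx"]], tr[["ty"]]))
  rounds <- list(); landmarks <- list()
  for (m in names(params$markers)) {
    t_m <- transforms[[m]]
    inv <- invert_transform(t_m)
    # scene geometry in this round's frame
    c_round <- apply_transform(inv, centres)
    s <- transform_params(t_m)[["scale"]]
    r_round <- radii / s
    hvec <- stain_matrix("AEC")$vectors["hematoxylin", ]
    cvec <- stain_matrix("AEC")$vectors["chromogen", ]
    od <- array(0, c(H, W, 3))
    hconc <- matrix(0, H, W); cconc <- matrix(0, H, W)
    pos <- labs[, m]
    ring <- params$compartments[[m]] == "cytoplasm"
    for (i in seq_len(n)) {
      r0 <- r_round[i]
      r_out <- if (ring) 1.6 * r0 else r0
      x0 <- c_round[i, 1]; y0 <- c_round[i, 2]
      xs <- max(0, floor(x0 - r_out - 1)):min(W - 1, ceiling(x0 + r_out + 1))
      ys <- max(0, floor(y0 - r_out - 1)):min(H - 1, ceiling(y0 + r_out + 1))
      if (!length(xs) || !length(ys)) next
      dx <- outer(rep(1, length(ys)), xs - x0)
      dy <- outer(ys - y0, rep(1, length(xs)))
      d <- sqrt(dx^2 + dy^2)
      # anti-aliased disk coverage over a 1 px transition band
      alpha_n <- pmin(1, pmax(0, r0 - d + 0.5))
      idx <- cbind(rep(ys, length(xs)) + 1, rep(xs, each = length(ys)) + 1)
      hconc[idx] <- hconc[idx] + params$hematoxylin_od * as.vector(alpha_n)
      if (pos[i]) {
        alpha_c <- if (ring)
          pmin(1, pmax(0, r_out - d + 0.5)) - alpha_n else alpha_n
        alpha_c <- pmax(alpha_c, 0)
        cconc[idx] <- cconc[idx] + params$chromogen_od * as.vector(alpha_c)
      }
    }
    for (k in 1:3) od[, , k] <- hconc * hvec[k] + cconc * cvec[k]
    px <- params$background * 10^(-od)
    if (params$noise_sd > 0)
      px <- px + array(stats::rnorm(length(px), 0, params$noise_sd), dim(px))
    if (params$quantize) px <- round(px)
    px <- pmin(pmax(px, 0), 255)
    rounds[[m]] <- rgb_image(px, mpp = mpp, round_id = m,
                             name = sprintf("synthetic %s round", m))
    landmarks[[m]] <- landmark_set(apply_transform(inv, fid), round_id = m)
  }
  cells <- data.frame(id = seq_len(n), x = centres[, 1], y = centres[, 2],
                      radius_px = radii)
  for (m in colnames(labs)) cells[[paste0(m, "_positive")]] <- labs[, m]
  list(rounds = rounds, landmarks = landmarks,
       truth = list(cells = cells, transforms = transforms,
                    landmarks_ref = fid, params = params))
}

#' Tumor annotation covering a full tile
#'
#' Convenience annotation: a single tumor polygon spanning the whole tile
#' (vertices at the outer pixel corners), for quantifying synthetic tiles.
#'
#' @param shape `c(H, W)` in pixels.
#' @param mpp microns per pixel.
#' @return A [region_annotation_set()].
#' @export
full_tile_annotation <- function(shape, mpp) {
  H <- shape[1]; W <- shape[2]
  region_annotation_set(list(list(
    vertices = rbind(c(-0.5, -0.5), c(W - 0.5, -0.5),
                     c(W - 0.5, H - 0.5), c(-0.5, H - 0.5)),
    class = "tumor", name = "tile")), mpp = mpp)
}

#' Generate a synthetic paired cohort
#'
#' Emulates the structure of the packaged patient table: per patient a
#' prior-treatment string (mixed so that roughly 9/16 of patients are
#' treatment-naive/CT/RT and the rest immuno-treated), a sampling status
#' (on- vs post-treatment), and per-marker pre/post values. Pre values are
#' log-normal (`meanlog`, `sdlog`); post values are
#' `pre + effect + N(0, noise_sd)`, floored at zero; cells go missing
#' independently at `missing_rate`. Deterministic given `seed`.
#'
#' @param n_patients number of patients (>= 3).
#' @param markers character vector of marker names (lower-case).
#' @param paired_effect named additive post-pre shift per marker (default 0).
#' @param noise_sd sd of the additive paired noise.
#' @param missing_rate probability a pre or post cell is missing.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters of the pre values.
#' @return A `paired_cohort` data frame.
#' @export
generate_cohort <- function(n_patients, markers = "cd8",
                            paired_effect = NULL, noise_sd = 1,
                            missing_rate = 0, seed = 1L,
                            meanlog = log(300), sdlog = 0.8) {
  if (n_patients < 3L) stop("`n_patients` must be >= 3")
  if (missing_rate < 0 || missing_rate > 1) stop("invalid `missing_rate`")
  if (noise_sd < 0) stop("invalid `noise_sd`")
  markers <- tolower(markers)
  if (is.null(paired_effect))
    paired_effect <- stats::setNames(rep(0, length(markers)), markers)
  set.seed(as.integer(seed))
  naive_pool <- c("No", "CT", "RT")
  immuno_pool <- c("Ipi", "Biot", "BioCT", "CT, Ipi")
  is_naive <- stats::runif(n_patients) < 9 / 16
  prior <- ifelse(is_naive,
                  sample(naive_pool, n_patients, replace = TRUE),
                  sample(immuno_pool, n_patients, replace = TRUE))
  sampling <- ifelse(stats::runif(n_patients) < 3 / 16,
                     "post_treatment", "on_treatment")
  df <- data.frame(patient_id = as.character(seq_len(n_patients)),
                   prior_treatments = prior, sampling = sampling,
                   stringsAsFactors = FALSE)
  for (m in markers) {
    pre <- stats::rlnorm(n_patients, meanlog, sdlog)
    eff <- if (m %in% names(paired_effect)) paired_effect[[m]] else 0
    post <- pmax(pre + eff + stats::rnorm(n_patients, 0, noise_sd), 0)
    if (missing_rate > 0) {
      pre[stats::runif(n_patients) < missing_rate] <- NA
      post[stats::runif(n_patients) < missing_rate] <- NA
    }
    df[[paste0(m, "_pre")]] <- pre
    df[[paste0(m, "_post")]] <- post
  }
  df$group <- assign_cohort_group(df$prior_treatments)
  class(df) <- c("paired_cohort", "data.frame")
  df
}
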