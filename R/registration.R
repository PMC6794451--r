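#' 2D transforms between staining rounds
#'
#' A `transform2d` maps (x, y) pixel coordinates of a moving round into the
#' frame of a fixed (reference) round. Two model classes are supported:
#' `similarity` (uniform scale s > 0, rotation theta, translation), the
#' smallest model accounting for the tissue dilation/shrink that
#' staining/destaining/stripping cycles can introduce, and `affine`
#' (arbitrary non-singular 2 x 2 linear part plus translation) for
#' anisotropic deformation. Both are represented by a 3 x 3 homogeneous
#' matrix acting on column vectors `(x, y, 1)`.
#'
#' @param matrix 3 x 3 homogeneous matrix, last row `(0, 0, 1)`.
#' @param model `"similarity"` or `"affine"`.
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(matrix, model = c("similarity", "affine")) {
  model <- match.arg(model)
  m <- base::matrix(as.numeric(matrix), 3, 3)
  if (any(abs(m[3, ] - c(0, 0, 1)) > 1e-12))
    stop("last row of a homogeneous 2D transform must be (0, 0, 1)")
  A <- m[1:2, 1:2]
  if (abs(det(A)) < 1e-12) stop("transform linear part is singular")
  if (model == "similarity") {
    # linear part must be s R(theta), s > 0
    if (det(A) <= 0)
      stop("similarity transform must have positive determinant (no reflection)")
    s <- sqrt(det(A))
    R <- A / s
    if (max(abs(crossprod(R) - diag(2))) > 1e-6)
      stop("linear part is not a scaled rotation; use model = 'affine'")
  }
  structure(list(matrix = m, model = model), class = "transform2d")
}

#' @rdname transform2d
#' @param scale uniform scale factor (> 0).
#' @param theta rotation angle in radians (counter-clockwise in the
#'   x-right / y-down pixel frame appears clockwise on screen).
#' @param tx,ty translation in pixels.
#' @export
similarity_transform <- function(scale = 1, theta = 0, tx = 0, ty = 0) {
  if (scale <= 0) stop("`scale` must be > 0")
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- rbind(cbind(scale * R, c(tx, ty)), c(0, 0, 1))
  transform2d(m, "similarity")
}

#' @export
print.transform2d <- function(x, ...) {
  if (x$model == "similarity") {
    p <- transform_params(x)
    cat(sprintf("<transform2d similarity> s = %.6g, theta = %.6g rad, t = (%.6g, %.6g)\n",
                p["scale"], p["theta"], p["tx"], p["ty"]))
  } else {
    cat("<transform2d affine>\n")
    print(x$matrix)
  }
  invisible(x)
}

#' @rdname transform2d
#' @param t,t1,t2 `transform2d` objects.
#' @export
transform_params <- function(t) {
  stopifnot(inherits(t, "transform2d"), t$model == "similarity")
  A <- t$matrix[1:2, 1:2]
  s <- sqrt(det(A))
  c(scale = s, theta = atan2(A[2, 1], A[1, 1]),
    tx = t$matrix[1, 3], ty = t$matrix[2, 3])
}

#' @rdname transform2d
#' @export
invert_transform <- function(t) {
  transform2d(solve(t$matrix), t$model)
}

#' @rdname transform2d
#' @export
compose_transform <- function(t1, t2) {
  model <- if (t1$model == "similarity" && t2$model == "similarity")
    "similarity" else "affine"
  transform2d(t1$matrix %*% t2$matrix, model)
}

#' @rdname transform2d
#' @param xy n x 2 matrix of (x, y) coordinates.
#' @export
apply_transform <- function(t, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (nrow(xy) == 0L) return(xy)
  out <- cbind(xy, 1, deparse.level = 0) %*% t(t$matrix)
  out[, 1:2, drop = FALSE]
}

#' Least-squares landmark transform estimation
#'
#' Estimates the transform mapping `moving` landmarks onto `fixed` ones as
#' the global minimizer of the sum of squared residuals
#' `sum ||T(m_i) - f_i||^2` within the chosen model class — the
#' least-squares solution of the over-determined correspondence system. For
#' `similarity` the closed-form Procrustes/Umeyama solution is used, with
#' reflections excluded (physical slides do not mirror); for `affine` the
#' normal equations are solved directly.
#'
#' @param moving,fixed [landmark_set()]s with equal point counts (order
#'   defines correspondence); >= 2 points for similarity, >= 3 non-collinear
#'   for affine.
#' @param model `"similarity"` (default) or `"affine"`.
#' @return A [transform2d()].
#' @export
estimate_transform <- function(moving, fixed, model = c("similarity", "affine")) {
  model <- match.arg(model)
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  M <- moving$points; F <- fixed$points
  if (nrow(M) != nrow(F)) stop("landmark sets must have equal point counts")
  n <- nrow(M)
  mu_m <- colMeans(M); mu_f <- colMeans(F)
  Mc <- sweep(M, 2, mu_m); Fc <- sweep(F, 2, mu_f)
  var_m <- sum(Mc^2) / n
  if (var_m < 1e-24) stop("degenerate landmark configuration: points coincide")
  if (model == "similarity") {
    # Umeyama: Sigma = F_c' M_c / n; rotation from its SVD with det +1
    Sigma <- crossprod(Fc, Mc) / n
    sv <- svd(Sigma)
    S <- diag(2)
    if (det(sv$u) * det(sv$v) < 0) S[2, 2] <- -1
    R <- sv$u %*% S %*% t(sv$v)
    s <- sum(diag(S) * sv$d) / var_m
    if (s <= 0) stop("degenerate landmark configuration for similarity fit")
    t_vec <- mu_f - s * R %*% mu_m
    transform2d(rbind(cbind(s * R, t_vec), c(0, 0, 1)), "similarity")
  } else {
    if (n < 3L) stop("affine fit requires at least 3 landmarks")
    X <- cbind(M, 1)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12)
      stop("degenerate landmark configuration: collinear points")
    B <- solve(XtX, crossprod(X, F))   # 3 x 2, rows (a., b., t.)
    A <- t(B[1:2, ]); t_vec <- B[3, ]
    transform2d(rbind(cbind(A, t_vec), c(0, 0, 1)), "affine")
  }
}

#' Root-mean-square landmark registration error
#'
#' `sqrt(mean ||T(m_i) - f_i||^2)` in pixels.
#'
#' @inheritParams estimate_transform
#' @param t a [transform2d()].
#' @return scalar RMSE in pixels.
#' @export
registration_error <- function(t, moving, fixed) {
  M <- moving$points; F <- fixed$points
  if (nrow(M) != nrow(F)) stop("landmark sets must have equal point counts")
  res <- apply_transform(t, M) - F
  sqrt(mean(rowSums(res^2)))
}

#' Warp an image by a 2D transform
#'
#' Resamples `img` into the target frame: output pixel `(x, y)` takes the
#' bilinearly interpolated value of the source at `T^-1 (x, y)`. Pixels
#' mapping outside the source are filled with background white (255), which
#' is neutral in optical-density space. The output inherits `mpp`.
#'
#' @param img an [rgb_image()].
#' @param t a [transform2d()] mapping source coordinates to target
#'   coordinates.
#' @param out_shape `c(H, W)` of the output (default: input shape).
#' @return An `rgb_image`.
#' @export
warp_image <- function(img, t, out_shape = dim(img$pixels)[1:2]) {
  stopifnot(inherits(img, "rgb_image"), inherits(t, "transform2d"))
  H <- out_shape[1]; W <- out_shape[2]
  inv <- invert_transform(t)
  # target pixel centres (0-based)
  gx <- rep(seq_len(W) - 1, each = H)
  gy <- rep(seq_len(H) - 1, times = W)
  src <- apply_transform(inv, cbind(gx, gy))
  out <- array(255, c(H, W, 3))
  sx <- src[, 1]; sy <- src[, 2]
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbor at the border (replication)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  for (ch in 1:3) {
    plane <- img$pixels[, , ch]
    v <- rep(255, H * W)
    i00 <- cbind(y0[ok] + 1, x0[ok] + 1); i10 <- cbind(y1[ok] + 1, x0[ok] + 1)
    i01 <- cbind(y0[ok] + 1, x1[ok] + 1); i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
    v[ok] <- plane[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
             plane[i10] * (1 - fx[ok]) * fy[ok] +
             plane[i01] * fx[ok] * (1 - fy[ok]) +
             plane[i11] * fx[ok] * fy[ok]
    out[, , ch] <- matrix(v, H, W)
  }
  rgb_image(pmin(pmax(out, 0), 255), mpp = img$mpp,
            round_id = img$round_id, name = img$name)
}

# mean squared hematoxylin-OD difference over the overlap of fixed and
# warped moving; the fine-alignment cost
.alignment_cost <- function(fixed_od, moving_img, t, sm) {
  warped <- warp_image(moving_img, t)
  w_od <- .hematoxylin_od(warped, sm)
  # overlap = pixels whose source lies inside the moving image
  H <- dim(fixed_od)[1]; W <- dim(fixed_od)[2]
  inv <- invert_transform(t)
  gx <- rep(seq_len(W) - 1, each = H); gy <- rep(seq_len(H) - 1, times = W)
  src <- apply_transform(inv, cbind(gx, gy))
  h <- dim(moving_img$pixels)[1]; w <- dim(moving_img$pixels)[2]
  ok <- matrix(src[, 1] >= 0 & src[, 1] <= w - 1 &
               src[, 2] >= 0 & src[, 2] <= h - 1, H, W)
  if (!any(ok)) return(NA_real_)
  mean((fixed_od[ok] - w_od[ok])^2)
}

.hematoxylin_od <- function(img, sm) {
  od <- rgb_to_od(img)
  ch <- deconvolve(od, sm)
  pmax(ch$conc[, , 1], 0)
}

#' Iterative fine alignment of two rounds
#'
#' Landmark-free refinement of an initial transform by deterministic
#' coordinate descent on the similarity parameters (scale, rotation,
#' translation), minimizing the mean squared difference of the hematoxylin
#' OD channels over the image overlap. Each parameter is perturbed by a
#' step; steps are halved whenever no parameter move improves the cost
#' (step-halving schedule), until the improvement over a sweep falls below
#' `tol` or `max_iter` sweeps are reached. The cost never increases.
#'
#' @param fixed_img,moving_img [rgb_image()]s sharing `mpp`.
#' @param t0 initial [transform2d()] (similarity).
#' @param max_iter maximum number of parameter sweeps (default 50).
#' @param tol minimum cost improvement to continue (default 1e-6).
#' @param sm stain matrix used for the hematoxylin channel (default H-AEC).
#' @return A list of class `registration_report` with `transform`,
#'   `cost`, `initial_cost`, `iterations`.
#' @export
refine_transform <- function(fixed_img, moving_img, t0,
                             max_iter = 50L, tol = 1e-6,
                             sm = stain_matrix("AEC")) {
  stopifnot(inherits(fixed_img, "rgb_image"), inherits(moving_img, "rgb_image"))
  if (abs(fixed_img$mpp - moving_img$mpp) > 1e-12)
    stop("images must share the same mpp")
  if (t0$model != "similarity")
    stop("fine alignment refines similarity transforms")
  fixed_od <- .hematoxylin_od(fixed_img, sm)
  cost_of <- function(p) .alignment_cost(
    fixed_od, moving_img,
    similarity_transform(p[1], p[2], p[3], p[4]), sm)
  p <- unname(transform_params(t0))
  cost <- cost_of(p)
  if (is.na(cost)) stop("empty overlap between images at the initial transform")
  initial_cost <- cost
  steps <- c(0.01, 0.01, 2, 2)  # scale, theta (rad), tx, ty (px)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    sweep_start <- cost
    improved <- FALSE
    for (k in 1:4) {
      for (sgn in c(1, -1)) {
        cand <- p; cand[k] <- cand[k] + sgn * steps[k]
        if (cand[1] <= 0) next
        cc <- cost_of(cand)
        if (!is.na(cc) && cc < cost) { p <- cand; cost <- cc; improved <- TRUE }
      }
    }
    iterations <- it
    if (!improved) {
      steps <- steps / 2
      if (max(steps / c(0.01, 0.01, 2, 2)) < 1e-3) break
    } else if (sweep_start - cost < tol) break
  }
  structure(list(
    transform = similarity_transform(p[1], p[2], p[3], p[4]),
    cost = cost, initial_cost = initial_cost, iterations = iterations),
    class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> cost %.6g (from %.6g) after %d sweeps\n",
              x$cost, x$initial_cost, x$iterations))
  print(x$transform)
  invisible(x)
}

#' Re-align staining rounds into a common z-stack
#'
#' Warps every non-reference round into the reference frame and returns the
#' aligned stack; the reference image is passed through unchanged.
#'
#' @param rounds list of [rgb_image()]s.
#' @param transforms named list of [transform2d()]s, one per non-reference
#'   round (names = round ids), each mapping that round into the reference
#'   frame.
#' @param reference round id of the reference image.
#' @return List of `rgb_image`s sharing the reference shape and frame.
#' @export
build_stack <- function(rounds, transforms, reference) {
  ids <- vapply(rounds, `[[`, "", "round_id")
  if (!(reference %in% ids)) stop(sprintf("reference round '%s' not present", reference))
  ref_img <- rounds[[match(reference, ids)]]
  out_shape <- dim(ref_img$pixels)[1:2]
  out <- lapply(rounds, function(r) {
    if (r$round_id == reference) return(r)
    t <- transforms[[r$round_id]]
    if (is.null(t))
      stop(sprintf("missing transform for round '%s'", r$round_id))
    warp_image(r, t, out_shape)
  })
  names(out) <- ids
  out
}
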