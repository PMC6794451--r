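test_that("landmark fit returns exact transforms on exact correspondences", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  # identity
  t_id <- estimate_transform(landmark_set(pts), landmark_set(pts))
  expect_equal(unname(transform_params(t_id)), c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(registration_error(t_id, landmark_set(pts), landmark_set(pts)),
               0, tolerance = 1e-12)
  # rigid quarter turn plus translation, verifiable by substitution
  fixed <- matrix(c(2, 3, 2, 4, 1, 3), 3, 2, byrow = TRUE)
  t_q <- estimate_transform(landmark_set(pts), landmark_set(fixed))
  p <- transform_params(t_q)
  expect_equal(unname(p), c(1, pi / 2, 2, 3), tolerance = 1e-12)
  expect_equal(apply_transform(t_q, pts), fixed, tolerance = 1e-12)
})

test_that("noiseless similarity parameters are recovered to 1e-9", {
  set.seed(20)
  for (i in 1:12) {
    s <- runif(1, 0.5, 2); th <- runif(1, -pi, pi)
    tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    t_true <- similarity_transform(s, th, tx, ty)
    n <- sample(2:8, 1)
    M <- matrix(runif(2 * n, 0, 200), n, 2)
    if (n == 2 && sum((M[1, ] - M[2, ])^2) < 1) next
    F <- apply_transform(t_true, M)
    t_est <- estimate_transform(landmark_set(M), landmark_set(F))
    p <- transform_params(t_est)
    expect_equal(unname(p[1]), s, tolerance = 1e-9)
    expect_equal(unname(p[3:4]), c(tx, ty), tolerance = 1e-9)
    dth <- (p[2] - th + pi) %% (2 * pi) - pi
    expect_lt(abs(dth), 1e-9)
    expect_lt(registration_error(t_est, landmark_set(M), landmark_set(F)), 1e-9)
  }
})

test_that("noisy fits match the brute-force SSE minimizer and beat the truth", {
  set.seed(21)
  for (i in 1:5) {
    M <- matrix(runif(10, 0, 100), 5, 2)
    t_true <- similarity_transform(2, pi / 6, -4, 7)
    F <- apply_transform(t_true, M) + matrix(rnorm(10, 0, 0.5), 5, 2)
    t_est <- estimate_transform(landmark_set(M), landmark_set(F))
    p <- unname(transform_params(t_est))
    p_opt <- oracle_fit_similarity(M, F, start = c(2, pi / 6, -4, 7))
    expect_equal(p, unname(p_opt), tolerance = 1e-6)
    # least-squares optimality: estimated SSE <= SSE of the generator
    expect_lte(oracle_sse(p, M, F), oracle_sse(c(2, pi / 6, -4, 7), M, F))
  }
})

test_that("the similarity fit is rotation-equivariant", {
  set.seed(22)
  M <- matrix(runif(12, 0, 100), 6, 2)
  F <- apply_transform(similarity_transform(1.3, 0.4, 5, -2), M) +
    matrix(rnorm(12, 0, 0.3), 6, 2)
  t0 <- estimate_transform(landmark_set(M), landmark_set(F))
  phi <- 0.7
  Rt <- similarity_transform(1, phi, 0, 0)
  t1 <- estimate_transform(landmark_set(apply_transform(Rt, M)),
                           landmark_set(apply_transform(Rt, F)))
  conj <- compose_transform(Rt, compose_transform(t0, invert_transform(Rt)))
  expect_equal(t1$matrix, conj$matrix, tolerance = 1e-9)
})

test_that("affine fit solves the normal equations and flags degeneracy", {
  set.seed(23)
  A <- matrix(c(1.2, 0.3, -0.1, 0.8), 2, 2)
  M <- matrix(runif(16, 0, 50), 8, 2)
  F <- t(A %*% t(M)) + matrix(c(3, -2), 8, 2, byrow = TRUE) +
    matrix(rnorm(16, 0, 0.1), 8, 2)
  t_aff <- estimate_transform(landmark_set(M), landmark_set(F), model = "affine")
  # oracle: per-coordinate linear regression
  fit_x <- lm(F[, 1] ~ M[, 1] + M[, 2])
  fit_y <- lm(F[, 2] ~ M[, 1] + M[, 2])
  expect_equal(t_aff$matrix[1, ], unname(coef(fit_x))[c(2, 3, 1)],
               tolerance = 1e-9)
  expect_equal(t_aff$matrix[2, ], unname(coef(fit_y))[c(2, 3, 1)],
               tolerance = 1e-9)
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_transform(landmark_set(coll),
                                  landmark_set(coll + 1), model = "affine"),
               "collinear")
  same <- matrix(1, 4, 2)
  expect_error(estimate_transform(landmark_set(same), landmark_set(same)),
               "coincide")
})

test_that("registration error matches an explicit loop oracle", {
  # single point offset by (3, 4): 3-4-5 triangle
  t_id <- similarity_transform()
  mv <- landmark_set(rbind(c(0, 0), c(10, 10)))
  fx <- landmark_set(rbind(c(3, 4), c(10, 10)))
  expect_equal(registration_error(t_id, mv, fx), sqrt(25 / 2))
  set.seed(24)
  for (i in 1:10) {
    M <- matrix(runif(12, 0, 30), 6, 2)
    F <- matrix(runif(12, 0, 30), 6, 2)
    t <- similarity_transform(runif(1, 0.8, 1.2), runif(1, -1, 1),
                              runif(1, -5, 5), runif(1, -5, 5))
    sq <- 0
    for (k in 1:6) {
      pred <- t$matrix %*% c(M[k, ], 1)
      sq <- sq + sum((pred[1:2] - F[k, ])^2)
    }
    expect_equal(registration_error(t, landmark_set(M), landmark_set(F)),
                 sqrt(sq / 6), tolerance = 1e-12)
  }
})

test_that("transform algebra: compose, invert, reflection exclusion", {
  t <- similarity_transform(1.5, 0.3, 10, -4)
  id <- compose_transform(t, invert_transform(t))
  expect_equal(id$matrix, diag(3), tolerance = 1e-9)
  refl <- diag(3); refl[1, 1] <- -1
  expect_error(transform2d(refl, "similarity"), "reflection")
  expect_error(similarity_transform(scale = -1), "scale")
})

test_that("warping is exact for identity and integer shifts", {
  set.seed(25)
  img <- rgb_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)), 0.5)
  w_id <- warp_image(img, similarity_transform())
  expect_equal(w_id$pixels, img$pixels)
  w_sh <- warp_image(img, similarity_transform(tx = 10, ty = 0))
  # content moved 10 columns right, vacated strip is background white
  expect_equal(w_sh$pixels[, 11:32, ], img$pixels[, 1:22, ])
  expect_true(all(w_sh$pixels[, 1:10, ] == 255))
})

test_that("warp round trips through the inverse within interpolation error", {
  # smooth analytic image so bilinear interpolation error stays small
  gx <- matrix(rep(0:63, each = 64), 64, 64)
  gy <- matrix(rep(0:63, times = 64), 64, 64)
  px <- array(0, c(64, 64, 3))
  for (k in 1:3)
    px[, , k] <- 127 + 60 * sin(gx / (5 + k)) * cos(gy / (7 - k))
  img <- rgb_image(pmin(pmax(px, 0), 255), 0.5)
  t <- similarity_transform(1.0, 0.02, 2.5, -1.5)
  back <- warp_image(warp_image(img, t), invert_transform(t))
  interior <- 9:56
  expect_lt(max(abs(back$pixels[interior, interior, ] -
                    img$pixels[interior, interior, ])), 2 + 1e-9)
})

test_that("stacks share the reference frame and pass the reference through", {
  p <- slide_sim_params(shape = c(96, 96), n_cells = 8, seed = 30,
                        markers = c(cd8 = 0.5, gzmb = 0.4, foxp3 = 0.3),
                        round_transforms = list(
                          cd8 = c(scale = 1, theta = 0, tx = 0, ty = 0),
                          gzmb = c(scale = 1.01, theta = 0.02, tx = 3, ty = -2),
                          foxp3 = c(scale = 0.99, theta = -0.03, tx = -2, ty = 1)))
  sim <- generate_multiround_slide(p)
  transforms <- lapply(sim$landmarks, function(lm)
    estimate_transform(lm, sim$landmarks$cd8))
  stack <- build_stack(sim$rounds, transforms, reference = "cd8")
  expect_identical(stack$cd8$pixels, sim$rounds$cd8$pixels)
  expect_equal(dim(stack$gzmb$pixels), dim(sim$rounds$cd8$pixels))
  # after stacking, per-round landmarks agree with the reference to <= 1 px
  for (m in c("gzmb", "foxp3")) {
    rmse <- registration_error(transforms[[m]], sim$landmarks[[m]],
                               sim$landmarks$cd8)
    expect_lte(rmse, 1)
  }
  expect_error(build_stack(sim$rounds, transforms["gzmb"], "cd8"),
               "missing transform")
  single <- build_stack(sim$rounds["cd8"], list(), "cd8")
  expect_identical(single$cd8$pixels, sim$rounds$cd8$pixels)
})

test_that("fine alignment is a fixed point on identical images", {
  p <- slide_sim_params(shape = c(96, 96), n_cells = 8, seed = 31,
                        markers = c(cd8 = 0.5))
  img <- generate_multiround_slide(p)$rounds$cd8
  rep <- refine_transform(img, img, similarity_transform(), max_iter = 5)
  expect_equal(rep$transform$matrix, diag(3), tolerance = 1e-12)
  expect_equal(rep$cost, rep$initial_cost)
})

test_that("fine alignment recovers a small offset and lowers the cost", {
  p <- slide_sim_params(shape = c(128, 128), n_cells = 15, seed = 32,
                        markers = c(cd8 = 0.5, gzmb = 0.5),
                        round_transforms = list(
                          cd8 = c(scale = 1, theta = 0, tx = 0, ty = 0),
                          gzmb = c(scale = 1, theta = 0, tx = 2, ty = -1.5)))
  sim <- generate_multiround_slide(p)
  rep <- refine_transform(sim$rounds$cd8, sim$rounds$gzmb,
                          similarity_transform(), max_iter = 30)
  pars <- transform_params(rep$transform)
  expect_lt(abs(pars[["tx"]] - 2), 0.5)
  expect_lt(abs(pars[["ty"]] + 1.5), 0.5)
  expect_lt(rep$cost, rep$initial_cost)
})

test_that("fine alignment never increases the cost (seeded pairs)", {
  for (seed in 1:20) {
    set.seed(500 + seed)
    tr <- c(scale = exp(runif(1, -0.02, 0.02)), theta = runif(1, -0.05, 0.05),
            tx = runif(1, -3, 3), ty = runif(1, -3, 3))
    p <- slide_sim_params(shape = c(96, 96), n_cells = 8, seed = 400 + seed,
                          markers = c(cd8 = 0.5, gzmb = 0.5),
                          round_transforms = list(
                            cd8 = c(scale = 1, theta = 0, tx = 0, ty = 0),
                            gzmb = tr))
    sim <- generate_multiround_slide(p)
    rep <- refine_transform(sim$rounds$cd8, sim$rounds$gzmb,
                            similarity_transform(), max_iter = 4)
    expect_lte(rep$cost, rep$initial_cost)
  }
})
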