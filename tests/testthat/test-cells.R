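annot_tile <- function(shape = c(384, 384), mpp = 0.5)
  full_tile_annotation(shape, mpp)

test_that("a blank white tile yields no cells", {
  img <- rgb_image(array(255, c(128, 128, 3)), 0.5)
  cells <- detect_cells(img, stain_matrix("AEC"), detection_params(),
                        annot_tile(c(128, 128)))
  expect_equal(nrow(cells), 0L)
})

test_that("well-separated disk nuclei are all found near their centres", {
  p <- slide_sim_params(n_cells = 25, seed = 50)
  sim <- generate_multiround_slide(p)
  cells <- detect_cells(sim$rounds$cd8, stain_matrix("AEC"),
                        detection_params(), annot_tile())
  expect_equal(nrow(cells), 25L)
  tr <- sim$truth$cells
  d <- sqrt(outer(cells$x, tr$x, "-")^2 + outer(cells$y, tr$y, "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)
  # area filter: a floor above every disk removes everything
  none <- detect_cells(sim$rounds$cd8, stain_matrix("AEC"),
                       detection_params(min_nucleus_area = 390,
                                        max_nucleus_area = 400),
                       annot_tile())
  expect_equal(nrow(none), 0L)
})

test_that("raising the nucleus threshold never increases the cell count", {
  p <- slide_sim_params(n_cells = 40, seed = 51)
  sim <- generate_multiround_slide(p)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.35, 0.5), function(th)
    nrow(detect_cells(sim$rounds$cd8, stain_matrix("AEC"),
                      detection_params(nucleus_threshold = th),
                      annot_tile())), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("positivity classification is a threshold rule and idempotent", {
  ct <- make_cell_table(x = c(10, 20, 30), y = c(10, 10, 10),
                        chrom_mean = c(0.8, 0.2, 0.29))
  ct <- classify_positive(ct, "FOXP3", "nucleus", "mean", threshold = 0.3)
  expect_identical(ct$marker_FOXP3, c("positive", "negative", "negative"))
  ct2 <- classify_positive(ct, "FOXP3", "nucleus", "mean", threshold = 0.3)
  expect_identical(ct2$marker_FOXP3, ct$marker_FOXP3)
  expect_identical(attr(ct2, "markers"), "FOXP3")
  # unreachable threshold: zero positives
  ct3 <- classify_positive(ct, "FOXP3", "nucleus", "mean",
                           threshold = log10(255) + 1)
  expect_true(all(ct3$marker_FOXP3 == "negative"))
  expect_error(classify_positive(ct, "X", "membrane", "mean", 0.3))
  bare <- ct[, !grepl("chromogen_max", names(ct))]
  attr(bare, "mpp") <- 0.5
  expect_error(classify_positive(bare, "X", "cell", "max", 0.3),
               "not present")
})

test_that("region summaries do density and percentage arithmetic", {
  set.seed(52)
  ct <- make_cell_table(x = runif(100, 0, 999), y = runif(100, 0, 999),
                        chrom_mean = c(rep(0.5, 40), rep(0.01, 60)))
  ct <- classify_positive(ct, "CD8", "cell", "mean", 0.3)
  annot <- region_annotation_set(list(
    list(vertices = square_vertices(0, 0, 1000), class = "tumor")), 0.5)
  s <- summarize_region(ct, "CD8", annot)
  expect_equal(s$analysis_area_mm2, 0.25)
  expect_equal(s$n_positive, 40L)
  expect_equal(s$density_positive, 160)
  expect_equal(s$percent_positive, 40)
  # zero positives
  ct0 <- classify_positive(ct, "GZMB", "cell", "mean", 10)
  s0 <- summarize_region(ct0, "GZMB", annot)
  expect_equal(s0$density_positive, 0)
  expect_equal(s0$percent_positive, 0)
  # zero cells: percent undefined, density zero
  empty <- ct[0, ]
  attr(empty, "mpp") <- 0.5
  s_e <- summarize_region(empty, "CD8", annot)
  expect_true(is.na(s_e$percent_positive))
  expect_equal(s_e$density_positive, 0)
  expect_error(summarize_region(ct, "PD1", annot), "no labels")
})

test_that("densities and percentages are translation invariant", {
  p <- slide_sim_params(shape = c(256, 256), n_cells = 40, seed = 53)
  sim <- generate_multiround_slide(p)
  img <- sim$rounds$cd8
  shift <- 24L
  px <- array(255, dim(img$pixels))
  px[, (shift + 1):256, ] <- img$pixels[, 1:(256 - shift), ]
  img_sh <- rgb_image(px, img$mpp)
  annot <- region_annotation_set(list(
    list(vertices = square_vertices(40, 40, 170), class = "tumor")), img$mpp)
  annot_sh <- region_annotation_set(list(
    list(vertices = square_vertices(40 + shift, 40, 170), class = "tumor")),
    img$mpp)
  run <- function(im, an) {
    cells <- detect_cells(im, stain_matrix("AEC"), detection_params(), an)
    cells <- classify_positive(cells, "CD8", "cell", "mean", 0.12)
    summarize_region(cells, "CD8", an)
  }
  s1 <- run(img, annot); s2 <- run(img_sh, annot_sh)
  expect_equal(s1$n_total_cells, s2$n_total_cells)
  expect_equal(s1$density_positive, s2$density_positive, tolerance = 1e-9)
  expect_equal(s1$percent_positive, s2$percent_positive, tolerance = 1e-9)
})

test_that("density is stable under a resolution change of the same scene", {
  p <- slide_sim_params(shape = c(256, 256), n_cells = 40, seed = 54,
                        markers = c(cd8 = 0.5))
  sim <- generate_multiround_slide(p)
  img1 <- sim$rounds$cd8                       # 0.5 um/px
  px2 <- as.array(EBImage::resize(EBImage::Image(img1$pixels / 255,
                                                 colormode = "Color"),
                                  128, 128)) * 255
  img2 <- rgb_image(pmin(pmax(px2, 0), 255), mpp = 1.0)  # same scene, 2x mpp
  run <- function(im, shape) {
    an <- full_tile_annotation(shape, im$mpp)
    cells <- detect_cells(im, stain_matrix("AEC"), detection_params(), an)
    cells <- classify_positive(cells, "CD8", "cell", "mean", 0.12)
    summarize_region(cells, "CD8", an)
  }
  s1 <- run(img1, c(256, 256)); s2 <- run(img2, c(128, 128))
  expect_equal(s1$analysis_area_mm2, s2$analysis_area_mm2, tolerance = 1e-9)
  expect_lt(abs(s2$density_positive - s1$density_positive) /
            max(s1$density_positive, 1), 0.2)
})

test_that("mark-up images outline every cell in its label color", {
  img <- rgb_image(array(250, c(200, 200, 3)), 0.5)
  grid <- expand.grid(x = c(40, 100, 160), y = c(40, 100, 160))
  cells <- make_cell_table(x = grid$x, y = grid$y,
                           chrom_mean = rep(c(0.5, 0.01, 0.5), 3))
  cells <- classify_positive(cells, "CD8", "cell", "mean", 0.12)
  mk <- render_markup(img, cells, "CD8")
  overlay <- (mk$pixels[, , 1] != img$pixels[, , 1]) |
             (mk$pixels[, , 2] != img$pixels[, , 2]) |
             (mk$pixels[, , 3] != img$pixels[, , 3])
  n_outline <- max(EBImage::bwlabel(overlay))
  expect_equal(n_outline, nrow(cells))
  # all-positive labels use only the positive color
  all_pos <- cells; all_pos$marker_CD8 <- "positive"
  mk2 <- render_markup(img, all_pos, "CD8")
  changed <- which(mk2$pixels[, , 1] != img$pixels[, , 1] |
                   mk2$pixels[, , 2] != img$pixels[, , 2] |
                   mk2$pixels[, , 3] != img$pixels[, , 3])
  r <- mk2$pixels[, , 1][changed]
  g <- mk2$pixels[, , 2][changed]
  b <- mk2$pixels[, , 3][changed]
  expect_true(all(r == 255 & g == 0 & b == 0))
  # zero cells: unchanged image
  none <- cells[0, ]
  attr(none, "mpp") <- img$mpp
  expect_equal(render_markup(img, none, "CD8")$pixels, img$pixels)
})
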