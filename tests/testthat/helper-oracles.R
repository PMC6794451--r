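# Independent oracles and small fixture builders used across test files.

# Brute-force exact two-sided signed-rank p by enumerating all 2^n sign
# assignments with an explicit loop over patterns (n <= 16).
oracle_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  wplus <- numeric(2^n)
  for (pat in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(pat, 2^(0:(n - 1))))
    wplus[pat + 1] <- sum(r[bits])
  }
  min(1, 2 * mean(wplus <= w_obs))
}

# sum of squared landmark residuals under similarity parameters
oracle_sse <- function(par, M, F) {
  s <- par[1]; th <- par[2]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pred <- t(s * R %*% t(M)) + matrix(par[3:4], nrow(M), 2, byrow = TRUE)
  sum((pred - F)^2)
}

# numeric minimizer of the similarity SSE (local refinement from a start)
oracle_fit_similarity <- function(M, F, start) {
  fit <- stats::optim(start, oracle_sse, M = M, F = F, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 2000))
  fit2 <- stats::optim(fit$par, oracle_sse, M = M, F = F,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-16, maxit = 5000))
  if (fit2$value < fit$value) fit2$par else fit$par
}

# write a small GeoJSON FeatureCollection of polygons to a temp file
write_test_geojson <- function(features) {
  path <- tempfile(fileext = ".geojson")
  feats <- lapply(features, function(f) {
    ring <- lapply(seq_len(nrow(f$vertices)), function(i)
      as.numeric(f$vertices[i, ]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(class = f$class,
                           name = if (is.null(f$name)) "f" else f$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

square_vertices <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# minimal hand-built classified cell table
make_cell_table <- function(x, y, chrom_mean, mpp = 0.5) {
  df <- data.frame(id = seq_along(x), x = x, y = y,
                   nucleus_area_um2 = rep(30, length(x)))
  for (comp in c("nucleus", "cell", "cytoplasm")) {
    df[[paste0(comp, "_hematoxylin_mean")]] <- 0.5
    df[[paste0(comp, "_hematoxylin_max")]] <- 0.7
    df[[paste0(comp, "_chromogen_mean")]] <- chrom_mean
    df[[paste0(comp, "_chromogen_max")]] <- chrom_mean * 1.5
  }
  structure(df, mpp = mpp, markers = character(0),
            class = c("cell_table", "data.frame"))
}
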