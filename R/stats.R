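#' Exact two-sided Wilcoxon signed-rank test for paired samples
#'
#' Paired nonparametric test of a location shift between pre- and
#' post-treatment marker values. Differences `post - pre` are computed after
#' pairwise deletion of missing values; zero differences are dropped
#' (Wilcoxon's original treatment); absolute differences are mid-ranked; the
#' test statistic is `W = min(W+, W-)`, the smaller of the positive and
#' negative signed-rank sums. For `n <= 25` retained pairs the two-sided
#' p-value is exact: the null distribution of the signed-rank sum is obtained
#' by a dynamic program equivalent to full enumeration of all `2^n` sign
#' assignments (mid-ranks are doubled to integers, so ties are handled
#' exactly), and `p = min(1, 2 * P(W_null <= W))`. For larger `n` a normal
#' approximation with continuity and tie correction is used.
#'
#' @param pre,post numeric vectors of equal length; `NA` allowed and deleted
#'   pairwise.
#' @param exact_max largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return A list of class `paired_test_result` with elements `n_used`
#'   (pairs retained after deletion and zero-dropping), `w_statistic`,
#'   `p_two_sided` and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))  # p = 0.25
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 25L) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must have equal length")
  keep <- !(is.na(pre) | is.na(post))
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("test undefined: all paired differences are zero or missing")
  r <- rank(abs(d))                     # mid-ranks
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= exact_max) {
    p <- min(1, 2 * .signed_rank_cdf(r, w))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sig2)    # w <= mu, continuity toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  structure(list(n_used = n, w_statistic = w, p_two_sided = p,
                 method = method),
            class = "paired_test_result")
}

# P(W <= w) where W is the signed-rank sum of a uniformly random sign
# assignment over mid-ranks r. Exact: ranks doubled to integers, counts of
# achievable sums accumulated by dynamic programming over 2^n assignments.
.signed_rank_cdf <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  stopifnot(max(abs(2 * r - r2)) < 1e-9)
  total <- sum(r2)
  counts <- numeric(total + 1L)        # counts[s + 1] = #assignments with sum s
  counts[1L] <- 1
  for (k in r2) {
    shifted <- c(numeric(k), counts[seq_len(total + 1L - k)])
    counts <- counts + shifted
  }
  sum(counts[seq_len(min(total, floor(2 * w)) + 1L)]) / 2^length(r2)
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s): n = %d, W = %g, two-sided p = %.4g\n",
              x$method, x$n_used, x$w_statistic, x$p_two_sided))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks after pairwise deletion. The
#' default two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' when `|rho| = 1` the exact permutation bound `2 / n!` is reported instead.
#' `method = "exact"` enumerates all `n!` rank permutations (n <= 9).
#'
#' @param x,y numeric vectors of equal length; `NA` deleted pairwise.
#' @param method `"t_approx"` (default) or `"exact"`.
#' @return A list of class `correlation_result` with `rho`, `p_two_sided`, `n`.
#' @export
spearman_correlation <- function(x, y, method = c("t_approx", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks")
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 9L) stop("exact permutation p only supported for n <= 9")
    p <- .spearman_exact_p(rx, ry)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- min(1, 2 / factorial(n))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_two_sided = p, n = n),
            class = "correlation_result")
}

# two-sided permutation p for Spearman rho by full enumeration of the n!
# orderings of y-ranks (ties in y handled by permuting the tied mid-ranks)
.spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  obs <- abs(stats::cor(rx, ry))
  count <- 0L; total <- 0L
  perm_rec <- function(remaining, acc) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(stats::cor(rx, acc)) >= obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    for (i in seq_along(remaining))
      perm_rec(remaining[-i], c(acc, remaining[i]))
  }
  perm_rec(ry, numeric(0))
  count / total
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.4f, n = %d, two-sided p = %.4g\n",
              x$rho, x$n, x$p_two_sided))
  invisible(x)
}

#' Summary descriptives (mean, SEM, median, range)
#'
#' @param values numeric vector; `NA` removed.
#' @return A list of class `descriptives` with `n`, `mean`, `sem`
#'   (`sd / sqrt(n)` with the n-1 denominator; `NA` when n < 2), `median`
#'   (mean of the central two values for even n), `min`, `max`.
#' @export
descriptives <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no non-missing values")
  structure(list(
    n = n,
    mean = mean(values),
    sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
    median = stats::median(values),
    min = min(values),
    max = max(values)), class = "descriptives")
}

#' @export
print.descriptives <- function(x, ...) {
  cat(sprintf("n = %d, mean +/- SEM %.4g +/- %.4g, median %.4g, range [%.4g, %.4g]\n",
              x$n, x$mean, x$sem, x$median, x$min, x$max))
  invisible(x)
}

#' Post/pre marker ratio
#'
#' Ratio of the post-treatment to the pre-treatment value, as tabulated per
#' patient for CD8 density. Undefined (`NA`) when the pre value is zero or
#' either value is missing; pre must be non-negative.
#'
#' @param pre,post numeric vectors (recycled to common length).
#' @return numeric vector of ratios.
#' @export
post_pre_ratio <- function(pre, post) {
  out <- post / pre
  out[!is.na(pre) & pre == 0] <- NA_real_
  out
}

#' Lesion response classification from longest-diameter change
#'
#' RECIST-style classes of a surgically removed post-treatment lesion
#' relative to baseline: regressing if the longest diameter changed by
#' -30% or more, progressing if by +20% or more, stable otherwise.
#'
#' @param baseline_diameter,post_diameter positive lesion diameters (any
#'   common unit).
#' @return character vector in `{"regressing", "stable", "progressing"}`.
#' @export
classify_lesion_response <- function(baseline_diameter, post_diameter) {
  if (any(baseline_diameter <= 0, na.rm = TRUE) ||
      any(post_diameter <= 0, na.rm = TRUE))
    stop("diameters must be positive")
  delta <- 100 * (post_diameter - baseline_diameter) / baseline_diameter
  ifelse(delta <= -30, "regressing",
         ifelse(delta >= 20, "progressing", "stable"))
}

# recognized prior-treatment tokens
.IMMUNO_TOKENS <- c("ipi", "biot", "bioct", "biotct", "il-2", "il2", "ifn")
.NAIVE_TOKENS <- c("no", "ct", "rt")

#' Treatment-group stratification from the prior-treatments field
#'
#' Patients are stratified by what they received *before* vaccination:
#' `immuno_treated` if the prior-treatment string contains any
#' immune-modulating token (Ipilimumab "Ipi", biological/cytokine therapy
#' "Biot"/"BioCT", "IL-2", "IFN"), else `naive_ct_rt` (treatment-naive,
#' chemotherapy "CT", or radiotherapy "RT"). Tokens are matched
#' case-insensitively after splitting on commas, slashes, plus signs and
#' whitespace; a trailing `*` is ignored.
#'
#' @param prior_treatments character vector of prior-treatment strings (the
#'   pre-slash segment of a combined previous/following field).
#' @return character vector in `{"naive_ct_rt", "immuno_treated"}`.
#' @export
assign_cohort_group <- function(prior_treatments) {
  vapply(prior_treatments, function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      stop("empty prior-treatments string")
    toks <- tolower(trimws(strsplit(s, "[,/+[:space:]]+")[[1]]))
    toks <- sub("\\*$", "", toks)
    toks <- toks[nzchar(toks)]
    unknown <- setdiff(toks, c(.IMMUNO_TOKENS, .NAIVE_TOKENS))
    if (length(unknown))
      stop(sprintf("unrecognized prior-treatment token(s): %s",
                   paste(unknown, collapse = ", ")))
    if (any(toks %in% .IMMUNO_TOKENS)) "immuno_treated" else "naive_ct_rt"
  }, character(1), USE.NAMES = FALSE)
}
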