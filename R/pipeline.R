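#' Reproduce the cohort-level statistics of the study table
#'
#' Runs the full statistical layer over a patient table (by default the
#' packaged fixture, see [table1_cohort()]): exact paired Wilcoxon
#' signed-rank tests of PDL1 percent positivity (all assessable pairs, and
#' within the naive/CT/RT and immuno-treated strata derived from the
#' prior-treatment strings), group means with SEM, the count of pairs with
#' a PDL1 increase, CD8 post/pre-ratio descriptives by sampling status, and
#' the biopsy-timing descriptives. Every quantity is reported twice: `raw`
#' (full precision) and `display` (formatted to conventional reporting
#' precision: p-values to 4 decimals, summary statistics to 4 significant
#' digits).
#'
#' @param cohort a `paired_cohort`; default the packaged fixture.
#' @return An object of class `table1_report`: list with `raw` and
#'   `display`.
#' @export
reproduce_table1_stats <- function(cohort = table1_cohort()) {
  if (!inherits(cohort, "paired_cohort"))
    stop("`cohort` must be a paired_cohort (see read_cohort_table)")
  need <- c("pdl1_pre", "pdl1_post", "cd8_ratio_post_pre",
            "months_surgery_to_vax", "months_vax_to_biopsy",
            "sampling", "group")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(cohort) == 0L) stop("empty cohort table")

  assess <- !(is.na(cohort$pdl1_pre) | is.na(cohort$pdl1_post))
  strata <- list(all = assess,
                 naive_ct_rt = assess & cohort$group == "naive_ct_rt",
                 immuno_treated = assess & cohort$group == "immuno_treated")
  tests <- lapply(strata, function(keep)
    wilcoxon_signed_rank(cohort$pdl1_pre[keep], cohort$pdl1_post[keep]))
  means <- lapply(strata, function(keep) list(
    pre = descriptives(cohort$pdl1_pre[keep]),
    post = descriptives(cohort$pdl1_post[keep])))

  d <- cohort$pdl1_post[assess] - cohort$pdl1_pre[assess]
  inc <- sum(d > 0)

  post_trt <- cohort$sampling == "post_treatment"
  on_imm <- cohort$sampling == "on_treatment" &
    cohort$group == "immuno_treated"
  ratio_post <- descriptives(cohort$cd8_ratio_post_pre[post_trt])
  ratio_on_imm <- descriptives(cohort$cd8_ratio_post_pre[on_imm])

  timing_surgery <- descriptives(cohort$months_surgery_to_vax)
  timing_biopsy_post <- descriptives(cohort$months_vax_to_biopsy[post_trt])

  raw <- list(
    pdl1 = lapply(names(tests), function(g) list(
      group = g,
      n = tests[[g]]$n_used,
      w = tests[[g]]$w_statistic,
      p = tests[[g]]$p_two_sided,
      mean_pre = means[[g]]$pre$mean, sem_pre = means[[g]]$pre$sem,
      mean_post = means[[g]]$post$mean, sem_post = means[[g]]$post$sem)),
    n_pdl1_pairs = sum(assess),
    n_pdl1_increase = inc,
    cd8_ratio_post_treatment = list(n = ratio_post$n, mean = ratio_post$mean,
                                    sem = ratio_post$sem),
    cd8_ratio_on_treatment_immuno = list(n = ratio_on_imm$n,
                                         mean = ratio_on_imm$mean,
                                         sem = ratio_on_imm$sem),
    months_surgery_to_vax_mean = timing_surgery$mean,
    months_vax_to_biopsy_post_treatment_mean = timing_biopsy_post$mean,
    months_vax_to_biopsy_post_treatment_median = timing_biopsy_post$median)
  names(raw$pdl1) <- names(tests)

  fmt_p <- function(p) sprintf("%.4f", p)
  fmt <- function(x) formatC(signif(x, 4), format = "fg", flag = "#")
  display <- list(
    pdl1 = lapply(raw$pdl1, function(g) sprintf(
      "%s: n = %d, PDL1%% %s +/- %s (pre) vs %s +/- %s (post), p = %s",
      g$group, g$n, fmt(g$mean_pre), fmt(g$sem_pre),
      fmt(g$mean_post), fmt(g$sem_post), fmt_p(g$p))),
    pdl1_increase = sprintf("%d of %d assessable pairs with a PDL1 increase",
                            inc, sum(assess)),
    cd8_ratio = sprintf(
      "CD8 post/pre ratio: %s +/- %s (post-treatment, n = %d); %s +/- %s (on-treatment immuno, n = %d)",
      fmt(ratio_post$mean), fmt(ratio_post$sem), ratio_post$n,
      fmt(ratio_on_imm$mean), fmt(ratio_on_imm$sem), ratio_on_imm$n),
    timing = sprintf(
      "months surgery-to-vaccine mean %s; post-treatment vaccine-to-biopsy mean %s (median %s)",
      fmt(timing_surgery$mean), fmt(timing_biopsy_post$mean),
      fmt(timing_biopsy_post$median)))
  structure(list(raw = raw, display = display), class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Cohort statistics report\n")
  for (line in x$display$pdl1) cat(" ", line, "\n")
  cat(" ", x$display$pdl1_increase, "\n")
  cat(" ", x$display$cd8_ratio, "\n")
  cat(" ", x$display$timing, "\n")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes both the raw (full-precision) and display (formatted) fields, so
#' downstream golden tests can compare raw values while documents quote the
#' display strings.
#'
#' @param report a `table1_report` (or any list).
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
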