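# The statistical layer: SEM, unpaired t test (raw values or published
# mean +/- SEM summaries), one-way ANOVA with Tukey HSD, significance
# stars, and a small plain-text report.

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square
#' root of the sample size.
#'
#' @param x numeric vector with at least 2 values.
#' @return The SEM.
#' @examples
#' sem(c(0.2, 0.3))  # 0.05
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need n >= 2 for a SEM", call. = FALSE)
  stats::sd(x) / sqrt(length(x))
}

#' Significance stars
#'
#' The usual legend convention: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Group summary for summary-form tests
#'
#' Packages a published group summary (mean +/- SEM, n) so that
#' [unpaired_t()] can reconstruct a test when raw replicate values are
#' unavailable.
#'
#' @param mean group mean.
#' @param sem standard error of the mean (>= 0).
#' @param n number of independent replicates (>= 2).
#' @param label optional group label.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n, label = NULL) {
  stopifnot_scalar(sem, "sem", 0)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = as.integer(n), label = label),
            class = "group_summary")
}

test_result <- function(method, statistic, df, p.value, estimate = NULL,
                        pairwise = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p.value, estimate = estimate,
                 stars = significance_stars(p.value), pairwise = pairwise),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g (%s)\n", x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p.value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("  pairwise comparisons (Tukey-adjusted):\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Unpaired two-sample t test
#'
#' Two-sided Student t test with pooled variance (the convention behind
#' an "unpaired t test" in common analysis software), either from raw
#' values or from published summaries. With two [group_summary()]
#' objects the statistic is \eqn{t = \Delta \bar x /
#' \sqrt{SEM_1^2 + SEM_2^2}} on \eqn{n_1 + n_2 - 2} degrees of freedom.
#'
#' @param a,b numeric vectors (n >= 2 each), or two [group_summary()]
#'   objects.
#' @param welch use the Welch unequal-variance form instead of pooled
#'   (raw values only).
#' @return A `test_result` with `statistic`, `df`, `p.value`, `estimate`
#'   (difference in means) and significance `stars`.
#' @examples
#' unpaired_t(group_summary(98.7, 0.27, 3), group_summary(81.5, 2.2, 3))
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  if (inherits(a, "group_summary")) {
    stopifnot(inherits(b, "group_summary"))
    d <- a$mean - b$mean
    t <- d / sqrt(a$sem^2 + b$sem^2)
    df <- a$n + b$n - 2L
    return(test_result("Unpaired t test (from group summaries)", t, df,
                       2 * stats::pt(-abs(t), df), estimate = d))
  }
  if (length(a[!is.na(a)]) < 2 || length(b[!is.na(b)]) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = !welch)
  test_result(if (welch) "Welch unpaired t test" else "Unpaired t test (pooled)",
              unname(ht$statistic), unname(ht$parameter), ht$p.value,
              estimate = unname(diff(rev(ht$estimate))))
}

#' One-way ANOVA with Tukey HSD post-test
#'
#' Ordinary one-way ANOVA across three or more groups followed by
#' Tukey's multiple-comparison post-test (all pairs, studentized-range
#' adjusted p-values).
#'
#' @param groups named list of >= 3 numeric vectors, each n >= 2.
#' @return A `test_result` with the F statistic, degrees of freedom,
#'   overall p-value, and a `pairwise` data frame (`comparison`, `diff`,
#'   `p_unadj` — the per-pair p from the same pooled error without
#'   multiplicity adjustment — `p_adj`, `stars`).
#' @examples
#' set.seed(1)
#' anova_tukey(list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(4)))
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need >= 3 groups", call. = FALSE)
  if (any(vapply(groups, function(g) sum(!is.na(g)), 0L) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), lengths(groups)),
                                 levels = names(groups)))
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  # unadjusted per-pair p from the same pooled error (MSE, residual df),
  # so the Tukey studentized-range adjustment is the only difference
  mse <- an["Residuals", "Mean Sq"]; dfr <- an["Residuals", "Df"]
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  key <- paste(pairs[2, ], pairs[1, ], sep = "-")
  tstat <- abs(tk[key, "diff"]) / se
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_unadj = unname(2 * stats::pt(-tstat, dfr))[
                           match(rownames(tk), key)],
                         p_adj = tk[, "p adj"],
                         stars = significance_stars(tk[, "p adj"]),
                         row.names = NULL, stringsAsFactors = FALSE)
  test_result("One-way ANOVA with Tukey HSD post-test",
              an["group", "F value"], c(an["group", "Df"], an["Residuals", "Df"]),
              an["group", "Pr(>F)"], pairwise = pairwise)
}

#' Plain-text statistics report
#'
#' Summarizes each group as n, mean +/- SEM and runs the test matching
#' the design: an unpaired t test for two groups, one-way ANOVA with
#' Tukey post-test for three or more.
#'
#' @param groups named list of numeric vectors.
#' @param file optional path; the group summary table is written as TSV
#'   to `<file>.tsv` and the report text to `<file>.txt`.
#' @return List with `summaries` (data frame `group`, `n`, `mean`,
#'   `sem`), `test` (a `test_result`) and `text` (report lines),
#'   invisibly when `file` is given.
#' @export
stats_report <- function(groups, file = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  summaries <- data.frame(
    group = names(groups), n = lengths(groups),
    mean = vapply(groups, mean, 0), sem = vapply(groups, sem, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  test <- if (length(groups) == 2) unpaired_t(groups[[1]], groups[[2]])
          else anova_tukey(groups)
  text <- c("Group summaries (mean +/- SEM):",
            sprintf("  %s: n = %d, %.4g +/- %.4g", summaries$group,
                    summaries$n, summaries$mean, summaries$sem),
            "", utils::capture.output(print(test)))
  out <- list(summaries = summaries, test = test, text = text)
  if (!is.null(file)) {
    write.table(summaries, paste0(file, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(text, paste0(file, ".txt"))
    return(invisible(out))
  }
  out
}
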