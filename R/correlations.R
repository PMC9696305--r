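new_correlation_result <- function(r, n, ci_low, ci_high, p_value = NA_real_,
                                   label = "") {
  structure(list(r = r, n = n, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, label = label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f (95%% CI %.3f, %.3f), n = %d", x$label, x$r,
              x$ci_low, x$ci_high, x$n))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3L || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Intra-pair Pearson correlation within a zygosity group
#'
#' The headline statistic of the classical twin design: how alike co-twins
#' are. `mode = "double_entry"` (default) enters every pair in both member
#' orders so the estimate is invariant to the within-pair ordering
#' convention — the intraclass-style estimator. `mode = "single_entry"` is
#' the plain Pearson correlation between first and second members under the
#' cohort's deterministic ordering. The 95% CI is Fisher-z,
#' `tanh(atanh(r) +/- 1.96/sqrt(n - 3))`, with `n` the number of pairs in
#' both modes (double entry does not pretend to have 2n observations).
#'
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param mode `"double_entry"` (default) or `"single_entry"`.
#' @param level confidence level for the Fisher-z interval.
#' @return a `correlation_result`: `r`, `n` (pairs), `ci_low`, `ci_high`.
#' @export
intrapair_correlation <- function(cohort, phenotype, zygosity,
                                  mode = c("double_entry", "single_entry"),
                                  level = 0.95) {
  mode <- match.arg(mode)
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  pw <- pair_wide(cohort, phenotype, zygosity = zygosity)
  n <- nrow(pw)
  if (n < 3L) {
    stop("need at least 3 complete ", zygosity, " pairs (have ", n, ")",
         call. = FALSE)
  }
  if (mode == "double_entry") {
    x <- c(pw$y1, pw$y2)
    y <- c(pw$y2, pw$y1)
  } else {
    x <- pw$y1
    y <- pw$y2
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: intra-pair correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  ci <- fisher_ci(r, n, level)
  new_correlation_result(r, n, ci[1L], ci[2L],
                         label = paste0("r", zygosity, "(", phenotype, ")"))
}

#' Cross-method agreement between two phenotype columns
#'
#' Pearson correlation over individuals (both twins of every pair included)
#' between two measurements of the same quantity, e.g. the same structure
#' volume from two segmentation pipelines. The two-sided p-value comes from
#' `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2` degrees of freedom; the CI is
#' Fisher-z with `n` the individual count.
#'
#' @param cohort a [twin_cohort].
#' @param phenotype_a,phenotype_b phenotype columns to compare.
#' @param level confidence level.
#' @return a `correlation_result` with `p_value` set.
#' @export
method_agreement <- function(cohort, phenotype_a, phenotype_b,
                             level = 0.95) {
  stopifnot(inherits(cohort, "twin_cohort"))
  for (p in c(phenotype_a, phenotype_b)) {
    if (!p %in% phenotype_names(cohort)) {
      stop("unknown phenotype: ", p, call. = FALSE)
    }
  }
  df <- as.data.frame(cohort)
  ok <- stats::complete.cases(df[, c(phenotype_a, phenotype_b)])
  x <- df[[phenotype_a]][ok]
  y <- df[[phenotype_b]][ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 individuals with both values",
                   call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- 0
  }
  ci <- fisher_ci(r, n, level)
  new_correlation_result(r, n, ci[1L], ci[2L], p_value = p,
                         label = paste0("r(", phenotype_a, ", ",
                                        phenotype_b, ")"))
}
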