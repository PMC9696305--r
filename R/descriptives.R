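new_group_comparison <- function(test_name, statistic, p_value, n_a, n_b,
                                 details = list()) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_a = n_a, n_b = n_b,
                 details = details),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Chi-squared test on a 2x2 contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' marginals; the Yates variant shrinks each deviation by 0.5 (never past
#' zero) before squaring. Both variants are first-class because published
#' tables often mix them. p from the chi-squared(1) upper tail.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction.
#' @return a `group_comparison` (`n_a`, `n_b` are the row totals).
#' @export
chi_squared_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal: test undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  new_group_comparison(
    test_name = if (yates) "chi-squared (Yates)" else "chi-squared (Pearson)",
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_a = sum(table[1L, ]), n_b = sum(table[2L, ]),
    details = list(df = unname(ht$parameter), yates = yates,
                   expected = ht$expected))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `df = n_a + n_b - 2` and a two-sided p-value.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return a `group_comparison`.
#' @export
students_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) stop("zero pooled variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  new_group_comparison("Student t (pooled)", unname(ht$statistic),
                       ht$p.value, length(a), length(b),
                       details = list(df = unname(ht$parameter),
                                      mean_a = mean(a), mean_b = mean(b)))
}

# All distinct values of U_a over assignments of n_a of the pooled midranks
# to group a: exhaustive enumeration, valid with ties.
mwu_enumerate <- function(ranks, n_a) {
  idx <- utils::combn(length(ranks), n_a)
  ua <- colSums(matrix(ranks[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
  ua
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. `method = "exact"` enumerates every
#' assignment of the pooled ranks to the two groups (capped at a combined
#' sample size of 12) and reports the two-sided tail probability of the
#' observed `U = min(U_a, U_b)`; `"normal_approx"` uses the tie-corrected
#' normal approximation with a continuity correction. `"auto"` picks exact
#' when the cap allows and there is no practical obstacle.
#'
#' @param a,b numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return a `group_comparison` with `statistic = U`.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact",
                                            "normal_approx")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (n_a < 1L || n_b < 1L) stop("both groups need data", call. = FALSE)
  if (method == "exact" && n > 12L) {
    stop("exact enumeration capped at 12 combined observations; ",
         "use method = 'normal_approx'", call. = FALSE)
  }
  if (method == "auto") method <- if (n <= 12L) "exact" else "normal_approx"

  ranks <- rank(c(a, b))
  u_a <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)

  if (method == "exact") {
    ua_all <- mwu_enumerate(ranks, n_a)
    # two-sided tail of the (symmetric) permutation distribution of U_a
    eps <- 1e-9
    p <- (sum(ua_all <= u + eps) + sum(ua_all >= n_a * n_b - u - eps)) /
      length(ua_all)
    p <- min(1, p)
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(ranks)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_a - mu)
      z <- (abs(z) - 0.5) / sqrt(sigma2)   # continuity correction
      z <- max(z, 0)
      p <- 2 * stats::pnorm(-z)
      p <- min(1, p)
    }
  }
  new_group_comparison(paste0("Mann-Whitney U (", method, ")"), u, p,
                       n_a, n_b,
                       details = list(u_a = u_a, u_b = u_b,
                                      median_a = stats::median(a),
                                      median_b = stats::median(b)))
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value (Royston's AS R94 approximation, as implemented
#' in `stats::shapiro.test`); sample size 3-5000.
#'
#' @param x numeric sample.
#' @return a `group_comparison` with `statistic = W` (`n_b` is 0).
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("constant sample", call. = FALSE)
  ht <- stats::shapiro.test(x)
  new_group_comparison("Shapiro-Wilk", unname(ht$statistic), ht$p.value,
                       length(x), 0L)
}

#' Compare MZ and DZ groups variable by variable
#'
#' Builds a characteristics table: each continuous variable is screened for
#' normality with Shapiro-Wilk (per group) and routed to the pooled t-test
#' when both groups look normal, otherwise to the Mann-Whitney U test; each
#' binary variable goes to the 2x2 chi-squared test. Variables observed at a
#' single level overall are skipped with a warning.
#'
#' @param cohort a [twin_cohort].
#' @param continuous names of continuous columns to compare (phenotypes or
#'   covariates); defaults to `"age"` plus all phenotype columns.
#' @param binary names of binary columns; defaults to `"sex"`.
#' @param normality_alpha Shapiro-Wilk p below which a variable is treated
#'   as non-normal (default 0.05).
#' @param yates use the continuity correction for binary variables.
#' @return data.frame: variable, test, statistic, p_value, n_mz, n_dz.
#' @export
describe_cohort <- function(cohort, continuous = NULL, binary = "sex",
                            normality_alpha = 0.05, yates = FALSE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  df <- as.data.frame(cohort)
  if (is.null(continuous)) continuous <- c("age", phenotype_names(cohort))

  rows <- list()
  add_row <- function(variable, gc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = gc$test_name, statistic = gc$statistic,
      p_value = gc$p_value, n_mz = gc$n_a, n_dz = gc$n_b,
      stringsAsFactors = FALSE)
  }

  for (v in continuous) {
    x <- df[[v]][df$zygosity == "MZ"]
    y <- df[[v]][df$zygosity == "DZ"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    normal <- tryCatch(
      shapiro_wilk(x)$p_value >= normality_alpha &&
        shapiro_wilk(y)$p_value >= normality_alpha,
      error = function(e) FALSE)
    gc <- if (normal) students_t_test(x, y)
          else mann_whitney_u(x, y, method = "normal_approx")
    add_row(v, gc)
  }
  for (v in binary) {
    vals <- df[[v]]
    levs <- sort(unique(vals[!is.na(vals)]))
    if (length(levs) != 2L) {
      warning("binary variable '", v, "' observed at ", length(levs),
              " level(s); skipped", call. = FALSE)
      next
    }
    tab <- rbind(
      MZ = c(sum(vals == levs[1L] & df$zygosity == "MZ", na.rm = TRUE),
             sum(vals == levs[2L] & df$zygosity == "MZ", na.rm = TRUE)),
      DZ = c(sum(vals == levs[1L] & df$zygosity == "DZ", na.rm = TRUE),
             sum(vals == levs[2L] & df$zygosity == "DZ", na.rm = TRUE)))
    gc <- chi_squared_2x2(tab, yates = yates)
    add_row(v, gc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
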