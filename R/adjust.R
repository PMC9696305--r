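#' Age- and sex-adjust a phenotype by least-squares residualization
#'
#' Replaces the phenotype with residuals from an ordinary least-squares fit
#' on an intercept plus the requested covariates, computed over individuals.
#' Age is centered before regression (numerical conditioning; residuals are
#' unaffected) and sex is coded female = 0, male = 1. With
#' `pooling = "pooled"` one regression is fitted across all individuals;
#' `"by_zygosity"` fits MZ and DZ separately — the sensitivity check used
#' when the two zygosity groups differ in age.
#'
#' A covariate that is constant within a fitted group (e.g. all one sex) is
#' dropped from that group's design with a warning rather than producing a
#' rank-deficient fit.
#'
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column to adjust.
#' @param covariates non-empty subset of `c("age", "sex")`.
#' @param pooling `"pooled"` (default) or `"by_zygosity"`.
#' @return the cohort with the phenotype column replaced by residuals.
#' @export
residualize <- function(cohort, phenotype, covariates = c("age", "sex"),
                        pooling = c("pooled", "by_zygosity")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  pooling <- match.arg(pooling)
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  if (!phenotype %in% phenotype_names(cohort)) {
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  }

  df <- as.data.frame(cohort)
  groups <- if (pooling == "pooled") list(all = seq_len(nrow(df)))
            else split(seq_len(nrow(df)), df$zygosity)

  res <- df[[phenotype]]
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    sub <- df[idx, , drop = FALSE]
    ok <- !is.na(sub[[phenotype]])
    if (!any(ok)) next
    design <- data.frame(y = sub[[phenotype]][ok])
    keep <- character()
    if ("age" %in% covariates) {
      age_c <- sub$age[ok] - mean(sub$age[ok])
      if (stats::var(age_c) > 0) {
        design$age <- age_c
        keep <- c(keep, "age")
      } else {
        warning("covariate 'age' constant in group '", gname,
                "'; dropped from the adjustment", call. = FALSE)
      }
    }
    if ("sex" %in% covariates) {
      sex01 <- as.numeric(sub$sex[ok] == "M")
      if (stats::var(sex01) > 0) {
        design$sex <- sex01
        keep <- c(keep, "sex")
      } else {
        warning("covariate 'sex' constant in group '", gname,
                "'; dropped from the adjustment", call. = FALSE)
      }
    }
    n_par <- length(keep) + 1L
    if (sum(ok) < n_par + 2L) {
      stop("too few complete observations (", sum(ok), ") to adjust for ",
           paste(covariates, collapse = "+"), call. = FALSE)
    }
    fit <- stats::lm(y ~ ., data = design)
    res[idx][ok] <- stats::residuals(fit)
  }

  df[[phenotype]] <- res
  twin_cohort(df, phenotypes = phenotype_names(cohort),
              provenance = attr(cohort, "provenance"))
}
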