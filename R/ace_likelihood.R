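MODEL_FREE_PATHS <- list(
  ACE = c("a", "c", "e"),
  AE  = c("a", "e"),
  CE  = c("c", "e"),
  E   = "e",
  ADE = c("a", "d", "e")
)

#' Specify a twin variance-component model
#'
#' The label fixes which path coefficients are free: `ACE` (additive genetic,
#' shared environment, unique environment), the nested reductions `AE`, `CE`
#' and `E`, and `ADE` which swaps shared environment for dominance. C and D
#' cannot be estimated simultaneously from MZ/DZ data alone (they are
#' confounded), so an ACDE label is rejected by construction.
#'
#' @param label one of `"ACE"`, `"AE"`, `"CE"`, `"E"`, `"ADE"`.
#' @param covariate_handling `"pre_residualized"` (phenotype already
#'   adjusted; single intercept in the means model) or `"means_model"`
#'   (intercept + age and sex effects estimated inside the likelihood).
#' @return a `model_spec` list with `label`, `free_paths`,
#'   `covariate_handling`.
#' @export
model_spec <- function(label = c("ACE", "AE", "CE", "E", "ADE"),
                       covariate_handling = c("pre_residualized",
                                              "means_model")) {
  label <- match.arg(label)
  covariate_handling <- match.arg(covariate_handling)
  structure(list(label = label,
                 free_paths = MODEL_FREE_PATHS[[label]],
                 covariate_handling = covariate_handling),
            class = "model_spec")
}

# Pair covariance structure implied by path coefficients.
# Diagonal: a^2+c^2+d^2+e^2 for both zygosities; off-diagonal reflects the
# genetic sharing: MZ a^2+d^2+c^2, DZ a^2/2+d^2/4+c^2.
pair_covariance <- function(paths) {
  a2 <- if ("a" %in% names(paths)) paths[["a"]]^2 else 0
  c2 <- if ("c" %in% names(paths)) paths[["c"]]^2 else 0
  d2 <- if ("d" %in% names(paths)) paths[["d"]]^2 else 0
  e2 <- if ("e" %in% names(paths)) paths[["e"]]^2 else 0
  list(v = a2 + c2 + d2 + e2,
       off_mz = a2 + c2 + d2,
       off_dz = a2 / 2 + d2 / 4 + c2,
       raw = c(A = a2, C = c2, D = d2, E = e2))
}

# -2 log bivariate normal density summed over pairs for one zygosity group,
# given residuals r1, r2 (values minus their means).
neg2ll_group <- function(r1, r2, v, off) {
  n <- length(r1)
  if (n == 0L) return(0)
  det <- v^2 - off^2
  if (!is.finite(det) || det <= 0 || v <= 0) return(Inf)
  quad <- (v * (r1^2 + r2^2) - 2 * off * r1 * r2) / det
  n * (2 * log(2 * pi) + log(det)) + sum(quad)
}

#' -2 log-likelihood of a twin variance-component model
#'
#' Each pair contributes the bivariate normal density with common variance
#' `a^2 + c^2 + d^2 + e^2` on the diagonal and zygosity-specific within-pair
#' covariance (`a^2 + d^2 + c^2` for MZ, `a^2/2 + d^2/4 + c^2` for DZ).
#' Under `pre_residualized` both members' means equal the intercept `mu`;
#' under `means_model` the mean is `mu + beta_age * age + beta_sex * [male]`.
#' A non-positive-definite covariance yields `Inf` rather than an error, so
#' optimizers can probe freely.
#'
#' @param params named numeric vector: the free path coefficients of the
#'   model (`a`, `c`, `d`, `e` as applicable), `mu`, and for `means_model`
#'   also `beta_age` and `beta_sex`.
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column.
#' @param spec a [model_spec()].
#' @return scalar -2 log-likelihood (possibly `Inf`).
#' @export
neg2_loglik <- function(params, cohort, phenotype, spec) {
  stopifnot(inherits(spec, "model_spec"))
  missing_paths <- setdiff(spec$free_paths, names(params))
  if (length(missing_paths) > 0L || !"mu" %in% names(params)) {
    stop("params must name ", paste(spec$free_paths, collapse = ", "),
         " and mu", call. = FALSE)
  }
  cov <- pair_covariance(params[spec$free_paths])

  total <- 0
  for (zyg in c("MZ", "DZ")) {
    pw <- pair_wide(cohort, phenotype, zygosity = zyg)
    if (nrow(pw) == 0L) next
    m <- rep(params[["mu"]], nrow(pw))
    if (spec$covariate_handling == "means_model") {
      if (!all(c("beta_age", "beta_sex") %in% names(params))) {
        stop("means_model requires beta_age and beta_sex in params",
             call. = FALSE)
      }
      m <- m + params[["beta_age"]] * pw$age +
        params[["beta_sex"]] * as.numeric(pw$sex == "M")
    }
    off <- if (zyg == "MZ") cov$off_mz else cov$off_dz
    total <- total + neg2ll_group(pw$y1 - m, pw$y2 - m, cov$v, off)
  }
  total
}

# Sufficient statistics per zygosity for the pre-residualized likelihood:
# with a single intercept, -2LL depends on the data only through
# n, s = sum(y1 + y2), q = sum(y1^2 + y2^2), p = sum(y1 * y2),
# making each likelihood evaluation O(1).
suff_stats <- function(cohort, phenotype) {
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    pw <- pair_wide(cohort, phenotype, zygosity = zyg)
    out[[zyg]] <- list(n = nrow(pw),
                       s = sum(pw$y1 + pw$y2),
                       q = sum(pw$y1^2 + pw$y2^2),
                       p = sum(pw$y1 * pw$y2))
  }
  out$all_values <- {
    pw <- rbind(pair_wide(cohort, phenotype, zygosity = "MZ"),
                pair_wide(cohort, phenotype, zygosity = "DZ"))
    c(pw$y1, pw$y2)
  }
  out
}

neg2ll_from_stats <- function(st, v, off_mz, off_dz, mu) {
  total <- 0
  for (zyg in c("MZ", "DZ")) {
    g <- st[[zyg]]
    if (g$n == 0L) next
    off <- if (zyg == "MZ") off_mz else off_dz
    det <- v^2 - off^2
    if (!is.finite(det) || det <= 0 || v <= 0) return(Inf)
    ss_sq <- g$q - 2 * mu * g$s + 2 * g$n * mu^2
    ss_cp <- g$p - mu * g$s + g$n * mu^2
    total <- total + g$n * (2 * log(2 * pi) + log(det)) +
      (v * ss_sq - 2 * off * ss_cp) / det
  }
  total
}
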