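#' Simulation configuration for a synthetic twin cohort
#'
#' Defines the generative model behind [generate_cohort()]: each individual's
#' phenotype is mu + beta_age * age + beta_sex * [male] + a + c + d + e, where
#' a is the additive-genetic deviation (fully shared within MZ pairs,
#' correlated 1/2 within DZ pairs), d the dominance deviation (shared within
#' MZ, correlated 1/4 within DZ — the standard biometrical result), c the
#' shared-environment deviation (common to both members of every pair) and e
#' the unique-environment deviation (independent per individual).
#'
#' Defaults emulate a volumetric twin cohort: 43 MZ + 19 DZ same-sex pairs,
#' pair-level ages uniform on 25–75 years (median 50, IQR 25), 29% male
#' pairs. When `beta_age`/`beta_sex` are `NULL` they default to
#' `-0.02 * sqrt(total variance)` per year (age-related atrophy direction)
#' and `+0.5 * sqrt(total variance)` for males, so the adjustment stage has a
#' real signal to remove.
#'
#' @param n_mz,n_dz counts of MZ and DZ pairs.
#' @param var_a,var_c,var_d,var_e raw variance components (phenotype
#'   units^2); `var_a`, `var_c`, `var_d` >= 0, `var_e` > 0.
#' @param mean grand mean of the phenotype.
#' @param beta_age linear age effect per year, or `NULL` for the default.
#' @param beta_sex additive effect of male sex, or `NULL` for the default.
#' @param age_range length-2 numeric, uniform range of pair-level age.
#' @param p_male_pair probability that a pair is male (pairs are same-sex).
#' @param method_error_sd default noise SD used by the pipeline when adding a
#'   second measurement channel.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mz = 43L, n_dz = 19L,
                       var_a = 1, var_c = 0, var_d = 0, var_e = 1,
                       mean = 10, beta_age = NULL, beta_sex = NULL,
                       age_range = c(25, 75), p_male_pair = 0.29,
                       method_error_sd = 0, seed = 1L) {
  total <- var_a + var_c + var_d + var_e
  if (is.null(beta_age)) beta_age <- -0.02 * sqrt(total)
  if (is.null(beta_sex)) beta_sex <- 0.5 * sqrt(total)
  cfg <- list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
              var_a = var_a, var_c = var_c, var_d = var_d, var_e = var_e,
              mean = mean, beta_age = beta_age, beta_sex = beta_sex,
              age_range = as.numeric(age_range),
              p_male_pair = p_male_pair,
              method_error_sd = method_error_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (var_a < 0 || var_c < 0 || var_d < 0) {
      stop("var_a, var_c, var_d must be non-negative", call. = FALSE)
    }
    if (var_e <= 0) stop("var_e must be strictly positive", call. = FALSE)
    if (n_mz + n_dz < 1L) stop("need at least one pair", call. = FALSE)
    if (length(age_range) != 2L || age_range[1L] > age_range[2L]) {
      stop("age_range must be c(min, max) with min <= max", call. = FALSE)
    }
    if (p_male_pair < 0 || p_male_pair > 1) {
      stop("p_male_pair must lie in [0, 1]", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Generate a synthetic twin cohort
#'
#' Draws a cohort under the ACE(D) generative model of [sim_config()]. The
#' induced population moments are: MZ within-pair covariance
#' `var_a + var_d + var_c`; DZ within-pair covariance
#' `var_a/2 + var_d/4 + var_c`; individual variance
#' `var_a + var_d + var_c + var_e` (all before covariate effects). Both
#' members of a pair share age and sex. A fixed draw order (all MZ pairs,
#' then all DZ pairs; variable by variable) makes identical seeds give
#' identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @param phenotype name of the generated phenotype column.
#' @return a validated [twin_cohort] with `2 * (n_mz + n_dz)` rows.
#' @export
generate_cohort <- function(cfg, phenotype = "volume") {
  validate_sim_config(cfg)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  build_block <- function(n, zyg, id_prefix) {
    if (n == 0L) {
      return(NULL)
    }
    age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
    male <- stats::rbinom(n, 1L, cfg$p_male_pair)
    cshare <- stats::rnorm(n, 0, sqrt(cfg$var_c))
    if (zyg == "MZ") {
      a1 <- stats::rnorm(n, 0, sqrt(cfg$var_a))
      a2 <- a1
      d1 <- stats::rnorm(n, 0, sqrt(cfg$var_d))
      d2 <- d1
    } else {
      g_sh <- stats::rnorm(n, 0, sqrt(cfg$var_a / 2))
      a1 <- g_sh + stats::rnorm(n, 0, sqrt(cfg$var_a / 2))
      a2 <- g_sh + stats::rnorm(n, 0, sqrt(cfg$var_a / 2))
      h_sh <- stats::rnorm(n, 0, sqrt(cfg$var_d / 4))
      d1 <- h_sh + stats::rnorm(n, 0, sqrt(3 * cfg$var_d / 4))
      d2 <- h_sh + stats::rnorm(n, 0, sqrt(3 * cfg$var_d / 4))
    }
    e1 <- stats::rnorm(n, 0, sqrt(cfg$var_e))
    e2 <- stats::rnorm(n, 0, sqrt(cfg$var_e))

    fixed <- cfg$mean + cfg$beta_age * age + cfg$beta_sex * male
    y1 <- fixed + a1 + cshare + d1 + e1
    y2 <- fixed + a2 + cshare + d2 + e2

    pair_id <- sprintf("%s%04d", id_prefix, seq_len(n))
    data.frame(
      pair_id = rep(pair_id, each = 2L),
      individual_id = paste0(rep(pair_id, each = 2L), "_",
                             rep(1:2, times = n)),
      twin_index = rep(1:2, times = n),
      zygosity = zyg,
      age = rep(age, each = 2L),
      sex = rep(ifelse(male == 1L, "M", "F"), each = 2L),
      value = as.vector(rbind(y1, y2)),
      stringsAsFactors = FALSE
    )
  }

  df <- rbind(build_block(cfg$n_mz, "MZ", "MZ"),
              build_block(cfg$n_dz, "DZ", "DZ"))
  names(df)[names(df) == "value"] <- phenotype
  digest <- paste0("simulated(seed=", cfg$seed, ", n_mz=", cfg$n_mz,
                   ", n_dz=", cfg$n_dz, ", var_a=", cfg$var_a,
                   ", var_c=", cfg$var_c, ", var_d=", cfg$var_d,
                   ", var_e=", cfg$var_e, ")")
  twin_cohort(df, phenotypes = phenotype, provenance = digest)
}

#' Add a second, noisier measurement channel for a phenotype
#'
#' Emulates re-measuring the same underlying quantity with a second pipeline:
#' the new column `<phenotype>_m2` equals the original plus independent
#' Gaussian noise per individual. With noise variance sigma^2 against signal
#' variance s^2, the induced cross-method Pearson correlation is
#' `1/sqrt(1 + sigma^2/s^2)` (classical attenuation).
#'
#' @param cohort a [twin_cohort].
#' @param phenotype existing phenotype column.
#' @param method_error_sd standard deviation of the added noise (>= 0).
#' @param seed integer seed for the noise draw.
#' @return the cohort with one extra phenotype column `<phenotype>_m2`.
#' @export
add_second_method <- function(cohort, phenotype, method_error_sd, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!phenotype %in% phenotype_names(cohort)) {
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  }
  if (method_error_sd < 0) stop("method_error_sd must be >= 0", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  df <- as.data.frame(cohort)
  newcol <- paste0(phenotype, "_m2")
  df[[newcol]] <- df[[phenotype]] +
    stats::rnorm(nrow(df), 0, method_error_sd)
  twin_cohort(df,
              phenotypes = unique(c(phenotype_names(cohort), newcol)),
              provenance = attr(cohort, "provenance"))
}
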