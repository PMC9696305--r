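new_model_fit <- function(spec, raw, mean_params, neg2ll, n_mz, n_dz,
                          converged, phenotype, ci = NULL) {
  total <- sum(raw)
  std <- if (total > 0) raw / total else raw * 0
  structure(list(label = spec$label,
                 covariate_handling = spec$covariate_handling,
                 raw = raw,
                 standardized = std,
                 mean_params = mean_params,
                 neg2ll = neg2ll,
                 n_mz = n_mz, n_dz = n_dz,
                 n_params = length(spec$free_paths) + length(mean_params),
                 converged = converged,
                 phenotype = phenotype,
                 ci = ci),
            class = "twin_model_fit")
}

#' @export
print.twin_model_fit <- function(x, ...) {
  cat(sprintf("%s model fit for '%s' (%d MZ / %d DZ pairs)\n", x$label,
              x$phenotype, x$n_mz, x$n_dz))
  comp <- names(x$standardized)[x$raw > 0 | names(x$raw) %in%
                                  strsplit(x$label, "")[[1]]]
  for (k in names(x$standardized)) {
    if (x$standardized[[k]] == 0 && !k %in% comp) next
    line <- sprintf("  %s = %.3f (raw %.4g)", k, x$standardized[[k]],
                    x$raw[[k]])
    if (!is.null(x$ci) && k %in% names(x$ci)) {
      line <- paste0(line, sprintf("  95%% CI [%.3f, %.3f]",
                                   x$ci[[k]][1L], x$ci[[k]][2L]))
    }
    cat(line, "\n")
  }
  cat(sprintf("  -2LL = %.4f, %d parameters, converged: %s\n", x$neg2ll,
              x$n_params, x$converged))
  invisible(x)
}

# Deterministic multi-start values for the free paths, seeded from moment
# estimates (double-entry intra-pair correlations + total variance) and
# +/-50% perturbations of each path in turn.
moment_starts <- function(cohort, phenotype, spec) {
  vals <- c(pair_wide(cohort, phenotype)$y1, pair_wide(cohort, phenotype)$y2)
  V <- stats::var(vals)
  if (!is.finite(V) || V <= 0) V <- 1

  r_mz <- tryCatch(
    intrapair_correlation(cohort, phenotype, "MZ")$r, error = function(e) 0.5)
  r_dz <- tryCatch(
    intrapair_correlation(cohort, phenotype, "DZ")$r, error = function(e) 0.25)
  fr <- falconer_estimates(r_mz, r_dz)$standardized

  clip <- function(x) pmin(pmax(x, 0.02), 0.96)
  frac <- switch(spec$label,
    ACE = c(a = clip(fr[["A"]]), c = clip(fr[["C"]]), e = clip(fr[["E"]])),
    AE  = c(a = clip(fr[["A"]] + fr[["C"]]), e = clip(fr[["E"]])),
    CE  = c(c = clip(fr[["A"]] + fr[["C"]]), e = clip(fr[["E"]])),
    E   = c(e = 1),
    ADE = c(a = clip(0.7 * (fr[["A"]] + fr[["C"]])),
            d = clip(0.3 * (fr[["A"]] + fr[["C"]])),
            e = clip(fr[["E"]]))
  )
  base <- sqrt(frac * V)
  names(base) <- names(frac)

  starts <- list(base)
  for (i in seq_along(base)) {
    up <- base; up[i] <- up[i] * 1.5
    dn <- base; dn[i] <- dn[i] * 0.5
    starts <- c(starts, list(up, dn))
  }
  starts
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Minimizes [neg2_loglik()] over unconstrained path coefficients (variances
#' are their squares, so non-negativity needs no constraints; boundary
#' estimates appear naturally as a path shrinking to 0) and the mean
#' parameters. Optimization is multi-start Nelder-Mead with a BFGS polish:
#' start 1 comes from moment estimates (double-entry correlations via
#' Falconer's formulas), the rest are deterministic +/-50% perturbations of
#' each path. For the pre-residualized means model the likelihood is
#' evaluated from sufficient statistics, making each evaluation O(1) in the
#' number of pairs.
#'
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column.
#' @param spec a [model_spec()], or a label string.
#' @param ci character vector of components for which to compute
#'   profile-likelihood CIs (e.g. `c("A", "E")`), or `TRUE` for all free
#'   components, or `NULL` (default) to skip.
#' @param level confidence level for the profile CIs.
#' @return a `twin_model_fit`: raw and standardized components,
#'   `neg2ll`, convergence flag, parameter count, optional `ci`.
#' @export
fit_model <- function(cohort, phenotype, spec = "ACE", ci = NULL,
                      level = 0.95) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))

  n_mz <- nrow(pair_wide(cohort, phenotype, zygosity = "MZ"))
  n_dz <- nrow(pair_wide(cohort, phenotype, zygosity = "DZ"))
  if (spec$label == "E") {
    if (n_mz + n_dz < 3L) stop("need at least 3 complete pairs",
                               call. = FALSE)
  } else if (n_mz < 3L || n_dz < 3L) {
    stop("need at least 3 complete MZ and 3 complete DZ pairs (have ",
         n_mz, "/", n_dz, ")", call. = FALSE)
  }

  # Optimize on unit-variance data for conditioning; variances, mean
  # parameters and -2LL are mapped back afterwards, which makes the fit
  # scale-equivariant up to floating point.
  pw_all <- pair_wide(cohort, phenotype)
  s0 <- stats::sd(c(pw_all$y1, pw_all$y2))
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  scaled_df <- as.data.frame(cohort)
  scaled_df[[phenotype]] <- scaled_df[[phenotype]] / s0
  scaled <- twin_cohort(scaled_df, phenotypes = phenotype_names(cohort),
                        provenance = attr(cohort, "provenance"))

  obj <- make_objective(scaled, phenotype, spec)
  k <- length(spec$free_paths)

  starts <- moment_starts(scaled, phenotype, spec)
  best <- NULL
  for (s in starts) {
    par0 <- c(s, obj$mean_start)
    res <- stats::optim(par0, obj$fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    polish <- tryCatch(
      stats::optim(res$par, obj$fn, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= res$value) res <- polish
    res$converged <- res$convergence == 0L || !is.null(polish)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("no optimizer start converged for model ", spec$label,
         call. = FALSE)
  }

  paths <- best$par[seq_len(k)] * s0
  names(paths) <- spec$free_paths
  cov <- pair_covariance(paths)
  mean_params <- best$par[-seq_len(k)] * s0
  names(mean_params) <- obj$mean_names
  # density transform back to the original scale: each pair picks up
  # 2 * log(s0^2)
  neg2ll <- best$value + (n_mz + n_dz) * 4 * log(s0)

  fit <- new_model_fit(spec, cov$raw, mean_params, neg2ll, n_mz, n_dz,
                       best$converged, phenotype)
  if (!is.null(ci) && !identical(ci, FALSE)) {
    comps <- if (isTRUE(ci)) toupper(spec$free_paths) else ci
    fit$ci <- lapply(stats::setNames(nm = comps), function(k2) {
      profile_ci(fit, k2, cohort, phenotype, level = level)
    })
  }
  fit
}

# Builds the optimizer objective: a function of c(paths, mean params) plus
# the mean-parameter start values and names. Uses sufficient statistics for
# the pre-residualized case, full O(n) evaluation for the means model.
make_objective <- function(cohort, phenotype, spec) {
  k <- length(spec$free_paths)
  if (spec$covariate_handling == "pre_residualized") {
    st <- suff_stats(cohort, phenotype)
    fn <- function(par) {
      paths <- par[seq_len(k)]
      names(paths) <- spec$free_paths
      cov <- pair_covariance(paths)
      val <- neg2ll_from_stats(st, cov$v, cov$off_mz, cov$off_dz,
                               par[k + 1L])
      if (!is.finite(val)) 1e12 else val
    }
    list(fn = fn, mean_start = c(mu = mean(st$all_values)),
         mean_names = "mu")
  } else {
    pw_mz <- pair_wide(cohort, phenotype, zygosity = "MZ")
    pw_dz <- pair_wide(cohort, phenotype, zygosity = "DZ")
    groups <- Filter(function(g) nrow(g) > 0L, list(MZ = pw_mz, DZ = pw_dz))
    # OLS start for the mean structure
    df <- as.data.frame(cohort)
    ok <- !is.na(df[[phenotype]])
    lmfit <- stats::lm(df[[phenotype]][ok] ~ df$age[ok] +
                         I(as.numeric(df$sex[ok] == "M")))
    cf <- stats::coef(lmfit)
    cf[is.na(cf)] <- 0
    fn <- function(par) {
      paths <- par[seq_len(k)]
      names(paths) <- spec$free_paths
      cov <- pair_covariance(paths)
      mu <- par[k + 1L]; b_age <- par[k + 2L]; b_sex <- par[k + 3L]
      total <- 0
      for (nm in names(groups)) {
        g <- groups[[nm]]
        m <- mu + b_age * g$age + b_sex * as.numeric(g$sex == "M")
        off <- if (nm == "MZ") cov$off_mz else cov$off_dz
        total <- total + neg2ll_group(g$y1 - m, g$y2 - m, cov$v, off)
      }
      if (!is.finite(total)) 1e12 else total
    }
    list(fn = fn,
         mean_start = c(mu = unname(cf[1L]), beta_age = unname(cf[2L]),
                        beta_sex = unname(cf[3L])),
         mean_names = c("mu", "beta_age", "beta_sex"))
  }
}
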