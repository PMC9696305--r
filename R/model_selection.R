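#' Profile-likelihood confidence interval for a standardized component
#'
#' The interval on a standardized component (fraction of total variance) is
#' the set of values at which the profile -2 log-likelihood — re-optimizing
#' every other parameter (total variance, the split of the remaining mass,
#' and the mean structure) — stays within the chi-squared(1) quantile
#' (3.841 at 95%) of its minimum. Bounds are located by bisection to a
#' tolerance of 1e-4 on the fraction scale and clipped to [0, 1]; a bound
#' that runs into the boundary is reported at 0 or 1 and flagged via the
#' `"boundary"` attribute.
#'
#' @param fit a converged `twin_model_fit`.
#' @param component standardized component to profile (`"A"`, `"C"`, `"D"`
#'   or `"E"`), which must be free in the fitted model.
#' @param cohort,phenotype the data the model was fitted to.
#' @param level confidence level.
#' @return numeric `c(low, high)` with attribute `boundary` (two logicals).
#' @export
profile_ci <- function(fit, component, cohort, phenotype, level = 0.95) {
  stopifnot(inherits(fit, "twin_model_fit"))
  free <- toupper(MODEL_FREE_PATHS[[fit$label]])
  component <- toupper(component)
  if (!component %in% free) {
    stop("component ", component, " is not free in the ", fit$label,
         " model", call. = FALSE)
  }
  if (length(free) < 2L) {
    stop("cannot profile the only free component", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  others <- setdiff(free, component)
  spec <- model_spec(fit$label, fit$covariate_handling)

  eval_n2ll <- make_variance_evaluator(cohort, phenotype, spec)

  total_raw <- sum(fit$raw)
  lv0 <- log(max(total_raw, 1e-12))
  mean0 <- fit$mean_params
  if (length(others) == 2L) {
    o1 <- fit$raw[[others[1L]]]
    o2 <- fit$raw[[others[2L]]]
    t0 <- (o1 + 1e-9) / (o1 + o2 + 2e-9)
    u0 <- stats::qlogis(pmin(pmax(t0, 1e-6), 1 - 1e-6))
  }

  prof <- function(s) {
    build_vars <- function(lv, u) {
      V <- exp(lv)
      vars <- c(A = 0, C = 0, D = 0, E = 0)
      vars[component] <- s * V
      if (length(others) == 1L) {
        vars[others] <- (1 - s) * V
      } else {
        t <- stats::plogis(u)
        vars[others[1L]] <- t * (1 - s) * V
        vars[others[2L]] <- (1 - t) * (1 - s) * V
      }
      vars
    }
    fn <- function(par) {
      lv <- par[1L]
      u <- if (length(others) == 2L) par[2L] else NA_real_
      meanpar <- par[(length(par) - length(mean0) + 1L):length(par)]
      val <- eval_n2ll(build_vars(lv, u), meanpar)
      if (!is.finite(val)) 1e12 else val
    }
    par0 <- c(lv0, if (length(others) == 2L) u0, mean0)
    res <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-11))
    res$value
  }

  thresh <- stats::qchisq(level, df = 1)
  s_hat <- min(max(fit$standardized[[component]], 0), 1)
  m0 <- min(fit$neg2ll, prof(s_hat))
  f <- function(s) prof(s) - m0 - thresh

  bisect <- function(lo, hi, f_lo_positive) {
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      pos <- f(mid) > 0
      if (pos == f_lo_positive) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  boundary <- c(FALSE, FALSE)
  if (s_hat <= 1e-6) {
    low <- 0
    boundary[1L] <- TRUE
  } else if (f(0) <= 0) {
    low <- 0
    boundary[1L] <- TRUE
  } else {
    low <- bisect(0, s_hat, f_lo_positive = TRUE)
  }
  if (s_hat >= 1 - 1e-6) {
    high <- 1
    boundary[2L] <- TRUE
  } else if (f(1) <= 0) {
    high <- 1
    boundary[2L] <- TRUE
  } else {
    high <- bisect(s_hat, 1, f_lo_positive = FALSE)
  }

  out <- c(low = max(0, low), high = min(1, high))
  attr(out, "boundary") <- boundary
  attr(out, "level") <- level
  out
}

# Evaluator closure: (named variance vector A/C/D/E, mean params) -> -2LL.
make_variance_evaluator <- function(cohort, phenotype, spec) {
  if (spec$covariate_handling == "pre_residualized") {
    st <- suff_stats(cohort, phenotype)
    function(vars, meanpar) {
      v <- sum(vars)
      neg2ll_from_stats(st, v, vars[["A"]] + vars[["C"]] + vars[["D"]],
                        vars[["A"]] / 2 + vars[["D"]] / 4 + vars[["C"]],
                        meanpar[[1L]])
    }
  } else {
    pw_mz <- pair_wide(cohort, phenotype, zygosity = "MZ")
    pw_dz <- pair_wide(cohort, phenotype, zygosity = "DZ")
    function(vars, meanpar) {
      v <- sum(vars)
      off_mz <- vars[["A"]] + vars[["C"]] + vars[["D"]]
      off_dz <- vars[["A"]] / 2 + vars[["D"]] / 4 + vars[["C"]]
      total <- 0
      for (g in list(MZ = pw_mz, DZ = pw_dz)) {
        if (nrow(g) == 0L) next
        m <- meanpar[[1L]] + meanpar[[2L]] * g$age +
          meanpar[[3L]] * as.numeric(g$sex == "M")
        off <- if (g$zygosity[1L] == "MZ") off_mz else off_dz
        total <- total + neg2ll_group(g$y1 - m, g$y2 - m, v, off)
      }
      total
    }
  }
}

#' Likelihood-ratio test between nested twin models
#'
#' Compares a full model with a nested reduction fitted to the same cohort
#' and phenotype: statistic `max(0, reduced$neg2ll - full$neg2ll)`, degrees
#' of freedom the difference in free parameter counts, p-value from the
#' chi-squared upper tail. Testing a variance component against its boundary
#' at 0 actually has a 50:50 mixture null; `boundary_mixture = TRUE` halves
#' the plain chi-squared p accordingly, while the default keeps the plain
#' chi-squared convention.
#'
#' @param full,reduced `twin_model_fit` objects; `reduced`'s free components
#'   must be a subset of `full`'s.
#' @param boundary_mixture use the 50:50 chi-squared mixture p-value.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced, boundary_mixture = FALSE) {
  stopifnot(inherits(full, "twin_model_fit"),
            inherits(reduced, "twin_model_fit"))
  if (!all(MODEL_FREE_PATHS[[reduced$label]] %in%
           MODEL_FREE_PATHS[[full$label]])) {
    stop(reduced$label, " is not nested in ", full$label, call. = FALSE)
  }
  if (full$covariate_handling != reduced$covariate_handling ||
      full$phenotype != reduced$phenotype ||
      full$n_mz != reduced$n_mz || full$n_dz != reduced$n_dz) {
    stop("models were not fitted to the same data", call. = FALSE)
  }
  stat <- max(0, reduced$neg2ll - full$neg2ll)
  df <- full$n_params - reduced$n_params
  p <- if (df == 0L) {
    1
  } else if (boundary_mixture && df == 1L) {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
      0.5 * as.numeric(stat <= 0)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

#' Fit ACE and apply the model-reduction procedure
#'
#' Fits the full ACE model; when the standardized C (respectively A)
#' estimate is negligible — below `negligible_threshold` — the nested AE
#' (respectively CE) reduction is fitted and accepted if the likelihood-
#' ratio test against ACE has p > 0.05 (no demonstrable worsening of fit,
#' justifying the more parsimonious model). If both reductions qualify, the
#' accepted reduction with the lower -2 log-likelihood wins (tie: AE).
#' Otherwise ACE is retained. Every fit and test is recorded in the audit
#' trail.
#'
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column.
#' @param negligible_threshold standardized-component size below which a
#'   reduction is attempted (default 0.05).
#' @param covariate_handling passed to [model_spec()].
#' @param ci compute profile CIs on the selected model's free components.
#' @return list of class `model_selection`: `selected` (`twin_model_fit`),
#'   `fits` (all fitted models), `audit` (data.frame of fits and tests).
#' @export
select_model <- function(cohort, phenotype, negligible_threshold = 0.05,
                         covariate_handling = "pre_residualized",
                         ci = FALSE) {
  ace <- fit_model(cohort, phenotype,
                   model_spec("ACE", covariate_handling))
  audit <- data.frame(model = "ACE", neg2ll = ace$neg2ll,
                      lrt_p = NA_real_, accepted = NA,
                      note = "base model", stringsAsFactors = FALSE)
  fits <- list(ACE = ace)
  candidates <- list()

  if (ace$standardized[["C"]] < negligible_threshold) {
    ae <- fit_model(cohort, phenotype, model_spec("AE", covariate_handling))
    test <- lrt(ace, ae)
    ok <- test$p_value > 0.05
    fits$AE <- ae
    audit <- rbind(audit, data.frame(
      model = "AE", neg2ll = ae$neg2ll, lrt_p = test$p_value, accepted = ok,
      note = sprintf("C = %.3f negligible; LRT vs ACE",
                     ace$standardized[["C"]]), stringsAsFactors = FALSE))
    if (ok) candidates$AE <- ae
  }
  if (ace$standardized[["A"]] < negligible_threshold) {
    ce <- fit_model(cohort, phenotype, model_spec("CE", covariate_handling))
    test <- lrt(ace, ce)
    ok <- test$p_value > 0.05
    fits$CE <- ce
    audit <- rbind(audit, data.frame(
      model = "CE", neg2ll = ce$neg2ll, lrt_p = test$p_value, accepted = ok,
      note = sprintf("A = %.3f negligible; LRT vs ACE",
                     ace$standardized[["A"]]), stringsAsFactors = FALSE))
    if (ok) candidates$CE <- ce
  }

  selected <- if (length(candidates) == 0L) {
    ace
  } else if (length(candidates) == 1L) {
    candidates[[1L]]
  } else if (candidates$AE$neg2ll <= candidates$CE$neg2ll) {
    candidates$AE
  } else {
    candidates$CE
  }

  if (isTRUE(ci)) {
    comps <- toupper(MODEL_FREE_PATHS[[selected$label]])
    selected$ci <- lapply(stats::setNames(nm = comps), function(k) {
      profile_ci(selected, k, cohort, phenotype)
    })
  }

  structure(list(selected = selected, fits = fits, audit = audit),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection audit:\n")
  print(x$audit, row.names = FALSE)
  cat("\nSelected:\n")
  print(x$selected)
  invisible(x)
}

#' Falconer-style moment estimates of the standardized components
#'
#' Quick heuristic estimates from the two intra-pair correlations:
#' `h2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`; each is clipped
#' to [0, 1] and the triple renormalized to sum to one. These are
#' method-of-moments quantities, useful as optimizer starts and sanity
#' checks, not substitutes for the likelihood fit.
#'
#' @param r_mz,r_dz intra-pair correlations in [-1, 1].
#' @return list with `standardized` (named `A`, `C`, `E`) and
#'   `heuristic = TRUE`.
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  h2 <- min(max(2 * (r_mz - r_dz), 0), 1)
  c2 <- min(max(2 * r_dz - r_mz, 0), 1)
  e2 <- min(max(1 - r_mz, 0), 1)
  total <- h2 + c2 + e2
  std <- if (total > 0) c(A = h2, C = c2, E = e2) / total
         else c(A = 0, C = 0, E = 1)
  list(standardized = std, heuristic = TRUE)
}
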