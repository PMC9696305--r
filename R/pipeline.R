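#' Configuration for an end-to-end analysis run
#'
#' @param input a [sim_config()] (cohort is simulated) or a CSV path
#'   (cohort is read).
#' @param phenotypes phenotype columns to analyze; `NULL` = all primary
#'   phenotypes (second-channel `_m2` columns are paired automatically).
#' @param covariates covariates to residualize out before the correlation
#'   and likelihood stages.
#' @param correlation_mode `"double_entry"` or `"single_entry"`.
#' @param model `"auto"` (ACE with AE/CE reduction) or a fixed label.
#' @param negligible_threshold reduction trigger for `"auto"`.
#' @param ci_level confidence level.
#' @param seed root seed; governs simulation only (inference is
#'   deterministic by construction).
#' @param output_dir where intermediate CSVs and the JSON report go; `NULL`
#'   for no files.
#' @return a `run_config` list.
#' @export
run_config <- function(input, phenotypes = NULL,
                       covariates = c("age", "sex"),
                       correlation_mode = "double_entry",
                       model = "auto", negligible_threshold = 0.05,
                       ci_level = 0.95, seed = 1L, output_dir = NULL) {
  stopifnot(ci_level > 0, ci_level < 1)
  structure(list(input = input, phenotypes = phenotypes,
                 covariates = covariates,
                 correlation_mode = correlation_mode, model = model,
                 negligible_threshold = negligible_threshold,
                 ci_level = ci_level, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full twin analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate or read), descriptive
#' MZ-vs-DZ comparison, age/sex residualization, intra-pair correlations,
#' variance-component model fitting (with reduction when `model = "auto"`),
#' and cross-method agreement for every phenotype with a `_m2` companion
#' column. Identical config and seed give identical reports.
#'
#' @param cfg a [run_config()].
#' @return an `analysis_report` list: `cohort` summary, `descriptives`,
#'   per-phenotype blocks (`correlations`, `model`, `agreement`), `seed`.
#'   Files are written when `cfg$output_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))

  cohort <- if (inherits(cfg$input, "sim_config")) {
    sim <- cfg$input
    sim$seed <- cfg$seed
    cohort <- generate_cohort(sim)
    if (sim$method_error_sd > 0) {
      cohort <- add_second_method(cohort, phenotype_names(cohort)[1L],
                                  sim$method_error_sd,
                                  seed = cfg$seed + 1L)
    }
    cohort
  } else {
    read_cohort(cfg$input)
  }

  all_phen <- phenotype_names(cohort)
  primary <- if (is.null(cfg$phenotypes)) {
    all_phen[!grepl("_m2$", all_phen)]
  } else {
    cfg$phenotypes
  }
  unknown <- setdiff(primary, all_phen)
  if (length(unknown) > 0L) {
    stop("[validate] unknown phenotype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  descriptives <- describe_cohort(cohort, continuous = c("age", primary))

  blocks <- list()
  for (p in primary) {
    adjusted <- residualize(cohort, p, covariates = cfg$covariates)
    r_mz <- intrapair_correlation(adjusted, p, "MZ",
                                  mode = cfg$correlation_mode,
                                  level = cfg$ci_level)
    r_dz <- intrapair_correlation(adjusted, p, "DZ",
                                  mode = cfg$correlation_mode,
                                  level = cfg$ci_level)
    if (cfg$model == "auto") {
      sel <- select_model(adjusted, p,
                          negligible_threshold = cfg$negligible_threshold,
                          ci = TRUE)
      fit <- sel$selected
      audit <- sel$audit
    } else {
      fit <- fit_model(adjusted, p, cfg$model, ci = TRUE,
                       level = cfg$ci_level)
      audit <- NULL
    }
    m2 <- paste0(p, "_m2")
    agreement <- if (m2 %in% all_phen) {
      method_agreement(cohort, p, m2, level = cfg$ci_level)
    } else {
      NULL
    }
    blocks[[p]] <- list(correlations = list(mz = r_mz, dz = r_dz),
                        model = fit, audit = audit, agreement = agreement)
  }

  report <- structure(
    list(cohort = list(n_mz = n_pairs(cohort, "MZ"),
                       n_dz = n_pairs(cohort, "DZ"),
                       provenance = attr(cohort, "provenance")),
         descriptives = descriptives,
         phenotypes = blocks,
         seed = cfg$seed,
         version = as.character(utils::packageVersion("twinace"))),
    class = "analysis_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(cfg$output_dir, "cohort.csv"))
    utils::write.csv(descriptives,
                     file.path(cfg$output_dir, "descriptives.csv"),
                     row.names = FALSE)
    render_tables(report, cfg$output_dir)
    jsonlite::write_json(report_to_list(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}

# Plain-list view of the report with numbers rounded to a fixed precision so
# identical runs serialize byte-identically.
report_to_list <- function(report) {
  num <- function(x) signif(x, 10)
  blocks <- lapply(report$phenotypes, function(b) {
    fit <- b$model
    out <- list(
      r_mz = list(r = num(b$correlations$mz$r), n = b$correlations$mz$n,
                  ci = num(c(b$correlations$mz$ci_low,
                             b$correlations$mz$ci_high))),
      r_dz = list(r = num(b$correlations$dz$r), n = b$correlations$dz$n,
                  ci = num(c(b$correlations$dz$ci_low,
                             b$correlations$dz$ci_high))),
      model = list(label = fit$label,
                   standardized = as.list(num(fit$standardized)),
                   raw = as.list(num(fit$raw)),
                   neg2ll = num(fit$neg2ll),
                   ci = lapply(fit$ci, function(ci) num(unname(ci)))))
    if (!is.null(b$audit)) {
      out$reduction <- lapply(seq_len(nrow(b$audit)), function(i) {
        list(model = b$audit$model[i], neg2ll = num(b$audit$neg2ll[i]),
             lrt_p = if (is.na(b$audit$lrt_p[i])) NULL
                     else num(b$audit$lrt_p[i]))
      })
    }
    if (!is.null(b$agreement)) {
      out$agreement <- list(r = num(b$agreement$r), n = b$agreement$n,
                            p = num(b$agreement$p_value))
    }
    out
  })
  list(cohort = report$cohort,
       descriptives = lapply(seq_len(nrow(report$descriptives)), function(i)
         list(variable = report$descriptives$variable[i],
              test = report$descriptives$test[i],
              statistic = num(report$descriptives$statistic[i]),
              p_value = num(report$descriptives$p_value[i]))),
       phenotypes = blocks,
       seed = report$seed,
       version = report$version)
}

#' Render an analysis report to CSV tables
#'
#' Writes `correlations.csv` (phenotype, rMZ and rDZ with CIs),
#' `variance_components.csv` (phenotype, model label, standardized A/C/E
#' with CIs, reduction-test p) and, when any phenotype has a second
#' measurement channel, `method_agreement.csv` (phenotype, r, p).
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  cor_rows <- lapply(names(report$phenotypes), function(p) {
    b <- report$phenotypes[[p]]
    data.frame(phenotype = p,
               r_mz = b$correlations$mz$r,
               r_mz_low = b$correlations$mz$ci_low,
               r_mz_high = b$correlations$mz$ci_high,
               n_mz = b$correlations$mz$n,
               r_dz = b$correlations$dz$r,
               r_dz_low = b$correlations$dz$ci_low,
               r_dz_high = b$correlations$dz$ci_high,
               n_dz = b$correlations$dz$n,
               stringsAsFactors = FALSE)
  })
  f <- file.path(dir, "correlations.csv")
  utils::write.csv(do.call(rbind, cor_rows), f, row.names = FALSE)
  paths <- c(paths, f)

  vc_rows <- lapply(names(report$phenotypes), function(p) {
    b <- report$phenotypes[[p]]
    fit <- b$model
    ci_of <- function(k) {
      if (!is.null(fit$ci) && k %in% names(fit$ci)) fit$ci[[k]]
      else c(NA_real_, NA_real_)
    }
    red_p <- if (!is.null(b$audit)) {
      acc <- b$audit[!is.na(b$audit$accepted) & b$audit$accepted &
                       b$audit$model == fit$label, , drop = FALSE]
      if (nrow(acc) > 0L) acc$lrt_p[1L] else NA_real_
    } else {
      NA_real_
    }
    data.frame(phenotype = p, model = fit$label,
               A = fit$standardized[["A"]],
               A_low = ci_of("A")[1L], A_high = ci_of("A")[2L],
               C = fit$standardized[["C"]],
               C_low = ci_of("C")[1L], C_high = ci_of("C")[2L],
               E = fit$standardized[["E"]],
               E_low = ci_of("E")[1L], E_high = ci_of("E")[2L],
               reduction_p = red_p,
               stringsAsFactors = FALSE)
  })
  f <- file.path(dir, "variance_components.csv")
  utils::write.csv(do.call(rbind, vc_rows), f, row.names = FALSE)
  paths <- c(paths, f)

  ag <- Filter(Negate(is.null),
               lapply(names(report$phenotypes), function(p) {
                 b <- report$phenotypes[[p]]
                 if (is.null(b$agreement)) return(NULL)
                 data.frame(phenotype = p, r = b$agreement$r,
                            n = b$agreement$n, p_value = b$agreement$p_value,
                            stringsAsFactors = FALSE)
               }))
  if (length(ag) > 0L) {
    f <- file.path(dir, "method_agreement.csv")
    utils::write.csv(do.call(rbind, ag), f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
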