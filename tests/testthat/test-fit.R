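test_that("null-variance recovery: pure-E data fits to E ~ 1", {
  co <- generate_cohort(sim_config(n_mz = 1500, n_dz = 1500, var_a = 0,
                                   var_c = 0, var_e = 1, beta_age = 0,
                                   beta_sex = 0, seed = 60))
  fit <- fit_model(co, "volume", "ACE")
  expect_true(fit$converged)
  expect_lt(fit$standardized[["A"]], 0.05)
  expect_lt(fit$standardized[["C"]], 0.05)
  expect_gt(fit$standardized[["E"]], 0.9)
})

test_that("standardized components sum to one and match raw ratios", {
  co <- generate_cohort(sim_config(n_mz = 300, n_dz = 300, var_a = 2,
                                   var_c = 1, var_e = 1, seed = 61))
  for (label in c("ACE", "AE", "CE", "ADE")) {
    fit <- fit_model(co, "volume", label)
    expect_equal(sum(fit$standardized), 1, tolerance = 1e-8)
    expect_equal(unname(fit$standardized),
                 unname(fit$raw / sum(fit$raw)), tolerance = 1e-10)
  }
})

test_that("large-n ML estimates agree with the moment estimator", {
  co <- generate_cohort(sim_config(n_mz = 4000, n_dz = 4000, var_a = 2,
                                   var_c = 0.8, var_e = 1.2, beta_age = 0,
                                   beta_sex = 0, seed = 62))
  r_mz <- intrapair_correlation(co, "volume", "MZ")$r
  r_dz <- intrapair_correlation(co, "volume", "DZ")$r
  moments <- falconer_estimates(r_mz, r_dz)$standardized
  fit <- fit_model(co, "volume", "ACE")
  expect_lt(abs(fit$standardized[["A"]] - moments[["A"]]), 0.02)
  expect_lt(abs(fit$standardized[["C"]] - moments[["C"]]), 0.02)
  expect_lt(abs(fit$standardized[["E"]] - moments[["E"]]), 0.02)
})

test_that("means model recovers covariate effects inside the likelihood", {
  cfg <- sim_config(n_mz = 1500, n_dz = 1000, var_a = 2, var_c = 0,
                    var_e = 1, beta_age = -0.05, beta_sex = 1.0, seed = 63)
  co <- generate_cohort(cfg)
  fit <- fit_model(co, "volume", model_spec("AE", "means_model"))
  expect_true(fit$converged)
  expect_lt(abs(fit$mean_params[["beta_age"]] - (-0.05)), 0.01)
  expect_lt(abs(fit$mean_params[["beta_sex"]] - 1.0), 0.25)
  expect_lt(abs(fit$standardized[["A"]] - 2 / 3), 0.05)
  # residualization route gives a consistent heritability estimate
  fit2 <- fit_model(residualize(co, "volume"), "volume", "AE")
  expect_lt(abs(fit$standardized[["A"]] - fit2$standardized[["A"]]), 0.02)
})

test_that("fit preconditions and reported -2LL are honoured", {
  co_small <- generate_cohort(sim_config(n_mz = 2, n_dz = 2, seed = 64))
  expect_error(fit_model(co_small, "volume", "ACE"), "at least 3")

  co <- generate_cohort(sim_config(n_mz = 50, n_dz = 40, var_a = 1,
                                   var_e = 1, seed = 65))
  fit <- fit_model(co, "volume", "ACE")
  params <- c(a = sqrt(fit$raw[["A"]]), c = sqrt(fit$raw[["C"]]),
              e = sqrt(fit$raw[["E"]]), mu = fit$mean_params[["mu"]])
  expect_equal(neg2_loglik(params, co, "volume", model_spec("ACE")),
               fit$neg2ll, tolerance = 1e-6)
})

test_that("nesting monotonicity of -2LL holds on random cohorts", {
  for (seed in c(70, 71, 72)) {
    co <- generate_cohort(sim_config(
      n_mz = 60, n_dz = 50, var_a = runif(1, 0, 2), var_c = runif(1, 0, 2),
      var_e = runif(1, 0.5, 2), seed = seed))
    ace <- fit_model(co, "volume", "ACE")$neg2ll
    ae <- fit_model(co, "volume", "AE")$neg2ll
    ce <- fit_model(co, "volume", "CE")$neg2ll
    e <- fit_model(co, "volume", "E")$neg2ll
    tol <- 1e-4
    expect_lte(ace, ae + tol)
    expect_lte(ace, ce + tol)
    expect_lte(ae, e + tol)
    expect_lte(ce, e + tol)
  }
})

test_that("scale equivariance: raw variances scale by k^2, fractions unchanged", {
  co <- generate_cohort(sim_config(n_mz = 100, n_dz = 80, var_a = 1.5,
                                   var_c = 0.5, var_e = 1, seed = 73))
  k <- 7.3
  df <- as.data.frame(co)
  df$volume <- df$volume * k
  co_k <- twin_cohort(df, "volume")
  f1 <- fit_model(co, "volume", "ACE")
  f2 <- fit_model(co_k, "volume", "ACE")
  expect_equal(f2$standardized, f1$standardized, tolerance = 1e-6)
  big <- f1$raw > 1e-8
  expect_equal(unname(f2$raw[big] / f1$raw[big]),
               rep(k^2, sum(big)), tolerance = 1e-6)
})

test_that("optimizer attains the grid-search oracle on small cohorts", {
  for (seed in c(80, 81)) {
    co <- generate_cohort(sim_config(n_mz = 16, n_dz = 14, var_a = 1.5,
                                     var_c = 0.5, var_e = 1, beta_age = 0,
                                     beta_sex = 0, seed = seed))
    fit <- fit_model(co, "volume", "ACE")
    oracle <- grid_oracle_neg2ll(co, "volume", step = 0.02)
    expect_lte(fit$neg2ll, oracle + 1e-3)
  }
})

test_that("ADE is supported and ACDE-style requests are rejected", {
  co <- generate_cohort(sim_config(n_mz = 400, n_dz = 400, var_a = 1.5,
                                   var_d = 0.8, var_e = 1, beta_age = 0,
                                   beta_sex = 0, seed = 82))
  fit <- fit_model(co, "volume", "ADE")
  expect_true(fit$converged)
  expect_equal(sum(fit$standardized), 1, tolerance = 1e-8)
  expect_gt(fit$standardized[["A"]] + fit$standardized[["D"]], 0.5)
  expect_error(model_spec("ACDE"))
})
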