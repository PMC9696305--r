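test_that("LRT basics: self-comparison, chi-squared quantile, nesting guard", {
  co <- generate_cohort(sim_config(n_mz = 80, n_dz = 60, var_a = 1,
                                   var_e = 1, seed = 90))
  ace <- fit_model(co, "volume", "ACE")
  ae <- fit_model(co, "volume", "AE")
  ce <- fit_model(co, "volume", "CE")

  self <- lrt(ace, ace)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  test <- lrt(ace, ae)
  expect_gte(test$statistic, 0)
  expect_equal(test$df, 1L)
  expect_error(lrt(ae, ce), "not nested")

  # chi-squared(1) calibration of the p-value at the 95% quantile
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  fake_full <- ace; fake_red <- ae
  fake_red$neg2ll <- ace$neg2ll + 3.841
  expect_equal(lrt(fake_full, fake_red)$p_value, 0.05, tolerance = 1e-3)

  # boundary-mixture option halves the plain p
  plain <- lrt(ace, ae)$p_value
  mixed <- lrt(ace, ae, boundary_mixture = TRUE)$p_value
  expect_equal(mixed, plain / 2, tolerance = 1e-12)
})

test_that("reduction selects AE when C is absent and recovers heritability", {
  co <- generate_cohort(sim_config(n_mz = 1500, n_dz = 1500, var_a = 2.76,
                                   var_c = 0, var_e = 1.24, beta_age = 0,
                                   beta_sex = 0, seed = 91))
  sel <- select_model(co, "volume")
  expect_equal(sel$selected$label, "AE")
  expect_lt(abs(sel$selected$standardized[["A"]] - 0.69), 0.04)
  expect_true(any(sel$audit$model == "AE" & sel$audit$accepted))
})

test_that("reduction selects CE when A is absent", {
  co <- generate_cohort(sim_config(n_mz = 1500, n_dz = 1500, var_a = 0,
                                   var_c = 2.19, var_e = 0.81, beta_age = 0,
                                   beta_sex = 0, seed = 92))
  sel <- select_model(co, "volume")
  expect_equal(sel$selected$label, "CE")
  expect_lt(abs(sel$selected$standardized[["C"]] - 0.73), 0.04)
})

test_that("ACE is retained when both A and C are substantial", {
  co <- generate_cohort(sim_config(n_mz = 2000, n_dz = 2000, var_a = 1.76,
                                   var_c = 1.80, var_e = 0.44, beta_age = 0,
                                   beta_sex = 0, seed = 93))
  sel <- select_model(co, "volume")
  expect_equal(sel$selected$label, "ACE")
  expect_lt(abs(sel$selected$standardized[["A"]] - 0.44), 0.06)
  expect_lt(abs(sel$selected$standardized[["C"]] - 0.45), 0.06)
})

test_that("LRT of the C = 0 boundary is conservatively calibrated under the null", {
  # under var_c = 0 the plain chi-squared p rejects at ~alpha/2 because the
  # null distribution is the 50:50 mixture; check the rejection rate is well
  # below alpha and nonzero-ish over replicates
  n_rep <- 150
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(sim_config(n_mz = 150, n_dz = 150, var_a = 1,
                                     var_c = 0, var_e = 1, beta_age = 0,
                                     beta_sex = 0, seed = 1000 + i))
    ace <- fit_model(co, "volume", "ACE")
    ae <- fit_model(co, "volume", "AE")
    if (lrt(ace, ae)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # mixture-adjusted level is 0.025; allow generous binomial noise
  expect_lt(rate, 0.07)
})

test_that("Falconer moment estimates match direct arithmetic", {
  f <- falconer_estimates(1, 0.5)
  expect_equal(unname(f$standardized), c(1, 0, 0))
  f2 <- falconer_estimates(0.92, 0.50)
  expect_equal(unname(f2$standardized), c(0.84, 0.08, 0.08),
               tolerance = 1e-12)
  f3 <- falconer_estimates(0.4, 0.4)
  expect_equal(f3$standardized[["A"]], 0)
  expect_equal(sum(f3$standardized), 1, tolerance = 1e-12)
  expect_true(f3$heuristic)
})

test_that("profile CI brackets the estimate and matches a brute-force scan", {
  co <- generate_cohort(sim_config(n_mz = 16, n_dz = 14, var_a = 2,
                                   var_c = 0, var_e = 1, beta_age = 0,
                                   beta_sex = 0, seed = 94))
  fit <- fit_model(co, "volume", "AE")
  ci <- profile_ci(fit, "A", co, "volume")
  a_hat <- fit$standardized[["A"]]
  expect_lte(ci[["low"]], a_hat)
  expect_gte(ci[["high"]], a_hat)

  # brute-force profile scan: for each s on a fine grid, minimize over the
  # total variance and mean with an independent likelihood implementation
  pw_mz <- pair_wide(co, "volume", zygosity = "MZ")
  pw_dz <- pair_wide(co, "volume", zygosity = "DZ")
  prof_brute <- function(s) {
    obj <- function(par) {
      V <- exp(par[1L])
      val <- brute_neg2ll(pw_mz, pw_dz, s * V, 0, (1 - s) * V, par[2L])
      if (!is.finite(val)) 1e12 else val
    }
    optim(c(log(sum(fit$raw)), fit$mean_params[["mu"]]), obj,
          method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10))$value
  }
  grid <- seq(0.001, 0.999, by = 0.001)
  vals <- vapply(grid, prof_brute, numeric(1))
  ok <- vals <= min(min(vals), fit$neg2ll) + qchisq(0.95, 1)
  expect_lt(abs(ci[["low"]] - grid[which(ok)[1L]]), 0.005)
  expect_lt(abs(ci[["high"]] - grid[rev(which(ok))[1L]]), 0.005)
})

test_that("profile CI narrows as the cohort grows", {
  width <- sapply(c(250, 2500), function(n) {
    co <- generate_cohort(sim_config(n_mz = n, n_dz = n, var_a = 3,
                                     var_c = 0, var_e = 1, beta_age = 0,
                                     beta_sex = 0, seed = 95))
    fit <- fit_model(co, "volume", "AE")
    ci <- profile_ci(fit, "A", co, "volume")
    ci[["high"]] - ci[["low"]]
  })
  expect_lt(width[2L], width[1L])
})
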