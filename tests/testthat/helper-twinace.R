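# Fixture builders and independent oracles shared across test files.

# Minimal hand-built cohort: values is a list of c(y1, y2) per pair.
make_cohort <- function(values, zygosity = rep("MZ", length(values)),
                        age = rep(50, length(values)),
                        sex = rep("F", length(values)),
                        phenotype = "vol") {
  n <- length(values)
  df <- data.frame(
    pair_id = rep(sprintf("p%03d", seq_len(n)), each = 2L),
    individual_id = paste0(rep(sprintf("p%03d", seq_len(n)), each = 2L),
                           "_", rep(1:2, n)),
    twin_index = rep(1:2, n),
    zygosity = rep(zygosity, each = 2L),
    age = rep(age, each = 2L),
    sex = rep(sex, each = 2L),
    stringsAsFactors = FALSE)
  df[[phenotype]] <- unlist(values)
  twin_cohort(df, phenotype)
}

# Brute-force -2 log-likelihood: per-pair 2x2 multivariate normal density
# via solve()/determinant(), no shared code with the package's evaluator.
brute_neg2ll <- function(pw_mz, pw_dz, var_a, var_c, var_e, mu,
                         var_d = 0) {
  v <- var_a + var_c + var_d + var_e
  total <- 0
  for (grp in list(list(pw = pw_mz, off = var_a + var_d + var_c),
                   list(pw = pw_dz, off = var_a / 2 + var_d / 4 + var_c))) {
    pw <- grp$pw
    if (is.null(pw) || nrow(pw) == 0L) next
    S <- matrix(c(v, grp$off, grp$off, v), 2L)
    if (det(S) <= 0) return(Inf)
    Sinv <- solve(S)
    logdet <- determinant(S, logarithm = TRUE)$modulus[1L]
    for (i in seq_len(nrow(pw))) {
      r <- c(pw$y1[i] - mu, pw$y2[i] - mu)
      total <- total + 2 * log(2 * pi) + logdet +
        drop(t(r) %*% Sinv %*% r)
    }
  }
  total
}

# Grid-search oracle for the ACE fit on small cohorts: standardized (A, C)
# on a simplex grid; at each grid point mu is the grand mean and the total
# variance has the closed-form conditional MLE V = Q / (2 n), with Q the
# summed Mahalanobis form under the correlation-only structure.
grid_oracle_neg2ll <- function(cohort, phenotype, step = 0.02) {
  pw_mz <- pair_wide(cohort, phenotype, zygosity = "MZ")
  pw_dz <- pair_wide(cohort, phenotype, zygosity = "DZ")
  mu <- mean(c(pw_mz$y1, pw_mz$y2, pw_dz$y1, pw_dz$y2))
  n <- nrow(pw_mz) + nrow(pw_dz)
  best <- Inf
  for (a2 in seq(0, 1, by = step)) {
    for (c2 in seq(0, 1 - a2, by = step)) {
      e2 <- 1 - a2 - c2
      if (e2 < 1e-9) next
      Q <- 0; logdets <- 0
      for (grp in list(list(pw = pw_mz, off = a2 + c2),
                       list(pw = pw_dz, off = a2 / 2 + c2))) {
        pw <- grp$pw
        if (nrow(pw) == 0L) next
        R <- matrix(c(1, grp$off, grp$off, 1), 2L)
        Rinv <- solve(R)
        for (i in seq_len(nrow(pw))) {
          r <- c(pw$y1[i] - mu, pw$y2[i] - mu)
          Q <- Q + drop(t(r) %*% Rinv %*% r)
        }
        logdets <- logdets + nrow(pw) *
          determinant(R, logarithm = TRUE)$modulus[1L]
      }
      V <- Q / (2 * n)
      val <- n * (2 * log(2 * pi) + 2 * log(V)) + logdets + Q / V
      if (val < best) best <- val
    }
  }
  best
}

# Independent Mann-Whitney oracle: bitmask enumeration of group labelings
# and U computed by direct pairwise comparison counts (win + half-tie),
# a distinct code path from the package's rank-subset enumeration.
mwu_oracle_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  pooled <- c(a, b)
  u_direct <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- min(u_direct(a, b), u_direct(b, a))
  nanb <- n_a * (n - n_a)
  ua_all <- c()
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(sel) != n_a) next
    ua_all <- c(ua_all, u_direct(pooled[sel], pooled[!sel]))
  }
  eps <- 1e-9
  min(1, (sum(ua_all <= u_obs + eps) + sum(ua_all >= nanb - u_obs - eps)) /
        length(ua_all))
}
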