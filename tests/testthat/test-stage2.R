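# Huber loss at scale s (the IWLS objective)
huber_loss <- function(r, s, k = 1.345) {
  u <- abs(r) / s
  sum(ifelse(u <= k, 0.5 * u^2, k * u - 0.5 * k^2)) * s^2
}

test_that("block QC counts genotype-by-sex cells and names the failing block", {
  mk <- function(counts_m, counts_f) {
    list(d = c(rep(0:2, counts_m), rep(0:2, counts_f)),
         s = c(rep(0L, sum(counts_m)), rep(1L, sum(counts_f))))
  }
  # M (5,5,5), F (5,5,4): fails on the female hom-alt block
  x <- mk(c(5, 5, 5), c(5, 5, 4))
  qc <- qc_block_filter(x$d, x$s)
  expect_false(qc$pass)
  expect_match(qc$reasons, "female genotype 2 count 4 < 5", all = FALSE)
  # M (10,10,10), F (5,5,5): passes
  x2 <- mk(c(10, 10, 10), c(5, 5, 5))
  expect_true(qc_block_filter(x2$d, x2$s)$pass)
  # genotype 1 absent in males on an autosome
  x3 <- list(d = c(rep(c(0, 2), c(8, 8)), rep(0:2, c(6, 6, 6))),
             s = rep(0:1, c(16, 18)))
  qc3 <- qc_block_filter(x3$d, x3$s)
  expect_false(qc3$pass)
  expect_match(qc3$reasons, "genotype 1 absent in males", all = FALSE)
  # on X the male heterozygote block is not required
  qcx <- qc_block_filter(x3$d, x3$s, is_x = TRUE)
  expect_true(qcx$pass)
  # min_count is respected and NAs are dropped before counting
  x4 <- mk(c(5, 5, 5), c(5, 5, 5))
  expect_false(qc_block_filter(x4$d, x4$s, min_count = 6)$pass)
  d5 <- x4$d; d5[1] <- NA
  qc5 <- qc_block_filter(d5, x4$s)
  expect_match(qc5$reasons, "male genotype 0 count 4 < 5", all = FALSE)
})

test_that("Huber IWLS matches OLS on clean data and MASS::rlm on contaminated data", {
  set.seed(71)
  # bounded noise where no residual exceeds k * scale: every Huber weight is
  # 1 and the M-estimate coincides with OLS up to the convergence tolerance
  for (i in 1:5) {
    n <- 200
    snp <- rbinom(n, 2, 0.3)
    y <- 1 + 0.5 * snp + sample(c(-0.9, -0.5, 0.5, 0.9), n, replace = TRUE)
    f <- fit_rlm_huber(y, snp)
    expect_equal(f$status, "ok")
    o <- ols_normal_equations(cbind(1, snp), y)
    expect_lt(max(abs(f$beta - o$beta)), 1e-6)
  }
  # clean gaussian: Huber downweights the ~18% of residuals beyond k * scale,
  # so it tracks OLS only to sampling precision
  for (i in 1:5) {
    n <- 200
    snp <- rbinom(n, 2, 0.3)
    pcs <- matrix(rnorm(n * 3), n)
    y <- 1 + 0.5 * snp + rnorm(n)
    f <- fit_rlm_huber(y, snp, pcs)
    expect_equal(f$status, "ok")
    o <- ols_normal_equations(cbind(1, snp, pcs), y)
    expect_lt(max(abs(f$beta - o$beta)), 0.06)
  }
  # contaminated: agrees with the independently-implemented MASS::rlm
  skip_if_not_installed("MASS")
  for (i in 1:5) {
    n <- 150
    snp <- rbinom(n, 2, 0.35)
    pcs <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("PC1", "PC2")))
    y <- 0.8 * snp + pcs %*% c(0.3, -0.2) + rnorm(n)
    y[1:6] <- y[1:6] + 12
    f <- fit_rlm_huber(y, snp, pcs)
    m <- MASS::rlm(y ~ snp + pcs, maxit = 100)
    expect_lt(max(abs(f$beta - coef(m))), 1e-4)
    expect_lt(max(abs(f$se - summary(m)$coefficients[, 2])), 1e-3)
    expect_equal(f$scale, m$s, tolerance = 1e-3)
  }
  # exact linear data: coefficients recovered, scale degenerate, no silent p
  snp <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  fp <- fit_rlm_huber(2 * snp, snp)
  expect_equal(fp$status, "scale_degenerate")
  expect_equal(unname(fp$beta), c(0, 2), tolerance = 1e-10)
  expect_error(robust_wald_test(fp), "degenerate scale")
  # precondition failures
  expect_equal(fit_rlm_huber(rnorm(50), rep(1, 50))$status, "constant_snp")
  expect_equal(fit_rlm_huber(rnorm(4), c(0, 1, 2, 1),
                             pcs = matrix(rnorm(8), 4))$status, "insufficient_n")
})

test_that("the IWLS objective is non-increasing across iterations", {
  set.seed(72)
  for (i in 1:20) {
    n <- sample(60:200, 1)
    snp <- rbinom(n, 2, runif(1, 0.2, 0.5))
    y <- 0.5 * snp + rnorm(n)
    nout <- sample(0:8, 1)
    if (nout > 0) y[seq_len(nout)] <- y[seq_len(nout)] + rnorm(nout, 0, 10)
    f <- fit_rlm_huber(y, snp, trace = TRUE)
    if (f$status != "ok") next
    X <- cbind(1, snp)
    losses <- apply(f$path, 1, function(b)
      huber_loss(y - drop(X %*% b), f$scale))
    expect_true(all(diff(losses) <= 1e-8 * (1 + losses[-length(losses)])))
  }
})

test_that("robust Wald test: null center, monotonicity, type-I calibration", {
  set.seed(73)
  n <- 170
  snp <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  f <- fit_rlm_huber(y, snp)
  # a zero coefficient gives p = 1 exactly
  f0 <- f; f0$beta[["snp"]] <- 0
  expect_equal(robust_wald_test(f0)$p, 1)
  # p decreases monotonically in |statistic|
  ps <- vapply(c(0.5, 1, 2, 4), function(b) {
    fb <- f; fb$beta[["snp"]] <- b * f$se[["snp"]]
    robust_wald_test(fb)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # unconverged fits refuse to produce a p
  fu <- f; fu$status <- "not_converged"
  expect_error(robust_wald_test(fu), "converged")

  # empirical type-I error at nominal 0.05 within [0.03, 0.07]
  reject <- logical(2000)
  for (i in 1:2000) {
    snp_i <- rbinom(n, 2, 0.3)
    fit <- fit_rlm_huber(rnorm(n), snp_i)
    reject[i] <- fit$status == "ok" && robust_wald_test(fit)$p < 0.05
  }
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("Huber regression resists gross outliers better than OLS", {
  # 5% contamination at 10 sigma, n = 100: the robust fit wins a clear
  # majority of head-to-head slope comparisons and cuts the aggregate error
  set.seed(74)
  reps <- 200
  err_rlm <- err_ols <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 100
    snp <- rbinom(n, 2, 0.3)
    e <- rnorm(n)
    out <- runif(n) < 0.05
    e[out] <- rnorm(sum(out), 0, 10)
    y <- 1 + 0.5 * snp + e
    err_ols[i] <- abs(ols_normal_equations(cbind(1, snp), y)$beta[2] - 0.5)
    err_rlm[i] <- abs(fit_rlm_huber(y, snp)$beta[["snp"]] - 0.5)
  }
  expect_gt(mean(err_rlm < err_ols), 0.6)
  expect_lt(mean(err_rlm), 0.6 * mean(err_ols))
})

test_that("stage-2 calls: QC exclusion, OR logic, ordering, permutation invariance", {
  # female-only effect so only the female stratum should drive the call
  ds <- make_tiny_dataset(n_male = 120, n_female = 120, beta3 = 1.5, seed = 75)
  s1 <- run_stage1(ds, pairs = data.frame(variant_id = "v01", feature_id = "f01"),
                   q = 0.999)  # force the pair through to stage 2
  s2 <- run_stage2(s1$results, ds)
  expect_equal(nrow(s2$calls), 1)
  expect_equal(s2$calls$which_stratum, "female")
  expect_true(s2$calls$p_female <= s2$screen$p_threshold)

  # candidate failing block QC is excluded before fitting, reason recorded
  ds$genotypes$dosage["v02", ] <- c(rep(0L, 236), rep(1L, 2), rep(2L, 2))
  cand <- data.frame(variant_id = c("v01", "v02"), feature_id = c("f01", "f02"))
  s2b <- run_stage2(cand, ds)
  r2 <- s2b$results[s2b$results$variant_id == "v02", ]
  expect_false(r2$qc_pass)
  expect_match(r2$qc_reason, "count")
  expect_true(is.na(r2$p_male) && is.na(r2$p_female))

  # per-stratum pooling is available and flags the same female-driven pair
  s2c <- run_stage2(cand, ds, pool = "per_stratum")
  expect_true(s2c$results$significant[s2c$results$variant_id == "v01"])

  # empty candidate set is not an error
  s2e <- run_stage2(ds$genotypes$variants[0, ], ds)
  expect_equal(nrow(s2e$calls), 0)

  # permuting sample order leaves the calls identical
  perm <- sample(nrow(ds$samples))
  dsp <- ds
  dsp$genotypes$dosage <- ds$genotypes$dosage[, perm]
  dsp$samples <- ds$samples[perm, ]
  rownames(dsp$samples) <- NULL
  dsp$expression$values <- ds$expression$values[, perm]
  s2p <- run_stage2(cand, dsp)
  for (col in c("variant_id", "feature_id", "significant", "which_stratum"))
    expect_identical(s2p$results[[col]], s2b$results[[col]])
  expect_equal(s2p$results$p_female, s2b$results$p_female, tolerance = 1e-9)
})
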