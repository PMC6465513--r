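test_that("genotype dosages follow binomial HWE moments; X males are hemizygous 0/2", {
  # p = 0.5, 10000 autosomal samples: mean dosage within 3 binomial SEs of 1
  cfg <- sim_config(n_male = 5000, n_female = 5000, n_variants = 3,
                    n_features = 1, maf_range = c(0.5, 0.5), seed = 101)
  g <- simulate_genotypes(cfg)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  for (j in 1:3)
    expect_lt(abs(mean(g$dosage[j, ]) - 1), 3 * se)

  # mean dosage per variant is ~2 * MAF across a range of frequencies
  cfg2 <- sim_config(n_male = 1000, n_female = 1000, n_variants = 50,
                     n_features = 1, maf_range = c(0.05, 0.5), seed = 102)
  g2 <- simulate_genotypes(cfg2)
  for (j in seq_len(50)) {
    p <- g2$variants$af[j]
    se_j <- sqrt(2 * p * (1 - p) / 2000)
    expect_lt(abs(mean(g2$dosage[j, ]) - 2 * p), 4 * se_j)
  }

  # X chromosome: every male dosage in {0, 2}, females in {0, 1, 2}
  cfgx <- sim_config(n_male = 200, n_female = 200, n_variants = 20,
                     n_features = 1, chrom_type = "X",
                     maf_range = c(0.2, 0.5), seed = 103)
  gx <- simulate_genotypes(cfgx)
  sex <- rep(c(0L, 1L), c(200, 200))
  expect_true(all(gx$dosage[, sex == 0] %in% c(0L, 2L)))
  expect_true(all(gx$dosage[, sex == 1] %in% c(0L, 1L, 2L)))
  expect_true(all(gx$variants$is_x))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(sigma = 0), "sigma")
  expect_error(sim_config(outlier_fraction = 1), "outlier_fraction")
  expect_error(sim_config(n_male = 4, n_female = 4, n_pcs = 3),
               "2 \\* n_pcs \\+ 6")
  expect_error(sim_config(effects = data.frame(feature = 1, beta3 = 1)),
               "missing columns")
  expect_error(sim_config(n_features = 2,
                          effects = data.frame(feature = 5, beta0 = 0,
                                               beta1 = 0, beta2 = 0, beta3 = 1)),
               "out of range")
})

test_that("sample table uses 0/1 sex coding and honours the PC count", {
  cfg <- sim_config(n_male = 162, n_female = 176, n_variants = 2,
                    n_features = 1, seed = 7)
  s <- simulate_samples(cfg)
  expect_equal(nrow(s), 338)
  expect_equal(sum(s$sex == 0), 162)
  expect_equal(sum(s$sex == 1), 176)
  expect_true(all(s$sex %in% c(0L, 1L)))
  expect_named(s, c("sample_id", "sex", "PC1", "PC2", "PC3"))

  # n_pcs = 0: no PC columns, and the downstream model still fits
  cfg0 <- sim_config(n_male = 50, n_female = 50, n_variants = 2,
                     n_features = 1, n_pcs = 0, seed = 8)
  s0 <- simulate_samples(cfg0)
  expect_named(s0, c("sample_id", "sex"))
  ds0 <- simulate_dataset(cfg0)
  f <- fit_interaction_model(ds0$expression$values[1, ],
                             ds0$genotypes$dosage[ds0$truth$variant_id[1], ],
                             s0$sex, pcs = NULL)
  expect_equal(f$status, "ok")
  expect_length(f$beta, 4)

  # sex-PC confounding knob shifts PC1 in females
  cfgc <- sim_config(n_male = 2000, n_female = 2000, n_variants = 2,
                     n_features = 1, sex_pc_cor = 1.5, seed = 9)
  sc <- simulate_samples(cfgc)
  expect_gt(mean(sc$PC1[sc$sex == 1]) - mean(sc$PC1[sc$sex == 0]), 1.0)
})

test_that("expression follows the generative interaction model", {
  # pure noise: variance ~ sigma^2 at n = 10000
  cfg <- sim_config(n_male = 5000, n_female = 5000, n_variants = 2,
                    n_features = 1, seed = 21)
  ds <- simulate_dataset(cfg)
  expect_lt(abs(var(ds$expression$values[1, ]) - 1), 3 * sqrt(2 / 10000))

  # beta3 = 0.5 with near-zero noise: female-minus-male per-dosage slope -> 0.5
  cfg2 <- sim_config(n_male = 200, n_female = 200, n_variants = 10,
                     n_features = 2, maf_range = c(0.3, 0.5), sigma = 1e-7,
                     n_pcs = 0, seed = 22,
                     effects = data.frame(feature = 1, beta0 = 0, beta1 = 0,
                                          beta2 = 0, beta3 = 0.5))
  ds2 <- simulate_dataset(cfg2)
  snp <- ds2$genotypes$dosage[ds2$truth$variant_id[1], ]
  y <- ds2$expression$values[1, ]
  sex <- ds2$samples$sex
  slope_m <- coef(lm(y[sex == 0] ~ snp[sex == 0]))[2]
  slope_f <- coef(lm(y[sex == 1] ~ snp[sex == 1]))[2]
  expect_equal(unname(slope_f - slope_m), 0.5, tolerance = 1e-5)

  # contaminated noise is heavier-tailed than gaussian (excess kurtosis)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  cfg_g <- sim_config(n_male = 5000, n_female = 5000, n_variants = 2,
                      n_features = 1, seed = 23)
  cfg_c <- sim_config(n_male = 5000, n_female = 5000, n_variants = 2,
                      n_features = 1, seed = 23, noise = "contaminated",
                      outlier_fraction = 0.05, outlier_scale = 10)
  kg <- kurt(simulate_dataset(cfg_g)$expression$values[1, ])
  kc <- kurt(simulate_dataset(cfg_c)$expression$values[1, ])
  expect_gt(kc, kg + 5)
})

test_that("the master seed reproduces the dataset bit-for-bit and per-variant streams", {
  cfg <- sim_config(n_variants = 30, n_features = 6, seed = 42)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(sim_config(n_variants = 30, n_features = 6, seed = 42))
  expect_identical(ds1$genotypes$dosage, ds2$genotypes$dosage)
  expect_identical(ds1$expression$values, ds2$expression$values)
  expect_identical(ds1$samples, ds2$samples)
  expect_identical(ds1$truth, ds2$truth)

  # per-variant derived streams: the first variants' dosages do not change
  # when more variants are appended to the same configuration
  g_small <- simulate_genotypes(sim_config(n_variants = 10, n_features = 2, seed = 42))
  g_big <- simulate_genotypes(sim_config(n_variants = 25, n_features = 2, seed = 42))
  expect_identical(unname(g_small$dosage), unname(g_big$dosage[1:10, ]))

  # different seed changes the data
  ds3 <- simulate_dataset(sim_config(n_variants = 30, n_features = 6, seed = 43))
  expect_false(identical(ds1$genotypes$dosage, ds3$genotypes$dosage))

  # truth has exactly one row per simulated feature, ids aligned
  expect_equal(nrow(ds1$truth), 6)
  expect_identical(ds1$truth$feature_id, rownames(ds1$expression$values))
  expect_identical(colnames(ds1$genotypes$dosage), ds1$samples$sample_id)
  expect_identical(colnames(ds1$expression$values), ds1$samples$sample_id)
})
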