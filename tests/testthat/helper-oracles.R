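# Independent oracles used across tests. These are deliberately naive
# implementations (normal equations, brute-force enumeration) kept separate
# from the package's code paths.

# OLS by explicit normal equations: beta = (X'X)^-1 X'y, se from sigma^2 (X'X)^-1.
ols_normal_equations <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% (t(X) %*% y))
  r <- y - drop(X %*% beta)
  sigma2 <- sum(r^2) / (length(y) - ncol(X))
  list(beta = beta, se = sqrt(sigma2 * diag(xtx_inv)))
}

# Benjamini-Hochberg by definition: sort, find the largest i with
# p_(i) <= i*q/m, reject everything at or below that p-value.
bh_by_definition <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  pass <- which(ps <= seq_len(m) * q / m)
  if (!length(pass)) return(integer(0))
  which(p <= ps[max(pass)])
}

# Brute-force cis pairing: double loop over every variant-feature combination.
cis_pairs_brute <- function(variants, features, window) {
  hits <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(features))) {
      if (variants$chrom[i] == features$chrom[j] &&
          abs(variants$pos[i] - features$anchor[j]) <= window)
        hits[[length(hits) + 1L]] <- c(variants$variant_id[i],
                                       features$feature_id[j])
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, paste, character(1), collapse = "|"))
}

# Small aligned dataset built directly (not via the generator) for
# stage-1/stage-2 plumbing tests.
make_tiny_dataset <- function(n_male = 90, n_female = 90, n_var = 12,
                              n_feat = 4, beta3 = 0, maf = 0.3, seed = 1,
                              sigma = 1) {
  set.seed(seed)
  n <- n_male + n_female
  sex <- rep(c(0L, 1L), c(n_male, n_female))
  sample_id <- sprintf("T%03d", seq_len(n))
  dosage <- matrix(rbinom(n_var * n, 2, maf), nrow = n_var,
                   dimnames = list(sprintf("v%02d", seq_len(n_var)), sample_id))
  variants <- data.frame(variant_id = rownames(dosage), chrom = "1",
                         pos = seq(1e5, by = 2e5, length.out = n_var),
                         ref = "A", alt = "G", is_x = FALSE,
                         stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("PC", 1:3)))
  samples <- data.frame(sample_id = sample_id, sex = sex, pcs,
                        stringsAsFactors = FALSE)
  class(samples) <- c("sseqtl_samples", "data.frame")
  values <- matrix(NA_real_, n_feat, n,
                   dimnames = list(sprintf("f%02d", seq_len(n_feat)), sample_id))
  for (f in seq_len(n_feat)) {
    b3 <- if (f == 1) beta3 else 0
    values[f, ] <- b3 * sex * dosage[f, ] + rnorm(n, 0, sigma)
  }
  features <- data.frame(feature_id = rownames(values), chrom = "1",
                         anchor = variants$pos[seq_len(n_feat)], strand = "+",
                         stringsAsFactors = FALSE)
  expression <- structure(list(values = values, features = features),
                          class = "sseqtl_expression")
  genotypes <- structure(list(dosage = dosage, variants = variants),
                         class = "sseqtl_genotypes")
  list(genotypes = genotypes, samples = samples, expression = expression)
}
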