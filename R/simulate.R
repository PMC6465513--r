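#' Configuration for the synthetic eQTL cohort generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' the design of a lymphoblastoid-cell-line eQTL cohort: 174 males and 160
#' females, biallelic SNP dosages drawn under Hardy-Weinberg equilibrium with
#' minor allele frequency at least 1\%, three population-structure principal
#' components, and continuous normalized expression produced by the stage-1
#' generative model
#' \eqn{y = \beta_0 + \beta_1 SNP + \beta_2 sex + \beta_3 sex \cdot SNP +
#' \sum_k \beta_{PC_k} PC_k + e}.
#'
#' @param n_male,n_female Number of male (sex code 0) and female (sex code 1)
#'   samples. Their sum must leave enough residual degrees of freedom for the
#'   interaction model (at least `2 * n_pcs + 6`).
#' @param n_variants,n_features Number of simulated variants and expression
#'   features.
#' @param maf_range Length-2 numeric, the interval in (0, 0.5] from which
#'   per-variant allele frequencies are drawn uniformly.
#' @param n_pcs Number of principal-component covariates (default 3; 0 is
#'   allowed and drops the PC terms everywhere downstream).
#' @param chrom_type `"autosome"` or `"X"`. On X, males are simulated
#'   hemizygous (one allele, dosage coded 0/2) and females diploid (0/1/2).
#' @param chrom_length Length in bp of the single synthetic chromosome over
#'   which variant positions and feature anchors are placed uniformly at
#'   random, so that the cis-window pairing is non-trivial (default 10 Mb).
#' @param effects Optional data frame of generative coefficients with columns
#'   `feature` (feature index), `variant` (variant index, `NA` = nearest
#'   variant to the feature anchor), `beta0`, `beta1`, `beta2`, `beta3`, and
#'   optionally `beta_pc1` ... `beta_pc<n_pcs>`. One row per feature; features
#'   without a row get all-zero coefficients. The interaction coefficient
#'   `beta3` is the sex-interacting effect a downstream scan should recover.
#' @param noise `"gaussian"` for N(0, sigma^2) errors, or `"contaminated"`
#'   for a scale mixture in which a fraction `outlier_fraction` of errors is
#'   drawn with standard deviation `sigma * outlier_scale` (heavy tails, to
#'   exercise the robust stage).
#' @param sigma Residual standard deviation of the clean component (> 0).
#' @param outlier_fraction,outlier_scale Contamination fraction in [0, 1) and
#'   scale multiplier of the contaminating component.
#' @param sex_pc_cor Optional confounding knob: a shift of `sex_pc_cor` added
#'   to PC1 for females, inducing a sex-PC correlation (default 0,
#'   independence).
#' @param seed Master integer seed; all component streams are derived from it
#'   deterministically (see [simulate_dataset()]).
#'
#' @return An object of class `sseqtl_sim_config` (a validated list).
#' @seealso [simulate_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 20, n_features = 5, seed = 7)
#' str(cfg[c("n_male", "n_female", "maf_range")])
sim_config <- function(n_male = 174, n_female = 160,
                       n_variants = 100, n_features = 20,
                       maf_range = c(0.01, 0.5), n_pcs = 3,
                       chrom_type = c("autosome", "X"),
                       chrom_length = 1e7,
                       effects = NULL,
                       noise = c("gaussian", "contaminated"),
                       sigma = 1, outlier_fraction = 0.05,
                       outlier_scale = 10, sex_pc_cor = 0,
                       seed = 1L) {
  chrom_type <- match.arg(chrom_type)
  noise <- match.arg(noise)
  for (nm in c("n_male", "n_female", "n_variants", "n_features")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
  }
  if (!is.numeric(maf_range) || length(maf_range) != 2L || any(is.na(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  if (!is.numeric(n_pcs) || length(n_pcs) != 1L || n_pcs < 0 || n_pcs != round(n_pcs))
    stop("`n_pcs` must be a non-negative integer", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("`outlier_fraction` must be in [0, 1)", call. = FALSE)
  if (outlier_scale <= 0) stop("`outlier_scale` must be > 0", call. = FALSE)
  if (n_male + n_female < 2 * n_pcs + 6)
    stop("n_male + n_female must be at least 2 * n_pcs + 6 ",
         "(residual degrees of freedom for the interaction model)", call. = FALSE)
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    need <- c("feature", "beta0", "beta1", "beta2", "beta3")
    miss <- setdiff(need, names(effects))
    if (length(miss))
      stop("`effects` is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!"variant" %in% names(effects)) effects$variant <- NA_integer_
    if (anyDuplicated(effects$feature))
      stop("`effects` must have at most one row per feature", call. = FALSE)
    if (any(effects$feature < 1 | effects$feature > n_features))
      stop("`effects$feature` indices out of range", call. = FALSE)
    bad <- !is.na(effects$variant) &
      (effects$variant < 1 | effects$variant > n_variants)
    if (any(bad)) stop("`effects$variant` indices out of range", call. = FALSE)
  }
  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    n_variants = as.integer(n_variants), n_features = as.integer(n_features),
    maf_range = maf_range, n_pcs = as.integer(n_pcs),
    chrom_type = chrom_type, chrom_length = chrom_length,
    effects = effects, noise = noise, sigma = sigma,
    outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
    sex_pc_cor = sex_pc_cor, seed = as.integer(seed)
  ), class = "sseqtl_sim_config")
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each variant gets an allele frequency drawn uniformly from
#' `config$maf_range` and a position uniform on the synthetic chromosome.
#' Autosomal dosages are iid Binomial(2, p) per sample (HWE). On the X
#' chromosome males carry one allele, Binomial(1, p), recoded to dosage
#' \{0, 2\} (hemizygous coding), while females are Binomial(2, p). Variants
#' are mutually independent: no linkage disequilibrium is simulated.
#'
#' Per-variant random streams are derived from the master seed, so the
#' dosages of any subset of variants are reproducible independently of the
#' rest.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sseqtl_genotypes`: a list with `dosage`
#'   (variants x samples integer matrix, dimnames set) and `variants` (data
#'   frame with `variant_id`, `chrom`, `pos`, `ref`, `alt`, `af`, `is_x`).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_variants = 5, seed = 1))
#' g$variants
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sseqtl_sim_config"))
  n <- config$n_male + config$n_female
  nv <- config$n_variants
  is_x <- config$chrom_type == "X"
  set.seed(derive_seed(config$seed, 1L))
  af <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  pos <- sort(sample.int(config$chrom_length, nv, replace = FALSE))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  sex <- rep(c(0L, 1L), c(config$n_male, config$n_female))
  dosage <- matrix(0L, nrow = nv, ncol = n)
  for (j in seq_len(nv)) {
    set.seed(derive_seed(config$seed, 1000L + j))
    if (is_x) {
      male <- stats::rbinom(config$n_male, 1L, af[j])
      female <- stats::rbinom(config$n_female, 2L, af[j])
      dosage[j, ] <- c(encode_x_dosage(male, rep(0L, config$n_male)), female)
    } else {
      dosage[j, ] <- stats::rbinom(n, 2L, af[j])
    }
  }
  variant_id <- sprintf("var%05d", seq_len(nv))
  sample_id <- sprintf("S%04d", seq_len(n))
  dimnames(dosage) <- list(variant_id, sample_id)
  variants <- data.frame(
    variant_id = variant_id,
    chrom = if (is_x) "X" else "1",
    pos = pos, ref = ref, alt = alt, af = af,
    is_x = is_x,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(dosage = dosage, variants = variants),
            class = "sseqtl_genotypes")
}

#' Simulate the sample metadata table
#'
#' Sex is coded 0 for male and 1 for female. Principal components are iid
#' standard normal; the optional `sex_pc_cor` knob shifts PC1 by that amount
#' in females to let tests probe sex-PC confounding.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `sseqtl_samples` with `sample_id`, `sex`,
#'   and `PC1` ... `PC<n_pcs>` columns (no PC columns when `n_pcs = 0`).
#' @export
#' @examples
#' head(simulate_samples(sim_config(n_male = 4, n_female = 4, seed = 2)))
simulate_samples <- function(config) {
  stopifnot(inherits(config, "sseqtl_sim_config"))
  n <- config$n_male + config$n_female
  set.seed(derive_seed(config$seed, 2L))
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = rep(c(0L, 1L), c(config$n_male, config$n_female)),
    stringsAsFactors = FALSE
  )
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), nrow = n,
                  dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
    if (config$sex_pc_cor != 0)
      pcs[, 1] <- pcs[, 1] + config$sex_pc_cor * samples$sex
    samples <- cbind(samples, as.data.frame(pcs))
  }
  class(samples) <- c("sseqtl_samples", "data.frame")
  samples
}

#' Simulate normalized expression from the interaction model
#'
#' For each feature, expression is generated as
#' \eqn{y = \beta_0 + \beta_1 SNP + \beta_2 sex + \beta_3 sex \cdot SNP +
#' \sum_k \beta_{PC_k} PC_k + e} where SNP is the dosage of the feature's
#' generative variant, and `e` follows the configured noise model (gaussian
#' or contaminated). Feature anchors (a stand-in for the TSS or miRNA locus)
#' are placed uniformly on the synthetic chromosome; by default the
#' generative variant of each feature is the variant nearest its anchor, so
#' the pair always falls inside the default 1 Mb cis window.
#'
#' @param genotypes A `sseqtl_genotypes` object from [simulate_genotypes()].
#' @param samples A `sseqtl_samples` table from [simulate_samples()].
#' @param config The same [sim_config()] used for the other two components.
#' @return An object of class `sseqtl_expression`: list with `values`
#'   (features x samples numeric matrix), `features` (data frame
#'   `feature_id`, `chrom`, `anchor`, `strand`), and `truth` (data frame of
#'   generative coefficients, one row per feature-variant pair).
#' @export
simulate_expression <- function(genotypes, samples, config) {
  stopifnot(inherits(config, "sseqtl_sim_config"),
            inherits(genotypes, "sseqtl_genotypes"))
  if (!identical(colnames(genotypes$dosage), samples$sample_id))
    stop("sample ids of `genotypes` and `samples` are not aligned", call. = FALSE)
  n <- nrow(samples)
  nf <- config$n_features
  set.seed(derive_seed(config$seed, 3L))
  anchor <- sort(sample.int(config$chrom_length, nf, replace = FALSE))
  features <- data.frame(
    feature_id = sprintf("feat%04d", seq_len(nf)),
    chrom = genotypes$variants$chrom[1],
    anchor = anchor, strand = "+",
    stringsAsFactors = FALSE
  )

  # Assemble per-feature coefficient rows (zero unless listed in effects).
  pc_names <- if (config$n_pcs > 0) paste0("PC", seq_len(config$n_pcs)) else character(0)
  beta_pc_cols <- paste0("beta_pc", seq_len(config$n_pcs))
  truth <- data.frame(
    feature_id = features$feature_id,
    variant_id = NA_character_,
    beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
    stringsAsFactors = FALSE
  )
  for (cn in beta_pc_cols) truth[[cn]] <- 0
  nearest <- vapply(anchor, function(a)
    which.min(abs(genotypes$variants$pos - a)), integer(1))
  vidx <- nearest
  if (!is.null(config$effects)) {
    ef <- config$effects
    for (i in seq_len(nrow(ef))) {
      f <- ef$feature[i]
      if (!is.na(ef$variant[i])) vidx[f] <- ef$variant[i]
      truth$beta0[f] <- ef$beta0[i]
      truth$beta1[f] <- ef$beta1[i]
      truth$beta2[f] <- ef$beta2[i]
      truth$beta3[f] <- ef$beta3[i]
      for (k in seq_len(config$n_pcs)) {
        cn <- beta_pc_cols[k]
        if (cn %in% names(ef)) truth[[cn]][f] <- ef[[cn]][i]
      }
    }
  }
  truth$variant_id <- genotypes$variants$variant_id[vidx]

  sex <- samples$sex
  pcs <- if (config$n_pcs > 0) as.matrix(samples[, pc_names, drop = FALSE]) else NULL
  values <- matrix(NA_real_, nrow = nf, ncol = n,
                   dimnames = list(features$feature_id, samples$sample_id))
  for (f in seq_len(nf)) {
    snp <- genotypes$dosage[vidx[f], ]
    mu <- truth$beta0[f] + truth$beta1[f] * snp + truth$beta2[f] * sex +
      truth$beta3[f] * sex * snp
    if (config$n_pcs > 0)
      mu <- mu + drop(pcs %*% unlist(truth[f, beta_pc_cols]))
    e <- stats::rnorm(n, 0, config$sigma)
    if (config$noise == "contaminated" && config$outlier_fraction > 0) {
      out <- stats::runif(n) < config$outlier_fraction
      e[out] <- stats::rnorm(sum(out), 0, config$sigma * config$outlier_scale)
    }
    values[f, ] <- mu + e
  }
  structure(list(values = values, features = features, truth = truth),
            class = "sseqtl_expression")
}

#' Simulate a complete synthetic eQTL dataset
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_samples()]
#' and [simulate_expression()] from one configuration. All randomness derives
#' deterministically from `config$seed`: the same configuration reproduces
#' the identical dataset bit-for-bit.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sseqtl_dataset`: list with `genotypes`,
#'   `samples`, `expression`, and `truth` (the generative coefficient table,
#'   also carried inside `expression`).
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_variants = 10, n_features = 3, seed = 5))
#' ds$truth
simulate_dataset <- function(config) {
  genotypes <- simulate_genotypes(config)
  samples <- simulate_samples(config)
  expression <- simulate_expression(genotypes, samples, config)
  structure(list(genotypes = genotypes, samples = samples,
                 expression = expression, truth = expression$truth,
                 config = config),
            class = "sseqtl_dataset")
}

#' @export
print.sseqtl_dataset <- function(x, ...) {
  cat("sseqtl synthetic dataset\n")
  cat(sprintf("  %d variants (%s), %d features, %d samples (%d male / %d female)\n",
              nrow(x$genotypes$variants),
              if (x$config$chrom_type == "X") "chrX" else "autosomal",
              nrow(x$expression$values), nrow(x$samples),
              sum(x$samples$sex == 0), sum(x$samples$sex == 1)))
  nz <- sum(x$truth$beta3 != 0)
  cat(sprintf("  noise: %s (sigma = %g); features with nonzero sex*SNP effect: %d\n",
              x$config$noise, x$config$sigma, nz))
  invisible(x)
}
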