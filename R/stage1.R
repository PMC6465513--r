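#' Fit the stage-1 sex-interaction model for one variant-feature pair
#'
#' Ordinary least squares fit of
#' \eqn{y = \beta_0 + \beta_1 SNP + \beta_2 sex + \beta_3 sex \cdot SNP +
#' \sum_k \beta_{PC_k} PC_k + e},
#' with a two-sided t-test of the interaction coefficient \eqn{\beta_3}
#' (degrees of freedom = complete cases minus fitted columns). Samples with
#' any missing value are dropped per-pair (complete-case analysis).
#'
#' Instead of silently returning an unreliable p-value, the fit is flagged:
#' `status` is `"ok"` for a regular fit, `"single_sex"` / `"constant_snp"` /
#' `"insufficient_n"` when the design cannot identify the interaction,
#' `"collinear"` when the design matrix is rank deficient, and
#' `"degenerate"` when the residual variance is numerically zero (exact
#' fit). Only `"ok"` fits carry a p-value.
#'
#' @param y Numeric response vector (normalized expression).
#' @param snp Dosage vector (0/1/2; on X males coded 0/2).
#' @param sex 0/1 vector (0 male, 1 female).
#' @param pcs Optional numeric matrix of covariates (columns = PCs), or NULL.
#' @return List of class `sseqtl_stage1_fit`: `beta` and `se` (named:
#'   intercept, snp, sex, sex_snp, PC...), `p_interaction`, `sigma`,
#'   `n_used`, `df`, `status`.
#' @export
#' @examples
#' set.seed(1)
#' n <- 200; snp <- rbinom(n, 2, 0.3); sex <- rep(0:1, each = n / 2)
#' y <- 0.5 * snp * sex + rnorm(n)
#' fit_interaction_model(y, snp, sex)$beta
fit_interaction_model <- function(y, snp, sex, pcs = NULL) {
  if (!is.null(pcs)) pcs <- as.matrix(pcs)
  n_all <- length(y)
  ok <- !is.na(y) & !is.na(snp) & !is.na(sex)
  if (!is.null(pcs) && ncol(pcs) > 0) ok <- ok & stats::complete.cases(pcs)
  y <- y[ok]; snp <- snp[ok]; sex <- sex[ok]
  if (!is.null(pcs)) pcs <- pcs[ok, , drop = FALSE]
  n <- length(y)
  p <- 4L + if (is.null(pcs)) 0L else ncol(pcs)
  nm <- c("intercept", "snp", "sex", "sex_snp",
          if (!is.null(pcs) && ncol(pcs) > 0) colnames(pcs) %||%
            paste0("PC", seq_len(ncol(pcs))))
  empty <- function(status) structure(
    list(beta = stats::setNames(rep(NA_real_, p), nm),
         se = stats::setNames(rep(NA_real_, p), nm),
         p_interaction = NA_real_, sigma = NA_real_,
         n_used = n, df = NA_integer_, status = status),
    class = "sseqtl_stage1_fit")
  if (n < p + 2L) return(empty("insufficient_n"))
  if (length(unique(sex)) < 2L) return(empty("single_sex"))
  if (length(unique(snp)) < 2L) return(empty("constant_snp"))

  X <- cbind(1, snp, sex, sex * snp, pcs)
  fit <- ols_qr(X, y)
  if (is.null(fit)) return(empty("collinear"))
  beta <- stats::setNames(fit$beta, nm)
  rss <- fit$rss
  df <- n - p
  xtx_inv <- fit$xtx_inv
  if (rss <= 1e-12 * (sum(y^2) + 1)) {
    out <- empty("degenerate")
    out$beta <- beta
    out$n_used <- n
    out$df <- df
    return(out)
  }
  sigma2 <- rss / df
  se <- stats::setNames(sqrt(sigma2 * diag(xtx_inv)), nm)
  tstat <- beta[["sex_snp"]] / se[["sex_snp"]]
  p_int <- 2 * stats::pt(-abs(tstat), df)
  structure(list(beta = beta, se = se, p_interaction = p_int,
                 sigma = sqrt(sigma2), n_used = n, df = df, status = "ok"),
            class = "sseqtl_stage1_fit")
}

#' Benjamini-Hochberg step-up screen
#'
#' Standard step-up procedure at level `q`: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, find the largest \eqn{i} with
#' \eqn{p_{(i)} \le i q / m} and reject all tests with p-values at or below
#' \eqn{p_{(i)}}. Ties at the threshold are rejected together. Implemented
#' through [stats::p.adjust()]. `NA` p-values (flagged degenerate fits) are
#' excluded from the test count `m` with a logged tally.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NAs allowed).
#' @param q FDR level (default 0.05).
#' @return List of class `sseqtl_fdr`: `q`, `m` (tests entering BH),
#'   `n_excluded` (NA count), `rejected` (integer indices into `pvalues`),
#'   `n_rejected`, and `p_threshold` — the largest rejected p-value, the
#'   run's "equivalent p-value threshold" (`NA` when nothing is rejected).
#' @export
#' @examples
#' bh_threshold(c(0.001, 0.01, 0.02, 0.04, 0.9), q = 0.05)
bh_threshold <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value vector", call. = FALSE)
  assert_prob(q, "q")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  keep <- which(!is.na(pvalues))
  m <- length(keep)
  if (m == 0) stop("all p-values are NA", call. = FALSE)
  adj <- stats::p.adjust(pvalues[keep], method = "BH")
  rej <- keep[adj <= q]
  structure(list(
    q = q, m = m, n_excluded = length(pvalues) - m,
    rejected = rej, n_rejected = length(rej),
    p_threshold = if (length(rej)) max(pvalues[rej]) else NA_real_
  ), class = "sseqtl_fdr")
}

#' @export
print.sseqtl_fdr <- function(x, ...) {
  cat(sprintf("BH screen at q = %g: %d / %d rejected", x$q, x$n_rejected, x$m))
  if (x$n_excluded) cat(sprintf(" (%d untestable excluded)", x$n_excluded))
  cat(sprintf("; equivalent p threshold: %s\n",
              if (is.na(x$p_threshold)) "none" else format(x$p_threshold)))
  invisible(x)
}

#' Run the stage-1 interaction scan over all cis pairs
#'
#' Fits [fit_interaction_model()] for every cis pair and applies the BH
#' screen to the interaction p-values of all regular fits jointly (one
#' screen per run: separate datasets, e.g. mRNA and miRNA, are screened by
#' separate calls). Pairs that fail fit preconditions are retained in the
#' results table with their status code but excluded from the BH test count.
#'
#' @param dataset A `sseqtl_dataset`, or any list with components
#'   `genotypes` (`sseqtl_genotypes`), `samples` (`sseqtl_samples`) and
#'   `expression` (either a `sseqtl_expression` object or a features x
#'   samples matrix).
#' @param pairs Data frame of cis pairs (`variant_id`, `feature_id`), e.g.
#'   from [enumerate_cis_pairs()]. Defaults to enumerating pairs from the
#'   dataset's own annotation with a 1 Mb window.
#' @param q Stage-1 FDR level (default 0.05).
#' @param window Cis window used when `pairs` is NULL.
#' @return List of class `sseqtl_stage1`: `results` (one row per pair:
#'   coefficients, `se_sex_snp`, `p_interaction`, `n_used`, `status`),
#'   `screen` (a `sseqtl_fdr`), and `candidates` (the rejected subset of
#'   `results`, the stage-2 input).
#' @export
run_stage1 <- function(dataset, pairs = NULL, q = 0.05, window = 1e6) {
  geno <- dataset$genotypes
  samples <- dataset$samples
  expr <- if (inherits(dataset$expression, "sseqtl_expression"))
    dataset$expression$values else dataset$expression
  if (!identical(colnames(geno$dosage), samples$sample_id) ||
      !identical(colnames(expr), samples$sample_id))
    stop("sample ids are not aligned across genotypes, expression and samples",
         call. = FALSE)
  if (is.null(pairs)) {
    feats <- if (inherits(dataset$expression, "sseqtl_expression"))
      dataset$expression$features
    else stop("`pairs` must be given when expression carries no annotation",
              call. = FALSE)
    pairs <- enumerate_cis_pairs(geno$variants, feats, window = window)
  }
  if (nrow(pairs) == 0) stop("no testable cis pairs", call. = FALSE)

  vi <- match(pairs$variant_id, geno$variants$variant_id)
  fi <- match(pairs$feature_id, rownames(expr))
  if (anyNA(vi) || anyNA(fi))
    stop("pairs reference unknown variant or feature ids", call. = FALSE)

  sex <- samples$sex
  pc_cols <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  pcs <- if (length(pc_cols)) as.matrix(samples[, pc_cols, drop = FALSE]) else NULL
  npair <- nrow(pairs)
  p_ncol <- 4L + length(pc_cols)

  beta3 <- se3 <- pint <- rep(NA_real_, npair)
  beta1 <- beta2 <- beta0 <- rep(NA_real_, npair)
  nuse <- integer(npair)
  status <- character(npair)

  # Fast path: shared design columns are fixed; only the snp and
  # interaction columns change per pair. Falls back to the general fitter
  # when the pair has missing values.
  X0 <- cbind(1, 0, sex, 0, pcs)
  any_na_base <- anyNA(sex) || (!is.null(pcs) && anyNA(pcs))
  for (i in seq_len(npair)) {
    snp <- geno$dosage[vi[i], ]
    y <- expr[fi[i], ]
    if (any_na_base || anyNA(snp) || anyNA(y)) {
      f <- fit_interaction_model(y, snp, sex, pcs)
    } else {
      n <- length(y)
      if (length(unique(sex)) < 2L) {
        f <- list(status = "single_sex", n_used = n)
      } else if (length(unique(snp)) < 2L) {
        f <- list(status = "constant_snp", n_used = n)
      } else {
        X0[, 2] <- snp
        X0[, 4] <- sex * snp
        lf <- ols_qr(X0, y)
        if (is.null(lf)) {
          f <- list(status = "collinear", n_used = n)
        } else if (lf$rss <= 1e-12 * (sum(y^2) + 1)) {
          f <- list(status = "degenerate", n_used = n, beta = lf$beta)
        } else {
          df <- n - p_ncol
          s4 <- sqrt(lf$rss / df * lf$xtx_inv[4, 4])
          tt <- lf$beta[4] / s4
          f <- list(status = "ok", n_used = n, beta = lf$beta,
                    se4 = s4, p_interaction = 2 * stats::pt(-abs(tt), df))
        }
      }
    }
    status[i] <- f$status
    nuse[i] <- f$n_used
    if (!is.null(f$beta)) {
      beta0[i] <- f$beta[[1]]; beta1[i] <- f$beta[[2]]
      beta2[i] <- f$beta[[3]]; beta3[i] <- f$beta[[4]]
    }
    if (f$status == "ok") {
      se3[i] <- if (!is.null(f$se4)) f$se4 else f$se[["sex_snp"]]
      pint[i] <- f$p_interaction
    }
  }

  results <- data.frame(
    variant_id = pairs$variant_id, feature_id = pairs$feature_id,
    beta_intercept = beta0, beta_snp = beta1, beta_sex = beta2,
    beta_sex_snp = beta3, se_sex_snp = se3, p_interaction = pint,
    n_used = nuse, status = status, stringsAsFactors = FALSE
  )
  screen <- bh_threshold(ifelse(results$status == "ok",
                                results$p_interaction, NA_real_), q = q)
  candidates <- results[screen$rejected, , drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(results = results, screen = screen, candidates = candidates),
            class = "sseqtl_stage1")
}

#' @export
print.sseqtl_stage1 <- function(x, ...) {
  cat(sprintf("stage-1 interaction scan: %d pairs (%d testable)\n",
              nrow(x$results), x$screen$m))
  print(x$screen)
  invisible(x)
}
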