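#' Genotype-by-sex block quality-control filter
#'
#' A candidate pair enters the stage-2 robust regressions only when every
#' genotype-by-sex block is well populated: each block must hold at least
#' `min_count` samples and every genotype class must be present in each sex.
#' On autosomes the required classes are dosages \{0, 1, 2\} in both sexes
#' (6 blocks). On the X chromosome males are hemizygous, so the realizable
#' male classes are \{0, 2\} and the filter requires male \{0, 2\} and
#' female \{0, 1, 2\} blocks (5 blocks).
#'
#' @param dosages Dosage vector (`NA` = missing, dropped before counting).
#' @param sex 0/1 vector aligned with `dosages`.
#' @param min_count Minimum samples per block (default 5).
#' @param is_x Logical: use the X-chromosome block definition.
#' @return List: `pass` (logical), `reasons` (character vector naming each
#'   failing block, empty when passing), `counts` (named block counts).
#' @export
#' @examples
#' qc_block_filter(rep(c(0, 1, 2), times = c(10, 10, 10)), rep(0:1, 15))
qc_block_filter <- function(dosages, sex, min_count = 5, is_x = FALSE) {
  stopifnot(length(dosages) == length(sex))
  ok <- !is.na(dosages) & !is.na(sex)
  dosages <- dosages[ok]; sex <- sex[ok]
  req_male <- if (is_x) c(0, 2) else c(0, 1, 2)
  req_female <- c(0, 1, 2)
  counts <- c()
  reasons <- character(0)
  for (s in 0:1) {
    req <- if (s == 0) req_male else req_female
    lab <- if (s == 0) "male" else "female"
    for (g in req) {
      cnt <- sum(sex == s & dosages == g)
      counts[sprintf("%s_%d", lab, g)] <- cnt
      if (cnt == 0)
        reasons <- c(reasons, sprintf("genotype %d absent in %ss", g, lab))
      else if (cnt < min_count)
        reasons <- c(reasons, sprintf("%s genotype %d count %d < %d",
                                      lab, g, cnt, min_count))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons, counts = counts)
}

#' Huber M-estimation regression by iterated reweighted least squares
#'
#' Robust fit of the sex-stratified model
#' \eqn{y = \beta_0 + \beta_1 SNP + \sum_k \beta_{PC_k} PC_k + e}
#' by a Huber-\eqn{\psi} M-estimator. Starting from the OLS solution, each
#' iteration (i) computes residuals at the current coefficients, (ii)
#' re-estimates the scale as the median absolute residual times 1.4826 (the
#' MAD normal-consistency factor), (iii) sets Huber weights
#' \eqn{w_i = \min(1, k\,\hat\sigma / |r_i|)}, and (iv) solves the weighted
#' least-squares problem. Iteration stops when the largest coefficient change
#' falls below `tol * (1 + max |beta|)` or at `max_iter`.
#'
#' Robust standard errors use the weighted-least-squares covariance at the
#' final weights with Huber's small-sample correction (the classical
#' M-estimation formula, as used for Wald tests on robust linear models):
#' \deqn{\widehat{var}(\hat\beta) = \kappa^2 \,
#'   \frac{\hat\sigma^2 \sum_i \psi(u_i)^2 / (n - p)}{[\,\overline{\psi'(u)}\,]^2}
#'   \,(X^\top X)^{-1}, \quad
#'   \kappa = 1 + \frac{p}{n}\,\frac{var(\psi'(u))}{[\,\overline{\psi'(u)}\,]^2}}
#' with \eqn{u_i = r_i / \hat\sigma}. An exact fit (median absolute residual
#' numerically zero) is flagged `scale_degenerate`: coefficients are
#' returned but no standard errors or test can be formed.
#'
#' @param y Numeric response vector.
#' @param snp Dosage vector for the stratum.
#' @param pcs Optional covariate matrix (columns = PCs).
#' @param tuning_k Huber tuning constant (default 1.345, 95\% efficiency at
#'   the gaussian).
#' @param max_iter,tol IWLS iteration cap and relative convergence tolerance.
#' @param trace Logical: keep the per-iteration coefficient path (for
#'   convergence diagnostics).
#' @return Object of class `sseqtl_rlm`: `beta`, `se` (robust), `scale`,
#'   `weights`, `n_used`, `df`, `iterations`, `converged`, `status`
#'   (`"ok"`, `"scale_degenerate"`, `"constant_snp"`, `"insufficient_n"`,
#'   `"collinear"`, `"not_converged"`), and optionally `path`.
#' @export
#' @examples
#' set.seed(2)
#' snp <- rbinom(120, 2, 0.3); y <- 1 + 0.6 * snp + rnorm(120)
#' y[1:5] <- y[1:5] + 15   # gross outliers
#' fit_rlm_huber(y, snp)$beta
fit_rlm_huber <- function(y, snp, pcs = NULL, tuning_k = 1.345,
                          max_iter = 50L, tol = 1e-8, trace = FALSE) {
  if (!is.null(pcs)) pcs <- as.matrix(pcs)
  ok <- !is.na(y) & !is.na(snp)
  if (!is.null(pcs) && ncol(pcs) > 0) ok <- ok & stats::complete.cases(pcs)
  y <- y[ok]; snp <- snp[ok]
  if (!is.null(pcs)) pcs <- pcs[ok, , drop = FALSE]
  n <- length(y)
  p <- 2L + if (is.null(pcs)) 0L else ncol(pcs)
  nm <- c("intercept", "snp",
          if (!is.null(pcs) && ncol(pcs) > 0) colnames(pcs) %||%
            paste0("PC", seq_len(ncol(pcs))))
  base <- structure(list(
    beta = stats::setNames(rep(NA_real_, p), nm),
    se = stats::setNames(rep(NA_real_, p), nm),
    scale = NA_real_, weights = NULL, n_used = n, df = n - p,
    iterations = 0L, converged = FALSE, status = ""),
    class = "sseqtl_rlm")
  fail <- function(status) { base$status <- status; base }
  if (n < p + 2L) return(fail("insufficient_n"))
  if (length(unique(snp)) < 2L) return(fail("constant_snp"))
  X <- cbind(1, snp, pcs)

  fit0 <- ols_qr(X, y)
  if (is.null(fit0)) return(fail("collinear"))
  beta <- fit0$beta
  path <- if (trace) list(beta) else NULL
  scale <- NA_real_
  converged <- FALSE
  iter <- 0L
  y_scale <- stats::median(abs(y - stats::median(y))) + 1e-12
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    scale <- stats::median(abs(r)) * 1.4826
    if (scale <= 1e-10 * y_scale) {
      base$beta <- stats::setNames(beta, nm)
      base$scale <- scale
      base$iterations <- iter
      base$status <- "scale_degenerate"
      if (trace) base$path <- do.call(rbind, path)
      return(base)
    }
    w <- pmin(1, tuning_k * scale / abs(r))
    w[r == 0] <- 1
    sw <- sqrt(w)
    wfit <- ols_qr(X * sw, y * sw)
    if (is.null(wfit)) return(fail("collinear"))
    delta <- max(abs(wfit$beta - beta))
    beta <- wfit$beta
    if (trace) path[[length(path) + 1L]] <- beta
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
  }

  r <- y - drop(X %*% beta)
  u <- r / scale
  psi <- pmax(-tuning_k, pmin(tuning_k, u))
  psip <- as.numeric(abs(u) <= tuning_k)
  m1 <- mean(psip)
  kappa <- 1 + p / n * stats::var(psip) / m1^2
  s2 <- kappa^2 * scale^2 * sum(psi^2) / (n - p) / m1^2
  xtx_inv <- ols_qr(X, y)$xtx_inv
  se <- sqrt(s2 * diag(xtx_inv))

  out <- base
  out$beta <- stats::setNames(beta, nm)
  out$se <- stats::setNames(se, nm)
  out$scale <- scale
  out$weights <- w
  out$iterations <- iter
  out$converged <- converged
  out$status <- if (converged) "ok" else "not_converged"
  if (trace) out$path <- do.call(rbind, path)
  out
}

#' Robust Wald test of a coefficient in a Huber regression fit
#'
#' Tests a single coefficient of a [fit_rlm_huber()] fit with the Wald
#' statistic \eqn{t = \hat\beta / \widehat{se}_{robust}(\hat\beta)}, referred
#' two-sided to a t distribution with `n_used - p` degrees of freedom. By
#' default the genotype slope (coefficient 2) is tested.
#'
#' @param fit A `sseqtl_rlm` object.
#' @param coef_index Index or name of the tested coefficient (default
#'   `"snp"`).
#' @return List: `statistic`, `df`, `p` (two-sided). Errors when the fit did
#'   not converge or has a degenerate scale — such fits carry no valid test.
#' @export
robust_wald_test <- function(fit, coef_index = "snp") {
  stopifnot(inherits(fit, "sseqtl_rlm"))
  if (fit$status == "scale_degenerate")
    stop("robust Wald test undefined: degenerate scale (exact fit)",
         call. = FALSE)
  if (fit$status != "ok")
    stop("robust Wald test requires a converged fit (status: ", fit$status,
         ")", call. = FALSE)
  b <- fit$beta[[coef_index]]
  s <- fit$se[[coef_index]]
  stat <- b / s
  list(statistic = stat, df = fit$df,
       p = 2 * stats::pt(-abs(stat), fit$df))
}

#' Run stage-2 sex-stratified robust validation of stage-1 candidates
#'
#' For each stage-1 candidate pair: apply the genotype-by-sex block filter,
#' fit the sex-stratified Huber regression separately in males and females,
#' and test the genotype slope with the robust Wald test. All stratum
#' p-values are then screened jointly with Benjamini-Hochberg at level `q`
#' (default pooling: both strata of all candidates in one BH run; set
#' `pool = "per_stratum"` to screen males and females separately). A pair is
#' called a ss-eQTL when the p-value for the genotype slope passes the
#' stage-2 threshold in either sex, or both ("OR" logic). Non-convergent or
#' degenerate robust fits are treated as QC failures for that stratum, with
#' a logged count, never as silent p-values.
#'
#' @param candidates Data frame with `variant_id`, `feature_id` columns
#'   (typically `run_stage1(...)$candidates`).
#' @param dataset The same dataset given to [run_stage1()].
#' @param q Stage-2 FDR level (default 0.05).
#' @param min_block Minimum genotype-by-sex block count (default 5).
#' @param pool `"pooled"` or `"per_stratum"` BH pooling.
#' @param tuning_k,max_iter,tol Passed to [fit_rlm_huber()].
#' @return List of class `sseqtl_stage2`: `results` (one row per candidate:
#'   per-sex slope, robust SE, Wald p, QC flag and reasons, significance and
#'   `which_stratum`), `calls` (the significant subset, ordered by
#'   chromosome, position, feature), and `screen` (pooled) or `screens`
#'   (per-stratum).
#' @export
run_stage2 <- function(candidates, dataset, q = 0.05, min_block = 5,
                       pool = c("pooled", "per_stratum"),
                       tuning_k = 1.345, max_iter = 50L, tol = 1e-8) {
  pool <- match.arg(pool)
  assert_prob(q, "q")
  geno <- dataset$genotypes
  samples <- dataset$samples
  expr <- if (inherits(dataset$expression, "sseqtl_expression"))
    dataset$expression$values else dataset$expression
  empty <- data.frame(
    variant_id = character(0), feature_id = character(0), chrom = character(0),
    pos = integer(0), qc_pass = logical(0), qc_reason = character(0),
    beta1_male = numeric(0), se_male = numeric(0), p_male = numeric(0),
    beta1_female = numeric(0), se_female = numeric(0), p_female = numeric(0),
    significant = logical(0), which_stratum = character(0),
    stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0)
    return(structure(list(results = empty, calls = empty, screen = NULL),
                     class = "sseqtl_stage2"))

  vi <- match(candidates$variant_id, geno$variants$variant_id)
  fi <- match(candidates$feature_id, rownames(expr))
  if (anyNA(vi) || anyNA(fi))
    stop("candidates reference unknown variant or feature ids", call. = FALSE)
  sex <- samples$sex
  pc_cols <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  pcs <- if (length(pc_cols)) as.matrix(samples[, pc_cols, drop = FALSE]) else NULL
  male <- sex == 0
  female <- sex == 1
  nc <- nrow(candidates)

  res <- data.frame(
    variant_id = candidates$variant_id, feature_id = candidates$feature_id,
    chrom = geno$variants$chrom[vi], pos = geno$variants$pos[vi],
    qc_pass = FALSE, qc_reason = "",
    beta1_male = NA_real_, se_male = NA_real_, p_male = NA_real_,
    beta1_female = NA_real_, se_female = NA_real_, p_female = NA_real_,
    significant = FALSE, which_stratum = NA_character_,
    stringsAsFactors = FALSE)
  n_unconverged <- 0L

  fit_stratum <- function(idx, j, f) {
    fit <- fit_rlm_huber(expr[f, idx], geno$dosage[j, idx],
                         if (is.null(pcs)) NULL else pcs[idx, , drop = FALSE],
                         tuning_k = tuning_k, max_iter = max_iter, tol = tol)
    if (fit$status != "ok") return(list(fit = fit, p = NA_real_))
    list(fit = fit, p = robust_wald_test(fit)$p)
  }

  for (i in seq_len(nc)) {
    dos <- geno$dosage[vi[i], ]
    qc <- qc_block_filter(dos, sex, min_count = min_block,
                          is_x = geno$variants$is_x[vi[i]])
    if (!qc$pass) {
      res$qc_reason[i] <- paste(qc$reasons, collapse = "; ")
      next
    }
    res$qc_pass[i] <- TRUE
    m <- fit_stratum(male, vi[i], fi[i])
    f <- fit_stratum(female, vi[i], fi[i])
    if (m$fit$status %in% c("not_converged", "scale_degenerate") ||
        f$fit$status %in% c("not_converged", "scale_degenerate"))
      n_unconverged <- n_unconverged + 1L
    res$beta1_male[i] <- m$fit$beta[["snp"]]
    res$se_male[i] <- m$fit$se[["snp"]]
    res$p_male[i] <- m$p
    res$beta1_female[i] <- f$fit$beta[["snp"]]
    res$se_female[i] <- f$fit$se[["snp"]]
    res$p_female[i] <- f$p
  }

  if (pool == "pooled") {
    pv <- c(res$p_male, res$p_female)
    if (all(is.na(pv))) {
      screen <- NULL
      thr <- NA_real_
    } else {
      screen <- bh_threshold(pv, q = q)
      thr <- screen$p_threshold
    }
    pass_m <- !is.na(res$p_male) & !is.na(thr) & res$p_male <= thr
    pass_f <- !is.na(res$p_female) & !is.na(thr) & res$p_female <= thr
    screens <- NULL
  } else {
    sm <- if (all(is.na(res$p_male))) NULL else bh_threshold(res$p_male, q = q)
    sf <- if (all(is.na(res$p_female))) NULL else bh_threshold(res$p_female, q = q)
    thr_m <- if (is.null(sm)) NA_real_ else sm$p_threshold
    thr_f <- if (is.null(sf)) NA_real_ else sf$p_threshold
    pass_m <- !is.na(res$p_male) & !is.na(thr_m) & res$p_male <= thr_m
    pass_f <- !is.na(res$p_female) & !is.na(thr_f) & res$p_female <= thr_f
    screen <- NULL
    screens <- list(male = sm, female = sf)
  }
  res$significant <- pass_m | pass_f
  res$which_stratum[pass_m & pass_f] <- "both"
  res$which_stratum[pass_m & !pass_f] <- "male"
  res$which_stratum[!pass_m & pass_f] <- "female"

  ord <- order(res$chrom, res$pos, res$feature_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  calls <- res[res$significant, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(results = res, calls = calls, screen = screen,
                 screens = screens, n_unconverged = n_unconverged),
            class = "sseqtl_stage2")
}

#' @export
print.sseqtl_stage2 <- function(x, ...) {
  cat(sprintf("stage-2 robust validation: %d candidates, %d passed QC, %d called\n",
              nrow(x$results), sum(x$results$qc_pass), nrow(x$calls)))
  if (!is.null(x$screen)) print(x$screen)
  invisible(x)
}
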