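# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed fans out into
# independent streams (genotypes, samples, expression, per-variant draws)
# so that regenerating any component, or a subset of variants, reproduces
# the same values. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + k * 16807) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash of a string (mod 2^31 - 1); used to stamp output
# tables with a config fingerprint so runs are attributable without heavy
# dependencies. Not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# QR least squares with pivot handling. Returns NULL on rank deficiency;
# otherwise beta, rss and the unscaled coefficient covariance (X'X)^{-1},
# all in the original column order.
ols_qr <- function(X, y) {
  p <- ncol(X)
  fit <- .lm.fit(X, y)
  if (fit$rank < p) return(NULL)
  piv <- fit$pivot
  R <- fit$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  v <- chol2inv(R)
  beta <- numeric(p)
  beta[piv] <- fit$coefficients
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[piv, piv] <- v
  list(beta = beta, rss = sum(fit$residuals^2), xtx_inv = xtx_inv,
       residuals = fit$residuals)
}

assert_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo || !hi)
    stop(sprintf("`%s` must be a single value in %s0, 1%s, got %s",
                 name, if (open_left) "(" else "[",
                 if (open_right) ")" else "]",
                 format(x)), call. = FALSE)
  invisible(x)
}
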