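#' Linkage-disequilibrium r-squared between two dosage vectors
#'
#' Composite LD: the squared Pearson correlation of unphased alternate-allele
#' dosages over the samples where both are non-missing. Invariant to ref/alt
#' relabeling (sign of the correlation is squared away).
#'
#' @param dosage_a,dosage_b Numeric dosage vectors over the same samples.
#' @return r-squared in [0, 1]. Errors when either vector is constant over
#'   the shared complete cases (LD undefined) or fewer than two complete
#'   pairs remain.
#' @export
#' @examples
#' ld_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))  # 1: perfect (anti)correlation
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) stop("fewer than two complete dosage pairs", call. = FALSE)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined for a constant dosage vector", call. = FALSE)
  stats::cor(a, b)^2
}

#' Annotate ss-eQTL calls against a trait-association catalog
#'
#' Reports, for each called variant, every catalog variant that (i) lies
#' within `window` bp on the same chromosome, (ii) is in high LD with the
#' call (`r2 > r2_min`, strict), and (iii) has a nominal trait association
#' stronger than `p_max` (`p < p_max`, strict). A call variant that is
#' itself in the catalog co-localizes with itself (r2 = 1). Catalog variants
#' absent from the genotype matrix cannot contribute an LD value and are
#' skipped, with a tally in the `"n_skipped"` attribute.
#'
#' @param calls Character vector of called variant ids, or a data frame with
#'   a `variant_id` column (e.g. `run_stage2(...)$calls`).
#' @param genotypes A `sseqtl_genotypes` object holding dosages for both the
#'   calls and the catalog variants.
#' @param catalog Data frame with columns `snp_id`, `trait`, `p` (nominal
#'   association p-value in (0, 1]) and optionally `source`.
#' @param r2_min LD threshold, strict lower bound (default 0.8).
#' @param p_max Catalog p-value threshold, strict upper bound (default 0.05).
#' @param window Max distance in bp between call and catalog variant
#'   (default 1 Mb).
#' @return Data frame with one row per (call, catalog entry) pair passing
#'   both thresholds: `variant_id`, `catalog_snp`, `r2`, `trait`,
#'   `catalog_p`, `source`; deterministically ordered. Empty catalog or no
#'   passing pair yields an empty data frame.
#' @export
annotate_with_catalog <- function(calls, genotypes, catalog,
                                  r2_min = 0.8, p_max = 0.05, window = 1e6) {
  stopifnot(inherits(genotypes, "sseqtl_genotypes"))
  if (is.data.frame(calls)) calls <- calls$variant_id
  calls <- unique(as.character(calls))
  out0 <- data.frame(variant_id = character(0), catalog_snp = character(0),
                     r2 = numeric(0), trait = character(0),
                     catalog_p = numeric(0), source = character(0),
                     stringsAsFactors = FALSE)
  if (is.null(catalog) || nrow(catalog) == 0 || length(calls) == 0)
    return(out0)
  if (!all(c("snp_id", "trait", "p") %in% names(catalog)))
    stop("catalog must have `snp_id`, `trait`, `p` columns", call. = FALSE)
  if (any(catalog$p <= 0 | catalog$p > 1, na.rm = TRUE))
    stop("catalog p-values must lie in (0, 1]", call. = FALSE)
  if (is.null(catalog$source)) catalog$source <- NA_character_

  v <- genotypes$variants
  miss_call <- setdiff(calls, v$variant_id)
  if (length(miss_call))
    stop("called variants absent from genotypes: ",
         paste(miss_call, collapse = ", "), call. = FALSE)
  in_geno <- catalog$snp_id %in% v$variant_id
  n_skipped <- sum(!in_geno)
  catalog <- catalog[in_geno, , drop = FALSE]

  rows <- list()
  for (cv in sort(calls)) {
    ci <- match(cv, v$variant_id)
    cand <- catalog[catalog$p < p_max, , drop = FALSE]
    if (nrow(cand) == 0) next
    ki <- match(cand$snp_id, v$variant_id)
    near <- v$chrom[ki] == v$chrom[ci] & abs(v$pos[ki] - v$pos[ci]) <= window
    cand <- cand[near, , drop = FALSE]
    ki <- ki[near]
    for (j in seq_len(nrow(cand))) {
      r2 <- tryCatch(ld_r2(genotypes$dosage[ci, ], genotypes$dosage[ki[j], ]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_min)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = cv, catalog_snp = cand$snp_id[j], r2 = r2,
          trait = cand$trait[j], catalog_p = cand$p[j],
          source = cand$source[j], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else out0
  out <- out[order(out$variant_id, out$catalog_snp, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
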