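#' Read a genotype dosage matrix from a VCF file
#'
#' Reads biallelic SNP records from a VCF (via \pkg{vcfR}), converts GT calls
#' to alternate-allele dosages (0/1/2, `NA` for missing), and optionally
#' applies the X-chromosome hemizygous coding for males. Multi-allelic
#' records and non-SNP records (indels, MNPs) are dropped and counted in the
#' filter log attached as attribute `"filter_log"`.
#'
#' On X-flagged chromosomes, when `sex` is supplied, male calls are recoded:
#' hemizygous or homozygous alternate becomes dosage 2, reference stays 0,
#' and a diploid heterozygous male call — a genotyping artifact on the
#' non-pseudoautosomal X — is set missing with a logged count.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped).
#' @param samples Optional character vector of sample ids to keep, in the
#'   desired order. Ids absent from the file raise an error naming them.
#' @param sex Optional integer vector (0 male / 1 female) aligned with
#'   `samples` (or with the file's sample order if `samples` is `NULL`);
#'   required to recode male X genotypes.
#' @param x_chroms Chromosome names treated as X (default `c("X", "chrX")`).
#' @return A `sseqtl_genotypes` object (see [simulate_genotypes()]), with a
#'   `"filter_log"` attribute listing record and call counts dropped at each
#'   rule.
#' @export
read_genotypes <- function(vcf_path, samples = NULL, sex = NULL,
                           x_chroms = c("X", "chrX")) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF ", vcf_path, ": ",
                             conditionMessage(e), call. = FALSE))
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm)))   # single-record files drop to a named vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n_input <- nrow(fix)
  if (n_input == 0) stop("VCF contains no variant records", call. = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- !multi & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- which(snp)
  if (!length(keep)) stop("no biallelic SNP records left after filtering",
                          call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  if (!is.null(samples)) {
    absent <- setdiff(samples, colnames(gt))
    if (length(absent))
      stop("samples absent from VCF: ", paste(absent, collapse = ", "),
           call. = FALSE)
    gt <- gt[, samples, drop = FALSE]
  }
  if (!is.null(sex) && length(sex) != ncol(gt))
    stop("`sex` length does not match the number of samples", call. = FALSE)

  # Map each distinct GT string once: alt-allele count and heterozygosity.
  u <- unique(as.vector(gt))
  alleles <- strsplit(u, "[/|]")
  cnt <- vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | a == "" | is.na(a))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  het <- vapply(alleles, function(a)
    length(a) == 2L && sum(a == "1") == 1L, logical(1))
  cnt[is.na(u)] <- NA_integer_
  het[is.na(u)] <- FALSE
  idx <- match(gt, u)
  dosage <- matrix(cnt[idx], nrow = nrow(gt), dimnames = dimnames(gt))
  hetm <- matrix(het[idx], nrow = nrow(gt))

  is_x <- fix$CHROM %in% x_chroms
  n_male_het <- 0L
  if (any(is_x) && !is.null(sex)) {
    male <- which(sex == 0)
    for (j in which(is_x)) {
      bad <- male[hetm[j, male]]
      n_male_het <- n_male_het + length(bad)
      dosage[j, bad] <- NA_integer_
      # hemizygous alt (count 1, haploid) and hom alt both code to 2
      carriers <- male[!is.na(dosage[j, male]) & dosage[j, male] > 0]
      dosage[j, carriers] <- 2L
    }
  }

  pos <- as.integer(fix$POS)
  variant_id <- fix$ID
  noid <- is.na(variant_id) | variant_id == "." | variant_id == ""
  variant_id[noid] <- paste0(fix$CHROM[noid], ":", pos[noid])
  variants <- data.frame(
    variant_id = variant_id, chrom = fix$CHROM, pos = pos,
    ref = fix$REF, alt = fix$ALT, is_x = is_x,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rownames(dosage) <- variant_id
  out <- structure(list(dosage = dosage, variants = variants),
                   class = "sseqtl_genotypes")
  attr(out, "filter_log") <- list(
    n_input = n_input,
    n_multiallelic = sum(multi),
    n_non_snp = sum(!snp & !multi),
    n_retained = nrow(variants),
    n_male_het_x_set_missing = n_male_het
  )
  out
}

#' Write genotypes to a plain-text VCF
#'
#' Minimal VCFv4.2 writer (GT field only) so simulated datasets can round-trip
#' through [read_genotypes()] and serve as fixtures for file-based runs. On
#' X-flagged variants, male samples are written as haploid calls (`0` or `1`,
#' from the 0/2 hemizygous dosage); everything else is written as unphased
#' diploid genotypes. Missing dosages become `./.`.
#'
#' @param genotypes A `sseqtl_genotypes` object.
#' @param path Output file path (plain text).
#' @param sex Optional 0/1 vector aligned with the sample columns; required
#'   to write haploid male calls on X.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, sex = NULL) {
  stopifnot(inherits(genotypes, "sseqtl_genotypes"))
  v <- genotypes$variants
  d <- genotypes$dosage
  samp <- colnames(d)
  gt_auto <- c("0/0", "0/1", "1/1")
  lines <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    dos <- d[j, ]
    if (isTRUE(v$is_x[j]) && !is.null(sex)) {
      g <- character(length(dos))
      male <- sex == 0
      g[male] <- ifelse(is.na(dos[male]), ".", ifelse(dos[male] >= 2, "1", "0"))
      g[!male] <- ifelse(is.na(dos[!male]), "./.", gt_auto[dos[!male] + 1L])
    } else {
      g <- ifelse(is.na(dos), "./.", gt_auto[dos + 1L])
    }
    lines[j] <- paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                        v$alt[j], ".", "PASS", ".", "GT", g),
                      collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a full synthetic dataset to disk as plain-text files
#'
#' Fixture factory: emits `genotypes.vcf`, `expression.tsv` (features x
#' samples), `samples.tsv`, `features.tsv` (anchor table) and `truth.tsv`
#' into `dir`, in the formats the readers of this package consume.
#'
#' @param dataset A `sseqtl_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sseqtl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    features = file.path(dir, "features.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(dataset$genotypes, paths["genotypes"], sex = dataset$samples$sex)
  expr <- data.frame(feature_id = rownames(dataset$expression$values),
                     dataset$expression$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$expression$features, paths["features"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a normalized expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids (any
#' column name). Values must be numeric; the expression is assumed already
#' normalized (no transformation is applied).
#'
#' @param path TSV file path.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids in ", path, call. = FALSE)
  m
}

#' Read the sample metadata table from TSV
#'
#' Requires columns `sample_id` and `sex` (coded 0 = male, 1 = female); any
#' columns named `PC1`, `PC2`, ... are taken as population-structure
#' covariates.
#'
#' @param path TSV file path.
#' @return A `sseqtl_samples` data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(df)))
    stop("sample table must have `sample_id` and `sex` columns", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!all(df$sex %in% c(0L, 1L)))
    stop("`sex` must be coded 0 (male) / 1 (female)", call. = FALSE)
  pc <- grep("^PC[0-9]+$", names(df), value = TRUE)
  df <- df[, c("sample_id", "sex", pc)]
  class(df) <- c("sseqtl_samples", "data.frame")
  df
}

#' Read feature anchors (TSS or miRNA locus positions)
#'
#' Accepts a TSV with columns `feature_id`, `chrom`, `start` and optionally
#' `end` and `strand`, or a GFF3/BED file (parsed with \pkg{rtracklayer} when
#' available; BED 0-based half-open coordinates are converted to 1-based on
#' read). The anchor is the transcription start: the `start` coordinate on
#' the + strand, the `end` coordinate on the - strand. When the strand is
#' unknown the start coordinate is used and a warning is emitted.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"gff3"` or `"bed"`.
#' @return Data frame with `feature_id`, `chrom`, `anchor`, `strand`.
#' @export
read_features <- function(path, format = c("auto", "tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed", "tsv")
  }
  if (format %in% c("gff3", "bed")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading ", format, " requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED")
    grd <- as.data.frame(gr)  # rtracklayer yields 1-based coords for BED too
    id <- if (!is.null(grd$ID)) as.character(grd$ID)
      else if (!is.null(grd$name)) as.character(grd$name)
      else paste0("feature", seq_len(nrow(grd)))
    df <- data.frame(
      feature_id = id,
      chrom = as.character(grd$seqnames),
      start = grd$start, end = grd$end,
      strand = as.character(grd$strand),
      stringsAsFactors = FALSE
    )
    df$strand[df$strand == "*"] <- "unknown"
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if ("anchor" %in% names(df)) {      # pre-resolved anchors (own format)
      if (!all(c("feature_id", "chrom") %in% names(df)))
        stop("feature TSV must have `feature_id`, `chrom` columns", call. = FALSE)
      if (is.null(df$strand)) df$strand <- "unknown"
      df$start <- df$end <- df$anchor
    } else if (!all(c("feature_id", "chrom", "start") %in% names(df))) {
      stop("feature TSV must have `feature_id`, `chrom` and `start` ",
           "(or `anchor`) columns", call. = FALSE)
    } else {
      if (is.null(df$end)) df$end <- df$start
      if (is.null(df$strand)) df$strand <- "unknown"
    }
  }
  feature_anchor(df)
}

# Strand-aware anchor: TSS = start on +, end on -; unknown falls back to
# start with a warning (single warning per call).
feature_anchor <- function(df) {
  strand <- as.character(df$strand)
  strand[!strand %in% c("+", "-")] <- "unknown"
  if (any(strand == "unknown") && !all(df$start == df$end))
    warning(sum(strand == "unknown"),
            " feature(s) with unknown strand: using the start coordinate as anchor")
  anchor <- ifelse(strand == "-", df$end, df$start)
  if (any(anchor < 1)) stop("feature anchors must be 1-based (>= 1)", call. = FALSE)
  data.frame(feature_id = as.character(df$feature_id),
             chrom = as.character(df$chrom),
             anchor = as.integer(anchor), strand = strand,
             stringsAsFactors = FALSE)
}

#' Folded minor allele frequency of a dosage vector
#'
#' Autosomes: alternate-allele frequency is the dosage sum over twice the
#' number of non-missing samples. X chromosome (hemizygous 0/2 male coding):
#' males contribute one allele each (dosage / 2) and females two, and the
#' denominator counts one allele per male and two per female. The returned
#' frequency is folded to the minor allele (\eqn{\le 0.5}), making it
#' invariant to ref/alt relabeling.
#'
#' @param dosages Numeric vector of dosages (`NA` = missing).
#' @param sex 0/1 vector aligned with `dosages`; required when `is_x`.
#' @param is_x Logical: use X-chromosome allele counting.
#' @return Folded minor allele frequency in [0, 0.5].
#' @export
#' @examples
#' compute_maf(c(0, 1, 2, 2))                       # 0.375
#' compute_maf(c(0, 2, 2, 1, 2), sex = c(0, 0, 0, 1, 1), is_x = TRUE)  # 2/7
compute_maf <- function(dosages, sex = NULL, is_x = FALSE) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("MAF undefined: all dosages missing", call. = FALSE)
  if (is_x) {
    if (is.null(sex)) stop("`sex` is required for X-chromosome MAF", call. = FALSE)
    male <- sex == 0 & ok
    female <- sex == 1 & ok
    alt <- sum(dosages[male]) / 2 + sum(dosages[female])
    total <- sum(male) + 2 * sum(female)
  } else {
    alt <- sum(dosages[ok])
    total <- 2 * sum(ok)
  }
  af <- alt / total
  min(af, 1 - af)
}

#' Hemizygous X-chromosome dosage coding
#'
#' Recodes raw male allele counts on the X chromosome to the 0/2 dosage
#' convention (hemizygous alternate counts as two dosage units, reflecting a
#' single expressed copy against X inactivation in females); female dosages
#' pass through unchanged. A male flagged heterozygous — impossible on the
#' non-pseudoautosomal X, so a genotyping artifact — is set missing with a
#' warning.
#'
#' @param raw_alt_count Integer vector of raw alternate-allele counts
#'   (males in \{0, 1\}, females in \{0, 1, 2\}).
#' @param sex 0/1 vector aligned with `raw_alt_count`.
#' @param het Optional logical vector marking diploid heterozygous calls;
#'   male `TRUE` entries are set to `NA`.
#' @return Integer dosage vector: males in \{0, 2, NA\}, females unchanged.
#' @export
#' @examples
#' encode_x_dosage(c(0, 1, 0, 1, 2), sex = c(0, 0, 1, 1, 1))
encode_x_dosage <- function(raw_alt_count, sex, het = NULL) {
  stopifnot(length(raw_alt_count) == length(sex))
  male <- !is.na(raw_alt_count) & sex == 0
  bad <- raw_alt_count[male] %in% c(0L, 1L)
  if (!all(bad))
    stop("male raw X allele counts must be 0 or 1 (hemizygous coding)",
         call. = FALSE)
  out <- as.integer(raw_alt_count)
  out[male] <- out[male] * 2L
  if (!is.null(het)) {
    drop <- male & het
    if (any(drop)) {
      warning(sum(drop), " heterozygous male X call(s) set to missing")
      out[drop] <- NA_integer_
    }
  }
  out
}

#' Enumerate cis variant-feature pairs within a window
#'
#' A variant is paired with a feature when both are on the same chromosome
#' and the distance between the variant position and the feature anchor is
#' at most `window` base pairs (inclusive boundary; default 1 Mb).
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos` (e.g.
#'   `genotypes$variants`).
#' @param features Data frame with `feature_id`, `chrom`, `anchor` (see
#'   [read_features()]).
#' @param window Window half-width in bp (default 1e6).
#' @return Data frame with `variant_id`, `feature_id`, `distance`, ordered by
#'   chromosome, anchor, position. Errors when the two tables share no
#'   chromosome names (e.g. `chr1` vs `1`), rather than silently returning
#'   zero pairs.
#' @export
enumerate_cis_pairs <- function(variants, features, window = 1e6) {
  stopifnot(window > 0)
  if (nrow(variants) == 0 || nrow(features) == 0)
    stop("variant and feature tables must be non-empty", call. = FALSE)
  shared <- intersect(unique(variants$chrom), unique(features$chrom))
  if (!length(shared))
    stop("no shared chromosome names between variants (",
         paste(utils::head(unique(variants$chrom)), collapse = ","),
         ") and features (",
         paste(utils::head(unique(features$chrom)), collapse = ","),
         "); check naming conventions (e.g. 'chr1' vs '1')", call. = FALSE)
  out <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    ch <- shared[i]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    f <- features[features$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    lo <- findInterval(f$anchor - window - 1L, v$pos) + 1L
    hi <- findInterval(f$anchor + window, v$pos)
    n_per <- pmax(hi - lo + 1L, 0L)
    if (sum(n_per) == 0) next
    fidx <- rep(seq_len(nrow(f)), n_per)
    vidx <- unlist(lapply(seq_len(nrow(f)), function(j)
      if (n_per[j] > 0) lo[j]:hi[j] else integer(0)))
    out[[i]] <- data.frame(
      variant_id = v$variant_id[vidx],
      feature_id = f$feature_id[fidx],
      chrom = ch,
      distance = abs(v$pos[vidx] - f$anchor[fidx]),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(variant_id = character(0), feature_id = character(0),
                        chrom = character(0), distance = integer(0))
  rownames(pairs) <- NULL
  pairs
}

#' Per-variant folded MAF for a genotype matrix
#'
#' Applies [compute_maf()] to every variant, using X-chromosome allele
#' counting for X-flagged variants when `sex` is given.
#'
#' @param genotypes A `sseqtl_genotypes` object.
#' @param sex Optional 0/1 vector aligned with the sample columns.
#' @return Named numeric vector of folded MAFs (NA for all-missing variants).
#' @export
maf_by_variant <- function(genotypes, sex = NULL) {
  stopifnot(inherits(genotypes, "sseqtl_genotypes"))
  vapply(seq_len(nrow(genotypes$dosage)), function(j) {
    d <- genotypes$dosage[j, ]
    if (all(is.na(d))) return(NA_real_)
    compute_maf(d, sex = sex, is_x = genotypes$variants$is_x[j])
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(genotypes$variants$variant_id)
}
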