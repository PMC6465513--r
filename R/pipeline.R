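#' Run the full ss-eQTL discovery pipeline
#'
#' Orchestrates the end-to-end analysis: load (or simulate) genotypes,
#' expression and sample metadata; apply the biallelic-SNP and minor allele
#' frequency filters; enumerate cis pairs; stage-1 interaction scan with BH
#' screening; stage-2 sex-stratified robust validation; optional LD
#' annotation against a trait catalog. Writes deterministic TSV tables plus
#' a machine-readable JSON manifest, and returns the same objects invisibly.
#'
#' `config` may be a named list, or a path to a YAML/JSON file with the same
#' fields:
#' \describe{
#'   \item{`vcf`, `expression`, `samples`, `features`}{input file paths
#'     (file mode), see [read_genotypes()], [read_expression()],
#'     [read_samples()], [read_features()];}
#'   \item{`sim`}{alternatively, a list of [sim_config()] arguments
#'     (simulate mode);}
#'   \item{`catalog`}{optional trait-catalog TSV (`snp_id`, `trait`, `p`);}
#'   \item{`window`}{cis window half-width in bp (default 1e6);}
#'   \item{`maf_min`}{MAF filter (default 0.01);}
#'   \item{`q_stage1`, `q_stage2`}{FDR levels (default 0.05 each);}
#'   \item{`min_block`}{genotype-by-sex block minimum (default 5);}
#'   \item{`stage2_pool`}{`"pooled"` (default) or `"per_stratum"`;}
#'   \item{`seed`}{integer seed (simulate mode);}
#'   \item{`out_dir`}{output directory (default `NULL`: nothing written).}
#' }
#'
#' Written outputs: `stage1_results.tsv`, `stage2_results.tsv`, `calls.tsv`,
#' `screen_summary.tsv` (the equivalent p-value thresholds),
#' `filter_log.tsv` (attrition counts per rule), `annotations.tsv` (when a
#' catalog is given) and `manifest.json` (full resolved configuration, seed,
#' package version, counts). Every TSV starts with a header comment naming
#' the package version and the configuration hash, so a table can be traced
#' to its run.
#'
#' @param config Named list or path to a YAML/JSON configuration file.
#' @return Invisibly, a list of class `sseqtl_run`: `stage1`, `stage2`,
#'   `calls`, `annotations`, `filter_log`, `manifest`, `paths`.
#' @export
#' @examples
#' cfg <- list(sim = list(n_variants = 60, n_features = 10, seed = 42),
#'             q_stage1 = 0.05)
#' run <- run_pipeline(cfg)
#' run$manifest$n_pairs
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }

  cfg <- list(
    window = config$window %||% 1e6,
    maf_min = config$maf_min %||% 0.01,
    q_stage1 = config$q_stage1 %||% 0.05,
    q_stage2 = config$q_stage2 %||% 0.05,
    min_block = config$min_block %||% 5,
    stage2_pool = config$stage2_pool %||% "pooled",
    seed = config$seed %||% config$sim$seed %||% 1L,
    out_dir = config$out_dir
  )
  assert_prob(cfg$q_stage1, "q_stage1")
  assert_prob(cfg$q_stage2, "q_stage2")
  assert_prob(cfg$maf_min, "maf_min", open_left = FALSE)
  if (cfg$window <= 0) stop("`window` must be > 0", call. = FALSE)

  # --- load or simulate -----------------------------------------------------
  simulate_mode <- !is.null(config$sim)
  if (simulate_mode) {
    dataset <- with_stage("simulate", {
      sim_args <- config$sim
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      simulate_dataset(do.call(sim_config, sim_args))
    })
    geno <- dataset$genotypes
    samples <- dataset$samples
    features <- dataset$expression$features
    geno_log <- list(n_input = nrow(geno$variants),
                     n_multiallelic = 0L, n_non_snp = 0L,
                     n_retained = nrow(geno$variants),
                     n_male_het_x_set_missing = 0L)
  } else {
    for (f in c("vcf", "expression", "samples", "features"))
      if (is.null(config[[f]]))
        stop("config needs either `sim` or all of `vcf`, `expression`, ",
             "`samples`, `features`", call. = FALSE)
    samples <- with_stage("read_samples", read_samples(config$samples))
    geno <- with_stage("read_genotypes",
                       read_genotypes(config$vcf, samples = samples$sample_id,
                                      sex = samples$sex))
    expr <- with_stage("read_expression", {
      e <- read_expression(config$expression)
      missing <- setdiff(samples$sample_id, colnames(e))
      if (length(missing))
        stop("expression matrix lacks samples: ",
             paste(missing, collapse = ", "))
      e[, samples$sample_id, drop = FALSE]
    })
    features <- with_stage("read_features", read_features(config$features))
    dataset <- list(genotypes = geno, samples = samples, expression = expr)
    geno_log <- attr(geno, "filter_log")
  }

  # --- MAF filter on the analysis samples -----------------------------------
  maf <- with_stage("maf_filter", maf_by_variant(geno, sex = samples$sex))
  keep <- !is.na(maf) & maf >= cfg$maf_min
  n_maf_dropped <- sum(!keep)
  geno$dosage <- geno$dosage[keep, , drop = FALSE]
  geno$variants <- geno$variants[keep, , drop = FALSE]
  dataset$genotypes <- geno

  # --- cis pairs ------------------------------------------------------------
  pairs <- with_stage("cis_pairs",
                      enumerate_cis_pairs(geno$variants, features,
                                          window = cfg$window))
  if (nrow(pairs) == 0)
    stop("[cis_pairs] no variant-feature pair falls inside the cis window",
         call. = FALSE)

  # --- stage 1 --------------------------------------------------------------
  s1 <- with_stage("stage1",
                   run_stage1(dataset, pairs = pairs, q = cfg$q_stage1))

  # --- stage 2 --------------------------------------------------------------
  s2 <- with_stage("stage2",
                   run_stage2(s1$candidates, dataset, q = cfg$q_stage2,
                              min_block = cfg$min_block,
                              pool = cfg$stage2_pool))

  # --- annotation -----------------------------------------------------------
  annotations <- NULL
  if (!is.null(config$catalog)) {
    catalog <- with_stage("annotate",
                          utils::read.delim(config$catalog,
                                            stringsAsFactors = FALSE))
    annotations <- with_stage("annotate",
                              annotate_with_catalog(s2$calls, geno, catalog))
  }

  filter_log <- data.frame(
    rule = c("input_records", "multiallelic_dropped", "non_snp_dropped",
             "male_het_x_set_missing", "maf_below_min_dropped",
             "variants_analyzed", "cis_pairs", "stage1_untestable",
             "stage1_candidates", "stage2_qc_failed", "stage2_unconverged",
             "final_calls"),
    count = c(geno_log$n_input, geno_log$n_multiallelic, geno_log$n_non_snp,
              geno_log$n_male_het_x_set_missing, n_maf_dropped,
              nrow(geno$variants), nrow(pairs), s1$screen$n_excluded,
              nrow(s1$candidates), sum(!s2$results$qc_pass),
              s2$n_unconverged %||% 0L, nrow(s2$calls)),
    stringsAsFactors = FALSE
  )

  resolved <- cfg
  resolved$simulate_mode <- simulate_mode
  resolved$sim <- config$sim
  resolved$inputs <- config[intersect(names(config),
                                      c("vcf", "expression", "samples",
                                        "features", "catalog"))]
  # the hash fingerprints the analysis, not where it is written
  hash <- config_hash(jsonlite::toJSON(resolved[names(resolved) != "out_dir"],
                                       auto_unbox = TRUE, null = "null",
                                       digits = NA))
  manifest <- list(
    package = "sseqtl",
    version = as.character(utils::packageVersion("sseqtl")),
    config = resolved,
    config_hash = hash,
    seed = cfg$seed,
    n_pairs = nrow(pairs),
    stage1_p_threshold = s1$screen$p_threshold,
    stage2_p_threshold = if (!is.null(s2$screen)) s2$screen$p_threshold else NA,
    n_candidates = nrow(s1$candidates),
    n_calls = nrow(s2$calls)
  )

  paths <- NULL
  if (!is.null(cfg$out_dir)) {
    paths <- with_stage("write_outputs", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      stamp <- sprintf("# sseqtl %s config=%s", manifest$version, hash)
      wt <- function(df, name) {
        p <- file.path(cfg$out_dir, name)
        con <- file(p, "w")
        writeLines(stamp, con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
        p
      }
      screen_summary <- data.frame(
        stage = c("stage1", "stage2"),
        q = c(cfg$q_stage1, cfg$q_stage2),
        m = c(s1$screen$m, if (!is.null(s2$screen)) s2$screen$m else NA),
        n_rejected = c(s1$screen$n_rejected,
                       if (!is.null(s2$screen)) s2$screen$n_rejected else NA),
        p_threshold = c(s1$screen$p_threshold, manifest$stage2_p_threshold))
      out <- c(
        stage1_results = wt(s1$results, "stage1_results.tsv"),
        stage2_results = wt(s2$results, "stage2_results.tsv"),
        calls = wt(s2$calls, "calls.tsv"),
        screen_summary = wt(screen_summary, "screen_summary.tsv"),
        filter_log = wt(filter_log, "filter_log.tsv")
      )
      if (!is.null(annotations))
        out["annotations"] <- wt(annotations, "annotations.tsv")
      mp <- file.path(cfg$out_dir, "manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
      c(out, manifest = mp)
    })
  }

  invisible(structure(list(
    stage1 = s1, stage2 = s2, calls = s2$calls, annotations = annotations,
    filter_log = filter_log, manifest = manifest, paths = paths
  ), class = "sseqtl_run"))
}

#' @export
print.sseqtl_run <- function(x, ...) {
  cat("sseqtl pipeline run (config", x$manifest$config_hash, ")\n")
  cat(sprintf("  %d cis pairs -> %d stage-1 candidates -> %d ss-eQTL calls\n",
              x$manifest$n_pairs, x$manifest$n_candidates, x$manifest$n_calls))
  thr <- x$manifest$stage1_p_threshold
  cat(sprintf("  stage-1 equivalent p threshold: %s\n",
              if (is.na(thr)) "none" else format(thr)))
  invisible(x)
}
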