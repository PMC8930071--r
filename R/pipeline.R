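#' Pipeline configuration
#'
#' One object holding every stage threshold, the scenario selector for the
#' simulator (or paths to real inputs), the master seed and the output
#' directory. Round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param scenario simulator scenario (see [scenario_config()]) or `NULL`
#'   when `genotypes`/`phenotypes` paths are given.
#' @param genotypes,phenotypes,regions,known_snps optional input file paths
#'   (dosage TSV, phenotype TSV, region TSV, and a text file of known GWAS
#'   SNP ids).
#' @param seed master seed.
#' @param out_dir output directory for TSVs and the summary (`NULL` = no
#'   files written).
#' @param n_studies,n_cases,n_controls simulated study layout.
#' @param stage1_p loose stage-1 filter (default 1e-2, sized for the small
#'   scanned SNP sets of the simulator; use 1e-8 at genome scale).
#' @param stage2_alpha family-wise rate for the stage-2 Bonferroni bar.
#' @param mds_k MDS components (0 disables ancestry covariates; simulated
#'   cohorts are single-population).
#' @param maf_min screen MAF filter.
#' @param r2_pair,proxy_r2,proxy_p,min_consistent prioritization thresholds.
#' @param window conditioning window half-width in bp.
#' @param region_window susceptibility-region half-width in bp.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(scenario = "tagging", genotypes = NULL,
                            phenotypes = NULL, regions = NULL,
                            known_snps = NULL, seed = 1, out_dir = NULL,
                            n_studies = 3, n_cases = 2000, n_controls = 2000,
                            stage1_p = 1e-2, stage2_alpha = 0.05,
                            mds_k = 0, maf_min = 0.05,
                            r2_pair = 0.2, proxy_r2 = 0.5, proxy_p = 0.05,
                            min_consistent = NULL, window = 200000,
                            region_window = 500000) {
  stopifnot(stage1_p > 0, stage1_p < 1, stage2_alpha > 0, stage2_alpha < 1,
            proxy_p > 0, proxy_p < 1, r2_pair >= 0, r2_pair <= 1,
            proxy_r2 >= 0, proxy_r2 <= 1, window > 0, mds_k >= 0)
  if (is.null(min_consistent)) {
    # the published criterion asks 8 of 10 studies; scale the same fraction
    min_consistent <- max(1, ceiling(0.8 * n_studies))
  }
  structure(list(scenario = scenario, genotypes = genotypes,
                 phenotypes = phenotypes, regions = regions,
                 known_snps = known_snps, seed = as.integer(seed),
                 out_dir = out_dir, n_studies = n_studies, n_cases = n_cases,
                 n_controls = n_controls, stage1_p = stage1_p,
                 stage2_alpha = stage2_alpha, mds_k = mds_k,
                 maf_min = maf_min, r2_pair = r2_pair, proxy_r2 = proxy_r2,
                 proxy_p = proxy_p, min_consistent = min_consistent,
                 window = window, region_window = region_window),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) multi-study cohorts, run the two-stage epistasis scan,
#' prioritize the top pair through the four criteria, run the conditional
#' window scan, and classify the locus as epistasis-consistent,
#' tagging-consistent, null, or inconclusive. When `config$out_dir` is set,
#' every stage writes a TSV and a run summary; identical config and seed
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`: list with `scan`, `criteria`,
#'   `conditional`, `classification`, `evidence`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$scenario)) {
    sim <- scenario_config(config$scenario, seed = config$seed,
                           n_studies = config$n_studies,
                           n_cases = config$n_cases,
                           n_controls = config$n_controls)
    studies <- simulate_cohorts(sim)
  } else {
    gm <- read_dosage_tsv(config$genotypes)
    ph <- read_phenotype_tsv(config$phenotypes)
    studies <- list(study_cohort(gm, ph, name = "study1"))
  }
  known <- character(0)
  if (!is.null(config$known_snps) && file.exists(config$known_snps)) {
    known <- readLines(config$known_snps)
  }
  if (config$mds_k > 0) {
    studies <- lapply(studies, function(s) {
      s$mds <- compute_mds(s$genotypes, k = config$mds_k)
      s
    })
  }
  scan <- epistasis_scan(studies, stage1_p = config$stage1_p,
                         count_encodings = TRUE, alpha = config$stage2_alpha,
                         mds_k = if (config$mds_k > 0) config$mds_k else NULL,
                         maf_min = config$maf_min)
  sig <- significant_pairs(scan)
  merged <- merge_cohorts(studies, mds_k = config$mds_k)
  criteria <- NULL
  conditional <- NULL
  classification <- "null"
  evidence <- "no SNP pair passed the stage-2 Bonferroni threshold"
  if (nrow(sig) > 0) {
    top <- sig[1, ]
    criteria <- prioritize_pair(top, studies, merged,
                                threshold = scan$config$stage2_threshold,
                                min_consistent = config$min_consistent,
                                r2_max = config$r2_pair,
                                proxy_r2 = config$proxy_r2,
                                proxy_p = config$proxy_p,
                                window = config$window, extra_snps = known)
    conditional <- criteria$conditional
    if (!conditional$vacuous && length(conditional$dependent_on) > 0) {
      classification <- "tagging"
      evidence <- paste0("interaction of ", top$snp1, " x ", top$snp2,
                         " is dependent on conditioning variant(s): ",
                         paste(conditional$dependent_on, collapse = ", "))
    } else if (criteria$pass) {
      classification <- "epistasis"
      evidence <- paste0("pair ", top$snp1, " x ", top$snp2,
                         " passes all four criteria; interaction independent",
                         " of every conditioning SNP")
    } else {
      classification <- "inconclusive"
      evidence <- "significant pair failed a non-conditional criterion"
    }
  }
  report <- structure(list(scan = scan, criteria = criteria,
                           conditional = conditional,
                           classification = classification,
                           evidence = evidence, config = config,
                           n_studies = length(studies)),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$scan)
  cat("classification:", toupper(x$classification), "\n")
  cat("evidence:", x$evidence, "\n")
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Emits one TSV per stage (stage-1 meta table, best encodings, stage-2
#' table, conditional results) plus a human-readable `summary.txt` with
#' per-stage counts, criteria verdicts and the final classification with
#' its evidence trail.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  stamp <- sprintf("# episcreen scenario=%s seed=%d",
                   cfg$scenario %||% "file-input", cfg$seed)
  wt <- function(d, f) {
    d <- as.data.frame(d)
    d <- d[!vapply(d, is.list, TRUE)]
    path <- file.path(out_dir, f)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(d, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  scan <- report$scan
  wt(scan$meta, "stage1_meta.tsv")
  wt(scan$best, "stage1_best_encoding.tsv")
  wt(scan$stage2, "stage2_pairs.tsv")
  if (!is.null(report$conditional) && !report$conditional$vacuous) {
    wt(report$conditional$results, "conditional_scan.tsv")
  }
  m <- length(scan$config$variant_ids)
  lines <- c(
    "episcreen pipeline summary",
    sprintf("studies: %d; SNPs scanned: %d; pairs: %d",
            report$n_studies, m, m * (m - 1) / 2),
    sprintf("stage-1 combinations tested: %d", nrow(scan$meta)),
    sprintf("pairs past stage-1 filter (p < %.3g): %d",
            scan$config$stage1_p, nrow(scan$stage2)),
    sprintf("pairs past stage-2 Bonferroni bar (%.4g): %d",
            scan$config$stage2_threshold,
            if (nrow(scan$stage2)) sum(scan$stage2$significant) else 0L))
  if (nrow(scan$stage2) == 0) {
    lines <- c(lines, "no pair passed stage 1: scan is null at these thresholds")
  }
  if (!is.null(report$criteria)) {
    cr <- report$criteria
    lines <- c(lines,
               sprintf("criterion 1 (replication): %s", if (cr$replication$pass) "pass" else "fail"),
               sprintf("criterion 2 (pair LD r2 = %.4g): %s", cr$ld$r_squared,
                       if (cr$ld$pass) "pass" else "fail"),
               sprintf("criterion 3 (proxy support%s): %s",
                       if (cr$proxy$vacuous) ", no proxies" else "",
                       if (cr$proxy$pass) "pass" else "fail"),
               sprintf("criterion 4 (conditional independence): %s",
                       if (cr$conditional$vacuous ||
                             length(cr$conditional$dependent_on) == 0) "pass" else "fail"))
  }
  lines <- c(lines,
             sprintf("classification: %s", report$classification),
             sprintf("evidence: %s", report$evidence))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Classify a simulated locus scenario
#'
#' Convenience wrapper: run the pipeline on one simulated scenario and
#' return only the classification string. Used for the discrimination
#' property of the scan (interaction vs tagging vs null).
#'
#' @param scenario scenario name for [scenario_config()].
#' @param seed master seed.
#' @param ... further arguments to [pipeline_config()].
#' @return one of `"epistasis"`, `"tagging"`, `"null"`, `"inconclusive"`.
#' @export
classify_locus <- function(scenario, seed = 1, ...) {
  run_pipeline(pipeline_config(scenario = scenario, seed = seed, ...))$classification
}
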