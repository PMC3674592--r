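#' Analysis configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]: where the genotype cohorts and the weight table live,
#' which cohort is the reference and which cohorts form the target, the QC
#' thresholds, the minimum cross-cohort MAF correlation required before
#' target cohorts are pooled, and the resampling parameters.
#'
#' The YAML layout mirrors the argument list:
#'
#' ```yaml
#' weights: panel.tsv
#' cohorts:
#'   - {name: UK, path: uk.tsv, dialect: tsv, role: reference}
#'   - {name: Cameroon, path: cameroon.tsv, dialect: tsv, role: target}
#'   - {name: YRI, path: yri.tsv, dialect: tsv, role: target}
#' qc: {sample_max_missing: 0.10, snp_min_callrate: 0.90, hwe_alpha: 0.001}
#' pooling_min_correlation: 0.9
#' B: 1000
#' seed: 1
#' outdir: results
#' ```
#'
#' @param weights Path to the SNP weight table.
#' @param cohorts A list of cohort descriptors, each a list with `name`,
#'   `path`, `dialect` (`"tsv"`/`"plink_text"`, default `"tsv"`) and `role`
#'   (`"reference"` or `"target"`). Exactly one reference is required.
#' @param qc A [qc_thresholds()] object (or a list of its fields).
#' @param pooling_min_correlation Minimum pairwise MAF correlation between
#'   target cohorts' controls for pooling to proceed, in \[0, 1\].
#' @param B Number of reference subsamples for the empirical null.
#' @param seed Integer master seed for all randomness in the run.
#' @param outdir Output directory, or `NULL` to skip writing artifacts.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(weights, cohorts, qc = qc_thresholds(),
                            pooling_min_correlation = 0.9,
                            B = 1000, seed = 1, outdir = NULL) {
  if (is.list(qc) && !inherits(qc, "qc_thresholds")) {
    qc <- do.call(qc_thresholds, qc)
  }
  roles <- vapply(cohorts, function(co) co$role %||% "target", character(1))
  if (sum(roles == "reference") != 1) {
    stop("exactly one cohort must have role 'reference'", call. = FALSE)
  }
  if (!all(roles %in% c("reference", "target"))) {
    stop("cohort roles must be 'reference' or 'target'", call. = FALSE)
  }
  stopifnot(pooling_min_correlation >= 0, pooling_min_correlation <= 1,
            B >= 1)
  structure(list(weights = weights, cohorts = cohorts, qc = qc,
                 pooling_min_correlation = pooling_min_correlation,
                 B = as.integer(B), seed = as.integer(seed),
                 outdir = outdir),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path Path to a YAML configuration file.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p) || grepl("^/", p)) p
    else file.path(base, p)
  }
  cohorts <- lapply(raw$cohorts, function(co) {
    co$path <- resolve(co$path)
    co
  })
  analysis_config(
    weights = resolve(raw$weights), cohorts = cohorts,
    qc = raw$qc %||% qc_thresholds(),
    pooling_min_correlation = raw$pooling_min_correlation %||% 0.9,
    B = raw$B %||% 1000, seed = raw$seed %||% 1,
    outdir = raw$outdir
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the end-to-end transferability analysis
#'
#' Executes the full pipeline: read the weight panel and every cohort,
#' orient genotypes to the risk alleles, apply QC per cohort, restrict all
#' cohorts (and the panel) to the SNPs surviving QC everywhere, compute
#' per-cohort allele frequencies and cross-cohort MAF comparisons (aligned
#' on the reference cohort's minor alleles), pool the target cohorts when
#' their pairwise control MAF correlation reaches
#' `pooling_min_correlation`, compute the GRS and its logistic association
#' in the reference and in the (pooled) target, build the empirical null of
#' reference-subsample odds ratios at the target's size, and summarize the
#' target's empirical p and the between-cohort effect-size ratio.
#'
#' When pooling is refused the target cohorts are analysed separately
#' (cohorts lacking cases or controls are skipped with a note) and the
#' transferability comparison uses the first analysable target.
#'
#' @param config An [analysis_config()], or a path to its YAML file.
#' @return A list of class `analysis_report`; if `config$outdir` is set, all
#'   intermediate tables are also written there as TSV/JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  log_stage <- function(...) message("[grstransfer] ", sprintf(...))

  panel <- read_weights(config$weights)
  log_stage("weights: %d SNPs read from %s", nrow(panel), config$weights)

  names(config$cohorts) <- vapply(config$cohorts, `[[`, character(1), "name")
  raw <- purrr::map(config$cohorts, function(co) {
    g <- read_genotypes(co$path, dialect = co$dialect %||% "tsv")
    g$cohort <- co$name
    log_stage("read %s: %d samples x %d SNPs", co$name,
              dplyr::n_distinct(g$sample_id), dplyr::n_distinct(g$snp_id))
    orient_to_risk_allele(g, panel)
  })

  qc_results <- purrr::map(raw, apply_qc, thresholds = config$qc)
  purrr::iwalk(qc_results, function(qc, name) {
    log_stage("QC %s: %d -> %d samples, %d -> %d SNPs", name,
              qc$n_samples_before, qc$n_samples_after,
              qc$n_snps_before, qc$n_snps_after)
  })
  clean <- purrr::map(qc_results, "genotypes")

  # analysis panel: SNPs surviving QC in every cohort
  common <- purrr::reduce(purrr::map(clean, \(g) unique(g$snp_id)),
                          intersect)
  if (length(common) == 0) stop("no SNPs survive QC in all cohorts",
                                call. = FALSE)
  panel_used <- dplyr::filter(panel, .data$snp_id %in% common)
  clean <- purrr::map(clean, \(g) dplyr::filter(g, .data$snp_id %in% common))
  log_stage("analysis panel: %d SNPs present in all cohorts",
            nrow(panel_used))

  roles <- vapply(config$cohorts, `[[`, character(1), "role")
  ref_name <- names(roles)[roles == "reference"]
  target_names <- names(roles)[roles == "target"]

  freqs <- purrr::map(clean, allele_frequencies)
  ref_ctrl_freq <- allele_frequencies(
    dplyr::filter(clean[[ref_name]], .data$phenotype == "control"))
  ref_ctrl_freq$cohort <- ref_name

  target_ctrl_freqs <- purrr::map(clean[target_names], function(g) {
    allele_frequencies(dplyr::filter(g, .data$phenotype == "control"))
  })
  for (nm in names(target_ctrl_freqs)) target_ctrl_freqs[[nm]]$cohort <- nm

  aligned <- do.call(align_minor_frequencies,
                     c(list(ref_ctrl_freq), unname(target_ctrl_freqs)))

  # pairwise MAF correlations (controls), aligned on reference minor allele
  cohort_cols <- setdiff(names(aligned), c("snp_id", "minor_allele"))
  pairs <- utils::combn(cohort_cols, 2, simplify = FALSE)
  maf_cor <- purrr::map_dfr(pairs, function(pr) {
    ct <- maf_correlation(aligned[[pr[1]]], aligned[[pr[2]]])
    dplyr::mutate(ct,
                  cohort_a = sub("^maf_", "", pr[1]),
                  cohort_b = sub("^maf_", "", pr[2]), .before = 1)
  })

  # pooling decision among target cohorts
  pooled <- NULL
  pooling_ok <- TRUE
  pooling_note <- NULL
  if (length(target_names) > 1) {
    among <- dplyr::filter(maf_cor, .data$cohort_a %in% target_names,
                           .data$cohort_b %in% target_names)
    pooling_ok <- all(among$r >= config$pooling_min_correlation)
    if (pooling_ok) {
      pooled <- pool_cohorts(unname(clean[target_names]))
      log_stage("pooled %s: %d individuals (%d cases, %d controls)",
                paste(target_names, collapse = "+"),
                dplyr::n_distinct(pooled$sample_id),
                sum(sample_info(pooled)$phenotype == "case"),
                sum(sample_info(pooled)$phenotype == "control"))
    } else {
      pooling_note <- sprintf(
        "target cohorts not pooled: pairwise control MAF correlation below %.2f",
        config$pooling_min_correlation)
      warning(pooling_note, call. = FALSE)
    }
  } else if (length(target_names) == 1) {
    pooled <- clean[[target_names]]
  }

  # per-cohort GRS + association
  analysable <- function(g) {
    info <- sample_info(g)
    any(info$phenotype == "case") && any(info$phenotype == "control")
  }
  ref_grs <- compute_grs(clean[[ref_name]], panel_used)
  ref_assoc <- fit_association(ref_grs)
  log_stage("reference association: OR %.3f (%.3f-%.3f), p %.3g",
            ref_assoc$or_value, ref_assoc$ci95[1], ref_assoc$ci95[2],
            ref_assoc$p)

  target_tables <- if (!is.null(pooled)) {
    list(target = pooled)
  } else {
    clean[target_names]
  }
  target_tables <- purrr::keep(target_tables, analysable)
  if (length(target_tables) == 0) {
    stop("no target cohort has both cases and controls", call. = FALSE)
  }
  target_grs <- purrr::map(target_tables, compute_grs, panel = panel_used)
  target_assoc <- purrr::map(target_grs, fit_association)

  first_target <- target_tables[[1]]
  first_assoc <- target_assoc[[1]]
  t_info <- sample_info(first_target)
  n_case_t <- sum(t_info$phenotype == "case")
  n_control_t <- sum(t_info$phenotype == "control")

  null <- null_or_distribution(clean[[ref_name]], panel_used,
                               n_case = n_case_t, n_control = n_control_t,
                               B = config$B, seed = config$seed)
  emp_p <- empirical_p(null, first_assoc$or_value)
  ratio <- effect_size_ratio(ref_assoc$or_value, ref_assoc$ci95,
                             first_assoc$or_value, first_assoc$ci95)
  log_stage("transferability: target OR %.3f, empirical p %.4g, ratio %.2f",
            first_assoc$or_value, emp_p, ratio$ratio)

  report <- structure(list(
    config = config, panel = panel_used, qc = qc_results,
    allele_frequencies = dplyr::bind_rows(
      purrr::imap(freqs, \(f, nm) dplyr::mutate(f, cohort = nm))),
    maf_aligned = aligned, maf_correlations = maf_cor,
    maf_bins = maf_difference_bins(
      aligned[[paste0("maf_", ref_name)]],
      aligned[[cohort_cols[min(2, length(cohort_cols))]]]),
    pooled = pooled, pooling_ok = pooling_ok, pooling_note = pooling_note,
    grs = c(list(reference = ref_grs), target_grs),
    association = c(list(reference = ref_assoc), target_assoc),
    null = null, empirical_p = emp_p, effect_size_ratio = ratio,
    seed = config$seed, timestamp = format(Sys.time(), tz = "UTC")
  ), class = "analysis_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("grstransfer analysis report\n")
  cat("  panel:", nrow(x$panel), "SNPs\n")
  cat("  cohorts:", paste(names(x$qc), collapse = ", "), "\n")
  for (nm in names(x$association)) {
    a <- x$association[[nm]]
    cat(sprintf("  %s: OR %.3f (95%% CI %.3f-%.3f), p %.3g\n", nm,
                a$or_value, a$ci95[1], a$ci95[2], a$p))
  }
  cat(sprintf("  null ORs (B = %d): %.2f-%.2f\n", x$null$B,
              x$null$summary$min, x$null$summary$max))
  cat(sprintf("  empirical p (target vs reference null): %.4g\n",
              x$empirical_p))
  cat(sprintf("  effect-size ratio: %.2f (95%% CI %.2f-%.2f)\n",
              x$effect_size_ratio$ratio, x$effect_size_ratio$conf.low,
              x$effect_size_ratio$conf.high))
  invisible(x)
}

#' @rdname run_pipeline
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return `write_report()` returns `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::iwalk(report$qc, function(qc, nm) {
    write_qc_report(qc, file.path(dir, paste0("qc_", nm)))
  })
  readr::write_tsv(report$allele_frequencies,
                   file.path(dir, "allele_frequencies.tsv"), progress = FALSE)
  readr::write_tsv(report$maf_aligned, file.path(dir, "maf_aligned.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$maf_correlations,
                   file.path(dir, "maf_correlations.tsv"), progress = FALSE)
  purrr::iwalk(report$grs, function(g, nm) {
    readr::write_tsv(g, file.path(dir, paste0("grs_", nm, ".tsv")),
                     progress = FALSE)
  })
  purrr::iwalk(report$association, function(a, nm) {
    write_association(a,
                      path_json = file.path(dir, paste0("assoc_", nm, ".json")),
                      path_tsv = file.path(dir, paste0("assoc_", nm, ".tsv")))
  })
  write_null(report$null,
             path_tsv = file.path(dir, "null_or_samples.tsv"),
             path_json = file.path(dir, "null_summary.json"))
  jsonlite::write_json(
    list(empirical_p = report$empirical_p,
         effect_size_ratio = as.list(report$effect_size_ratio),
         pooling_ok = report$pooling_ok,
         pooling_note = report$pooling_note,
         seed = report$seed, timestamp = report$timestamp),
    file.path(dir, "transferability.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
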