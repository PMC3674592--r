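#' Per-sample genotype missingness
#'
#' @param genotypes A long genotype tibble (see [validate_genotypes()]).
#' @return A tibble with one row per sample: `sample_id`, `n_missing`,
#'   `n_snps`, `f_missing` (fraction of SNPs with a missing call, in
#'   \[0, 1\]).
#' @export
sample_missingness <- function(genotypes) {
  validate_genotypes(genotypes)
  if (dplyr::n_distinct(genotypes$snp_id) < 1) {
    stop("genotype table has no SNPs", call. = FALSE)
  }
  genotypes |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_missing = sum(is.na(.data$dosage)),
                     n_snps = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(f_missing = .data$n_missing / .data$n_snps)
}

#' Per-SNP call rate
#'
#' @inheritParams sample_missingness
#' @return A tibble with one row per SNP: `snp_id`, `n_called`, `n_samples`,
#'   `call_rate` (fraction of samples with a non-missing call).
#' @export
snp_callrate <- function(genotypes) {
  validate_genotypes(genotypes)
  if (dplyr::n_distinct(genotypes$sample_id) < 1) {
    stop("genotype table has no samples", call. = FALSE)
  }
  genotypes |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(n_called = sum(!is.na(.data$dosage)),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(call_rate = .data$n_called / .data$n_samples)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from genotype counts,
#' using the conditional (Levene) distribution of the heterozygote count
#' given the observed allele counts. With `nA` and `na` copies of the two
#' alleles among `n` diploid genotypes, the probability of observing `h`
#' heterozygotes is
#' \deqn{P(h) = \frac{n!\, 2^h\, nA!\, na!}{[(nA-h)/2]!\, h!\, [(na-h)/2]!\, (2n)!}}
#' over all `h` of the same parity as `nA` with `0 <= h <= min(nA, na)`.
#' The returned p-value is the total probability of configurations no more
#' probable than the observed one (a relative tolerance of 1e-12 guards the
#' `<=` comparison against rounding). A monomorphic marker admits a single
#' configuration and so has p = 1.
#'
#' All three arguments are recycled to a common length, so the test can be
#' applied to whole columns of genotype counts at once.
#'
#' @param n_hom1 Count of homozygotes for the first allele.
#' @param n_het Count of heterozygotes.
#' @param n_hom2 Count of homozygotes for the second allele.
#' @return A numeric vector of exact p-values in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1) # 1/3: strong heterozygote deficit at n = 2
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  n <- max(length(n_hom1), length(n_het), length(n_hom2))
  n_hom1 <- rep_len(n_hom1, n)
  n_het <- rep_len(n_het, n)
  n_hom2 <- rep_len(n_hom2, n)
  counts <- cbind(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) < 1)) {
    stop("at least one genotype is required", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    hwe_exact_one(n_hom1[i], n_het[i], n_hom2[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_hom1, n_het, n_hom2) {
  n_a <- 2L * n_hom1 + n_het
  n_b <- 2L * n_hom2 + n_het
  probs <- levene_het_probabilities(n_a, n_b)
  p_obs <- probs$prob[probs$n_het == n_het]
  min(1, sum(probs$prob[probs$prob <= p_obs * (1 + 1e-12)]))
}

#' @rdname hwe_exact_test
#' @param n_a,n_b Counts of the two alleles (`n_a + n_b` must be even and
#'   positive).
#' @return `levene_het_probabilities()` returns a tibble with the attainable
#'   heterozygote counts `n_het` and their conditional probabilities `prob`
#'   (which sum to 1).
#' @export
levene_het_probabilities <- function(n_a, n_b) {
  stopifnot(n_a >= 0, n_b >= 0, (n_a + n_b) %% 2 == 0, n_a + n_b > 0)
  n <- (n_a + n_b) / 2
  h <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  lp <- lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_b - h) / 2) + h * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  tibble::tibble(n_het = as.integer(h), prob = exp(lp))
}

#' Per-SNP genotype counts and exact HWE p-values
#'
#' Tabulates homozygote/heterozygote counts per SNP (optionally in controls
#' only, the default, since a true disease association can distort genotype
#' proportions in cases) and applies [hwe_exact_test()]. SNPs with no called
#' genotype in the selected samples get `p_hwe = NA`.
#'
#' @inheritParams sample_missingness
#' @param controls_only Restrict to `phenotype == "control"` samples.
#' @return A tibble with `snp_id`, `n_hom_counted`, `n_het`, `n_hom_other`,
#'   `p_hwe`.
#' @export
snp_hwe <- function(genotypes, controls_only = TRUE) {
  validate_genotypes(genotypes)
  sel <- if (controls_only) {
    dplyr::filter(genotypes, .data$phenotype == "control")
  } else genotypes
  snps <- unique(genotypes$snp_id)
  counts <- sel |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      n_hom_counted = sum(.data$dosage == 2L, na.rm = TRUE),
      n_het = sum(.data$dosage == 1L, na.rm = TRUE),
      n_hom_other = sum(.data$dosage == 0L, na.rm = TRUE),
      .groups = "drop"
    )
  counts <- tibble::tibble(snp_id = snps) |>
    dplyr::left_join(counts, by = "snp_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                \(x) dplyr::coalesce(x, 0L)))
  n_tot <- counts$n_hom_counted + counts$n_het + counts$n_hom_other
  counts$p_hwe <- NA_real_
  ok <- n_tot > 0
  counts$p_hwe[ok] <- hwe_exact_test(counts$n_hom_counted[ok],
                                     counts$n_het[ok],
                                     counts$n_hom_other[ok])
  counts
}

#' Quality-control thresholds
#'
#' Bundles the three genotype QC filters with their conventional defaults:
#' samples with more than 10% missing genotypes, SNPs with a call rate below
#' 90%, and SNPs out of Hardy-Weinberg equilibrium at p < 0.001 are excluded.
#' Boundaries are strict: a sample at exactly the missingness threshold or a
#' SNP at exactly the call-rate threshold is kept.
#'
#' @param sample_max_missing Maximum tolerated per-sample missing fraction.
#' @param snp_min_callrate Minimum tolerated per-SNP call rate.
#' @param hwe_alpha Significance level of the exact HWE exclusion test.
#' @param hwe_controls_only Compute the HWE test in controls only (default)
#'   or in all samples.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_max_missing = 0.10,
                          snp_min_callrate = 0.90,
                          hwe_alpha = 0.001,
                          hwe_controls_only = TRUE) {
  vals <- c(sample_max_missing, snp_min_callrate, hwe_alpha)
  if (any(!is.finite(vals) | vals < 0 | vals > 1)) {
    stop("QC thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(sample_max_missing = sample_max_missing,
                 snp_min_callrate = snp_min_callrate,
                 hwe_alpha = hwe_alpha,
                 hwe_controls_only = isTRUE(hwe_controls_only)),
            class = "qc_thresholds")
}

#' Apply genotype quality control
#'
#' Three-stage filter, mirroring common PLINK practice:
#'
#' 1. drop samples with missingness strictly above
#'    `thresholds$sample_max_missing`;
#' 2. on the retained samples, drop SNPs with call rate strictly below
#'    `thresholds$snp_min_callrate`;
#' 3. drop SNPs whose exact HWE p-value (computed on retained control
#'    samples by default) is strictly below `thresholds$hwe_alpha`.
#'
#' Samples are filtered first so that SNP call rates depend only on retained
#' samples. Monomorphic SNPs have HWE p = 1 and are never excluded by stage
#' 3. When `hwe_controls_only = TRUE` and the table has no control samples,
#' stage 3 is skipped. Applying QC twice is a no-op: the second report is
#' empty.
#'
#' @inheritParams sample_missingness
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_result` with elements `genotypes` (filtered
#'   tibble), `excluded_samples` and `excluded_snps` (tibbles of
#'   `id`, `reason`, `value`), and before/after counts.
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  validate_genotypes(genotypes)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n_samples_before <- dplyr::n_distinct(genotypes$sample_id)
  n_snps_before <- dplyr::n_distinct(genotypes$snp_id)
  if (n_samples_before == 0 || n_snps_before == 0) {
    stop("genotype table is empty", call. = FALSE)
  }

  miss <- sample_missingness(genotypes)
  bad_samples <- dplyr::filter(miss,
                               .data$f_missing > thresholds$sample_max_missing)
  excluded_samples <- tibble::tibble(
    id = bad_samples$sample_id, reason = "missingness",
    value = bad_samples$f_missing
  )
  kept <- dplyr::filter(genotypes, !.data$sample_id %in% bad_samples$sample_id)
  if (nrow(kept) == 0) {
    stop("QC excluded every sample (missingness filter)", call. = FALSE)
  }

  cr <- snp_callrate(kept)
  bad_cr <- dplyr::filter(cr, .data$call_rate < thresholds$snp_min_callrate)
  excluded_snps <- tibble::tibble(
    id = bad_cr$snp_id, reason = "call_rate", value = bad_cr$call_rate
  )
  kept <- dplyr::filter(kept, !.data$snp_id %in% bad_cr$snp_id)

  if (dplyr::n_distinct(kept$snp_id) > 0) {
    has_controls <- any(kept$phenotype == "control")
    if (!thresholds$hwe_controls_only || has_controls) {
      hwe <- snp_hwe(kept, controls_only = thresholds$hwe_controls_only)
      bad_hwe <- dplyr::filter(hwe, !is.na(.data$p_hwe),
                               .data$p_hwe < thresholds$hwe_alpha)
      excluded_snps <- dplyr::bind_rows(
        excluded_snps,
        tibble::tibble(id = bad_hwe$snp_id, reason = "hwe",
                       value = bad_hwe$p_hwe)
      )
      kept <- dplyr::filter(kept, !.data$snp_id %in% bad_hwe$snp_id)
    }
  }
  if (nrow(kept) == 0 || dplyr::n_distinct(kept$snp_id) == 0) {
    stop("QC excluded every SNP", call. = FALSE)
  }

  structure(list(
    genotypes = kept,
    excluded_samples = excluded_samples,
    excluded_snps = excluded_snps,
    n_samples_before = n_samples_before,
    n_samples_after = dplyr::n_distinct(kept$sample_id),
    n_snps_before = n_snps_before,
    n_snps_after = dplyr::n_distinct(kept$snp_id),
    thresholds = thresholds
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC: ", x$n_samples_before, " -> ", x$n_samples_after,
      " samples; ", x$n_snps_before, " -> ", x$n_snps_after, " SNPs\n",
      sep = "")
  if (nrow(x$excluded_samples) > 0) {
    cat("Excluded samples:\n")
    print(x$excluded_samples)
  }
  if (nrow(x$excluded_snps) > 0) {
    cat("Excluded SNPs:\n")
    print(x$excluded_snps)
  }
  invisible(x)
}

#' @rdname apply_qc
#' @param qc A `qc_result` object.
#' @param dir Directory in which to write `qc_exclusions.tsv` (one row per
#'   excluded entity) and `qc_summary.json`.
#' @return `write_qc_report()` returns `dir`, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  stopifnot(inherits(qc, "qc_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  excl <- dplyr::bind_rows(
    dplyr::mutate(qc$excluded_samples, entity = "sample"),
    dplyr::mutate(qc$excluded_snps, entity = "snp")
  )
  readr::write_tsv(excl, file.path(dir, "qc_exclusions.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(n_samples_before = qc$n_samples_before,
         n_samples_after = qc$n_samples_after,
         n_snps_before = qc$n_snps_before,
         n_snps_after = qc$n_snps_after,
         thresholds = unclass(qc$thresholds)),
    file.path(dir, "qc_summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
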