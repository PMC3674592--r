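#' Group-wise risk-allele frequencies for missing-genotype imputation
#'
#' Missing genotypes are imputed as twice the risk-allele frequency of the
#' sample's own imputation group — cases and controls of the analysis
#' population, computed from the samples with available genotypes. This
#' returns those frequencies: per SNP and per phenotype group present in the
#' table.
#'
#' @param genotypes A genotype tibble oriented to risk alleles (see
#'   [orient_to_risk_allele()]).
#' @return A tibble with `phenotype`, `snp_id`, `freq`, `n_called`.
#' @export
imputation_frequencies <- function(genotypes) {
  validate_genotypes(genotypes)
  out <- genotypes |>
    dplyr::group_by(.data$phenotype, .data$snp_id) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$dosage)),
      freq = ifelse(.data$n_called > 0,
                    sum(.data$dosage, na.rm = TRUE) / (2 * .data$n_called),
                    NA_real_),
      .groups = "drop"
    )
  empty <- out[out$n_called == 0, ]
  if (nrow(empty) > 0) {
    stop("no called genotypes for SNP '", empty$snp_id[1], "' in the '",
         empty$phenotype[1], "' group; imputation frequency undefined",
         call. = FALSE)
  }
  out
}

#' Impute a missing risk-allele count
#'
#' Non-missing genotypes pass through unchanged; a missing genotype is
#' replaced by twice the risk-allele frequency of the sample's imputation
#' group, i.e. its expected risk-allele count.
#'
#' @param genotype Risk-allele counts in `{0, 1, 2, NA}` (vectorized).
#' @param group_freq Risk-allele frequency of the sample's group, in
#'   \[0, 1\] (recycled).
#' @return Numeric vector in \[0, 2\] with no `NA`.
#' @examples
#' impute_missing(c(0, 1, 2, NA), 0.3)
#' @export
impute_missing <- function(genotype, group_freq) {
  if (any(!is.finite(group_freq) | group_freq < 0 | group_freq > 1)) {
    stop("group_freq must lie in [0, 1]", call. = FALSE)
  }
  ifelse(is.na(genotype), 2 * group_freq, genotype)
}

#' Compute the weighted genetic risk score
#'
#' Per-sample score \eqn{GRS = \sum_i w_i \tilde g_i}{GRS = sum_i w_i * g_i}
#' where \eqn{w_i} is the panel's natural-log odds-ratio weight and
#' \eqn{\tilde g_i} the (possibly imputed) risk-allele count at SNP *i*.
#' The genotype table must already be oriented to the panel's risk alleles;
#' missing counts are imputed with [impute_missing()] using frequencies
#' computed within the table's own case/control groups (so a resampled
#' subcohort is scored self-contained).
#'
#' @inheritParams imputation_frequencies
#' @param panel A SNP weight panel (see [read_weights()]); every panel SNP
#'   must be present in the table.
#' @param standardize Divide the score by its sample standard deviation
#'   (off by default; the raw weighted count is the canonical scale).
#' @return A tibble with one row per sample: `sample_id`, `cohort`,
#'   `phenotype`, `grs`, `n_imputed` (count of imputed SNPs).
#' @export
compute_grs <- function(genotypes, panel, standardize = FALSE) {
  ds <- dosage_matrix(genotypes, panel)
  info <- sample_info(
    dplyr::filter(genotypes, .data$snp_id %in% panel$snp_id))
  scores <- numeric(nrow(ds$dosage))
  for (ph in unique(ds$phenotype)) {
    rows <- ds$phenotype == ph
    g <- ds$dosage[rows, , drop = FALSE]
    n_called <- colSums(!is.na(g))
    if (any(n_called == 0)) {
      stop("no called genotypes for SNP '",
           colnames(g)[n_called == 0][1], "' in the '", ph,
           "' group; imputation frequency undefined", call. = FALSE)
    }
    freq <- colSums(g, na.rm = TRUE) / (2 * n_called)
    na_idx <- which(is.na(g))
    if (length(na_idx) > 0) {
      g[na_idx] <- (2 * rep(freq, each = nrow(g)))[na_idx]
    }
    scores[rows] <- as.vector(g %*% ds$weights)
  }
  scored <- tibble::tibble(
    sample_id = info$sample_id, cohort = info$cohort,
    phenotype = info$phenotype, grs = scores,
    n_imputed = as.integer(rowSums(is.na(ds$dosage)))
  )
  if (standardize) {
    s <- stats::sd(scored$grs)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize a constant score", call. = FALSE)
    }
    scored$grs <- scored$grs / s
  }
  scored
}

#' Logistic case-control association of a risk score
#'
#' Maximum-likelihood logistic regression of case status on the score
#' (intercept plus slope). The per-unit-score odds ratio is `exp(slope)`
#' with a 95% Wald confidence interval `exp(slope +/- 1.96 * SE)` and a
#' two-sided Wald p-value; the standard error comes from the observed
#' information. Samples with `phenotype == "unknown"` are dropped. Complete
#' separation and non-convergence raise errors with a diagnostic rather than
#' returning an unstable estimate.
#'
#' @param scores A data frame with a `phenotype` column (`"case"` /
#'   `"control"`) and the score column named by `score_col` — typically the
#'   output of [compute_grs()].
#' @param score_col Name of the score column (default `"grs"`).
#' @return An object of class `grs_assoc`; see [tidy.grs_assoc()] and
#'   [glance.grs_assoc()] for tabular views.
#' @export
fit_association <- function(scores, score_col = "grs") {
  stopifnot(score_col %in% names(scores), "phenotype" %in% names(scores))
  dat <- scores[scores$phenotype %in% c("case", "control"), ]
  y <- as.integer(dat$phenotype == "case")
  x <- dat[[score_col]]
  res <- logistic_score_fit(x, y)
  structure(c(res, list(score_col = score_col)), class = "grs_assoc")
}

#' @export
print.grs_assoc <- function(x, ...) {
  cat(sprintf(
    "GRS-disease logistic association (%d cases, %d controls)\n",
    x$n_case, x$n_control))
  cat(sprintf("  OR per unit %s = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$score_col, x$or_value, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Tidy a fitted GRS association
#'
#' @param x A `grs_assoc` object from [fit_association()].
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble for the score term with
#'   `term`, `estimate` (log-odds per unit score), `std.error`, `statistic`,
#'   `p.value`, `or`, `conf.low`, `conf.high` (OR scale). `glance()` returns
#'   a one-row model summary.
#' @export
tidy.grs_assoc <- function(x, ...) {
  tibble::tibble(
    term = x$score_col, estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$p,
    or = x$or_value, conf.low = x$ci95[1], conf.high = x$ci95[2]
  )
}

#' @rdname tidy.grs_assoc
#' @export
glance.grs_assoc <- function(x, ...) {
  tibble::tibble(
    n_case = x$n_case, n_control = x$n_control,
    or = x$or_value, conf.low = x$ci95[1], conf.high = x$ci95[2],
    p.value = x$p,
    null.deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    AIC = x$fit$aic
  )
}

#' @rdname fit_association
#' @param assoc A `grs_assoc` object.
#' @param path_json,path_tsv Output paths; either may be `NULL` to skip.
#' @return `write_association()` returns `assoc`, invisibly.
#' @export
write_association <- function(assoc, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(assoc, "grs_assoc"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(or = assoc$or_value, ci95_lower = assoc$ci95[1],
           ci95_upper = assoc$ci95[2], p = assoc$p,
           beta = assoc$beta, se = assoc$se,
           n_case = assoc$n_case, n_control = assoc$n_control),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(path_tsv)) {
    readr::write_tsv(glance(assoc), path_tsv, progress = FALSE)
  }
  invisible(assoc)
}
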