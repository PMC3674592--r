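#' Draw a phenotype-stratified random subsample
#'
#' Samples exactly `n_case` cases and `n_control` controls uniformly without
#' replacement, the two strata drawn independently. Used to build the
#' empirical null distribution of subsample odds ratios at the target
#' cohort's size.
#'
#' @inheritParams sample_missingness
#' @param n_case,n_control Numbers of cases and controls to draw.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A genotype tibble with exactly `n_case` cases and `n_control`
#'   controls.
#' @export
draw_subsample <- function(genotypes, n_case, n_control, seed = NULL) {
  info <- sample_info(genotypes)
  cases <- info$sample_id[info$phenotype == "case"]
  controls <- info$sample_id[info$phenotype == "control"]
  if (length(cases) < n_case) {
    stop("requested ", n_case, " cases but only ", length(cases),
         " available", call. = FALSE)
  }
  if (length(controls) < n_control) {
    stop("requested ", n_control, " controls but only ", length(controls),
         " available", call. = FALSE)
  }
  draw <- function() {
    keep <- c(sample(cases, n_case), sample(controls, n_control))
    dplyr::filter(genotypes, .data$sample_id %in% keep)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed for draw b under a master seed; keeps each
# draw stable when B changes. Kept below 2^31.
substream_seed <- function(seed, b) {
  (as.numeric(seed) %% 1e6) * 2048 + (b %% 2048) + 1
}

# One-time conversion of an oriented genotype table to a samples-by-SNPs
# dosage matrix (sample order = order of appearance, SNP order = panel
# order), with phenotype and panel weights. The resampling loop works on
# this representation; score_and_fit_matrix() reproduces
# fit_association(compute_grs(...)) exactly.
dosage_matrix <- function(genotypes, panel) {
  validate_genotypes(genotypes)
  validate_panel(panel)
  absent <- setdiff(panel$snp_id, unique(genotypes$snp_id))
  if (length(absent) > 0) {
    stop("panel SNP(s) absent from genotype table: ",
         paste(utils::head(absent, 3), collapse = ", "), call. = FALSE)
  }
  sel <- dplyr::filter(genotypes, .data$snp_id %in% panel$snp_id)
  unoriented <- sel |>
    snp_alleles() |>
    dplyr::inner_join(dplyr::select(panel, "snp_id", "risk_allele"),
                      by = "snp_id") |>
    dplyr::filter(!is.na(.data$counted_allele),
                  .data$counted_allele != .data$risk_allele)
  if (nrow(unoriented) > 0) {
    stop("genotype table is not oriented to the panel risk allele at SNP '",
         unoriented$snp_id[1], "'; run orient_to_risk_allele() first",
         call. = FALSE)
  }
  info <- sample_info(sel)
  m <- matrix(NA_integer_, nrow = nrow(info), ncol = nrow(panel),
              dimnames = list(info$sample_id, panel$snp_id))
  m[cbind(match(sel$sample_id, info$sample_id),
          match(sel$snp_id, panel$snp_id))] <- sel$dosage
  list(dosage = m, phenotype = info$phenotype, weights = panel$weight)
}

# Group-frequency imputation + weighted score + logistic fit on the matrix
# representation; errors mirror imputation_frequencies()/fit_association().
score_and_fit_matrix <- function(dosage, phenotype, weights) {
  scores <- numeric(nrow(dosage))
  for (ph in unique(phenotype)) {
    rows <- phenotype == ph
    g <- dosage[rows, , drop = FALSE]
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
    scores[rows] <- as.vector(g %*% weights)
  }
  keep <- phenotype %in% c("case", "control")
  logistic_score_fit(scores[keep],
                     as.integer(phenotype[keep] == "case"))
}

# Shared Wald inference for a score-on-disease logistic regression; used by
# fit_association() and the resampling fast path.
logistic_score_fit <- function(x, y) {
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("score contains non-finite values", call. = FALSE)
  if (stats::sd(x) == 0) stop("score is constant", call. = FALSE)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, x = x), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients["x"])
  # observed-information SE from the IRLS weights
  xm <- cbind(1, x)
  xtwx <- crossprod(xm * sqrt(fit$weights))
  se <- sqrt(solve(xtwx)[2, 2])
  if (!fit$converged || (sep_warned && (abs(beta) > 15 || se > 50))) {
    stop("logistic fit failed: complete or quasi-complete separation ",
         "(|slope| = ", signif(abs(beta), 3), ", SE = ", signif(se, 3), ")",
         call. = FALSE)
  }
  z <- beta / se
  list(beta = beta, se = se, or_value = exp(beta),
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(z)),
       n_case = sum(y == 1), n_control = sum(y == 0), fit = fit)
}

#' Empirical null distribution of subsample odds ratios
#'
#' For `b = 1..B`: draw a random subsample of `n_case` cases and `n_control`
#' controls from the reference cohort, recompute the score's imputation
#' frequencies within the subsample, compute the GRS, fit the logistic
#' association and record the odds ratio and p-value. Subsamples where the
#' fit degenerates (separation) are recorded as failures and redrawn, so the
#' distribution always holds exactly `B` usable odds ratios; a failure rate
#' above 20% of `B` aborts with a diagnostic. A master `seed` spawns one
#' substream per draw, so earlier draws are unchanged when `B` grows.
#'
#' @inheritParams draw_subsample
#' @param panel A SNP weight panel (table must be oriented to it).
#' @param B Number of subsamples.
#' @param seed Integer master seed.
#' @return An object of class `resampling_null` with the odds-ratio vector,
#'   per-draw p-values, failure count and a summary (min, max, proportion of
#'   ORs above 1, proportion of p below 0.05).
#' @export
null_or_distribution <- function(genotypes, panel, n_case, n_control,
                                 B = 1000, seed = 1) {
  stopifnot(B >= 1)
  ds <- dosage_matrix(genotypes, panel)
  cases <- which(ds$phenotype == "case")
  controls <- which(ds$phenotype == "control")
  if (length(cases) < n_case) {
    stop("requested ", n_case, " cases but only ", length(cases),
         " available", call. = FALSE)
  }
  if (length(controls) < n_control) {
    stop("requested ", n_control, " controls but only ", length(controls),
         " available", call. = FALSE)
  }
  or_samples <- numeric(B)
  p_samples <- numeric(B)
  n_failures <- 0L
  max_failures <- ceiling(0.2 * B)
  attempt <- 0L
  for (b in seq_len(B)) {
    repeat {
      attempt <- attempt + 1L
      # index-based draw from the same RNG stream as draw_subsample()
      idx <- with_local_seed(substream_seed(seed, attempt),
                             c(sample(cases, n_case),
                               sample(controls, n_control)))
      res <- tryCatch(
        score_and_fit_matrix(ds$dosage[idx, , drop = FALSE],
                             ds$phenotype[idx], ds$weights),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
      n_failures <- n_failures + 1L
      if (n_failures > max_failures) {
        stop("more than 20% of subsample fits failed (", n_failures,
             " failures in ", attempt, " draws); last error: ",
             conditionMessage(res), call. = FALSE)
      }
    }
    or_samples[b] <- res$or_value
    p_samples[b] <- res$p
  }
  structure(list(
    n_case = n_case, n_control = n_control, B = B,
    or_samples = or_samples, p_samples = p_samples,
    seed = seed, n_failures = n_failures,
    summary = list(min = min(or_samples), max = max(or_samples),
                   prop_or_gt1 = mean(or_samples > 1),
                   prop_p_lt05 = mean(p_samples < 0.05))
  ), class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf(
    "Empirical null of %d subsample ORs (%d cases / %d controls each)\n",
    x$B, x$n_case, x$n_control))
  cat(sprintf("  OR range %.2f-%.2f; %.1f%% of ORs > 1; %.1f%% of p < 0.05",
              x$summary$min, x$summary$max, 100 * x$summary$prop_or_gt1,
              100 * x$summary$prop_p_lt05))
  if (x$n_failures > 0) cat(sprintf("; %d redrawn fits", x$n_failures))
  cat("\n")
  invisible(x)
}

#' Tidy a resampling null
#'
#' @param x A `resampling_null` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per draw (`draw`, `or`,
#'   `p.value`); `glance()` a one-row summary.
#' @export
tidy.resampling_null <- function(x, ...) {
  tibble::tibble(draw = seq_len(x$B), or = x$or_samples,
                 p.value = x$p_samples)
}

#' @rdname tidy.resampling_null
#' @export
glance.resampling_null <- function(x, ...) {
  tibble::tibble(
    B = x$B, n_case = x$n_case, n_control = x$n_control,
    or_min = x$summary$min, or_max = x$summary$max,
    prop_or_gt1 = x$summary$prop_or_gt1,
    prop_p_lt05 = x$summary$prop_p_lt05,
    n_failures = x$n_failures, seed = x$seed
  )
}

#' Empirical p-value of a target odds ratio against the null
#'
#' One-sided lower-tail empirical p with the add-one correction:
#' \deqn{p = (\#\{b : OR_b \le OR_{target}\} + 1)/(B + 1)} so the smallest
#' attainable value is `1/(B + 1)` and p is never 0 — a target OR below every
#' null OR at B = 1000 is reported as "< 1/1000". The two-sided option
#' doubles the smaller tail (capped at 1).
#'
#' @param null A `resampling_null` object.
#' @param or_target The target cohort's fitted odds ratio (positive).
#' @param alternative `"less"` (default; the transferability question is
#'   directional) or `"two.sided"`.
#' @return A single p-value in (0, 1\].
#' @export
empirical_p <- function(null, or_target, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(null, "resampling_null"), or_target > 0)
  lower <- (sum(null$or_samples <= or_target) + 1) / (null$B + 1)
  if (alternative == "less") return(lower)
  upper <- (sum(null$or_samples >= or_target) + 1) / (null$B + 1)
  min(1, 2 * min(lower, upper))
}

#' Between-cohort effect-size ratio with a combined-SE confidence interval
#'
#' Summarizes heterogeneity of the score's effect as
#' `ratio = OR_ref / OR_target`. On the log scale each OR's standard error is
#' recovered from its 95% confidence interval as
#' `SE = (ln upper - ln lower) / (2 * 1.96)`, and the ratio's interval is
#' `exp(ln ratio +/- 1.96 * sqrt(SE_ref^2 + SE_target^2))`.
#'
#' @param or_ref,or_target Per-unit-score odds ratios (positive).
#' @param ci_ref,ci_target Length-2 95% confidence intervals bracketing the
#'   respective OR.
#' @return A one-row tibble: `ratio`, `conf.low`, `conf.high`.
#' @examples
#' effect_size_ratio(2.87, c(2.60, 3.17), 0.71, c(0.29, 1.74))
#' @export
effect_size_ratio <- function(or_ref, ci_ref, or_target, ci_target) {
  check_ci <- function(or, ci, what) {
    if (length(ci) != 2 || any(!is.finite(ci)) || any(ci <= 0) ||
        ci[1] > or || ci[2] < or) {
      stop(what, " confidence interval must be positive and bracket its OR",
           call. = FALSE)
    }
  }
  stopifnot(or_ref > 0, or_target > 0)
  check_ci(or_ref, ci_ref, "reference")
  check_ci(or_target, ci_target, "target")
  z <- stats::qnorm(0.975)
  se_ref <- (log(ci_ref[2]) - log(ci_ref[1])) / (2 * z)
  se_target <- (log(ci_target[2]) - log(ci_target[1])) / (2 * z)
  log_ratio <- log(or_ref) - log(or_target)
  half <- z * sqrt(se_ref^2 + se_target^2)
  tibble::tibble(ratio = exp(log_ratio),
                 conf.low = exp(log_ratio - half),
                 conf.high = exp(log_ratio + half))
}

#' @rdname null_or_distribution
#' @param null A `resampling_null` object.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return `write_null()` returns `null` invisibly.
#' @export
write_null <- function(null, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(null, "resampling_null"))
  if (!is.null(path_tsv)) {
    readr::write_tsv(tidy(null), path_tsv, progress = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      c(list(B = null$B, n_case = null$n_case, n_control = null$n_control,
             seed = null$seed, n_failures = null$n_failures), null$summary),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(null)
}

#' Histogram of the empirical null with the target OR marked
#'
#' @param object A `resampling_null` object.
#' @param or_target Optional target-cohort OR drawn as a vertical line.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resampling_null <- function(object, or_target = NULL, bins = 40,
                                     ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$or)) +
    ggplot2::geom_histogram(bins = bins, fill = "goldenrod",
                            colour = "grey30") +
    ggplot2::labs(
      x = sprintf("Subsample OR (%d cases / %d controls, B = %d)",
                  object$n_case, object$n_control, object$B),
      y = "Count"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(or_target)) {
    p <- p + ggplot2::geom_vline(xintercept = or_target, colour = "red",
                                 linewidth = 1)
  }
  p
}

#' Scatter plot of minor allele frequencies between two cohorts
#'
#' @param aligned A tibble from [align_minor_frequencies()] (or any tibble
#'   with the two named frequency columns).
#' @param ref_col,other_col Names of the x and y frequency columns.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_maf_scatter <- function(aligned, ref_col, other_col) {
  stopifnot(ref_col %in% names(aligned), other_col %in% names(aligned))
  ggplot2::ggplot(aligned,
                  ggplot2::aes(x = .data[[ref_col]],
                               y = .data[[other_col]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = ref_col, y = other_col) +
    ggplot2::theme_minimal()
}
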