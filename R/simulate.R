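#' Configure a two-population case-control simulation
#'
#' Describes a synthetic study with the statistical structure the analysis
#' assumes: Hardy-Weinberg genotypes at specified risk-allele frequencies, a
#' logistic disease model additive in the risk-allele counts, case-control
#' ascertainment by rejection sampling, missing-completely-at-random
#' genotype dropout, and (optionally) Balding-Nichols frequency divergence
#' between a large reference population and a small target population.
#'
#' The reference cohort is drawn at `freq_ref` with generative per-SNP
#' log-odds-ratios `weights_gen`; the target cohort at `freq_target` (given
#' explicitly, or drawn from `freq_ref` by [diverge_frequencies()] when
#' `divergence_f > 0`) with `weights_gen_target` (defaults to `weights_gen`;
#' set to zeros for a target population in which the markers carry no
#' effect).
#'
#' @param n_snps Number of independent SNPs.
#' @param freq_ref Reference-population risk-allele frequencies in (0, 1);
#'   default evenly spaced over \[0.05, 0.45\].
#' @param freq_target Target-population frequencies, or `NULL` to derive
#'   them from `freq_ref` (identity when `divergence_f = 0`).
#' @param divergence_f Balding-Nichols divergence parameter F in \[0, 1).
#' @param weights_gen Generative per-SNP log odds ratios (reference).
#' @param weights_gen_target Generative log odds ratios in the target
#'   population (default: same as reference).
#' @param intercept Baseline log-odds of disease.
#' @param n_case,n_control Ascertained counts in the reference cohort.
#' @param n_case_target,n_control_target Ascertained counts in the target
#'   cohort.
#' @param missing_rate MCAR genotype dropout fraction in \[0, 1).
#' @param snp_failure_ids SNP ids forced to total genotyping failure.
#' @param seed Integer master seed for [simulate_study()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 28,
                              freq_ref = NULL,
                              freq_target = NULL,
                              divergence_f = 0,
                              weights_gen = rep(0, n_snps),
                              weights_gen_target = weights_gen,
                              intercept = -4,
                              n_case = 500, n_control = 430,
                              n_case_target = 43, n_control_target = 163,
                              missing_rate = 0,
                              snp_failure_ids = character(),
                              seed = 1) {
  if (is.null(freq_ref)) freq_ref <- seq(0.05, 0.45, length.out = n_snps)
  stopifnot(length(freq_ref) == n_snps,
            length(weights_gen) == n_snps,
            length(weights_gen_target) == n_snps,
            is.null(freq_target) || length(freq_target) == n_snps)
  if (any(freq_ref <= 0 | freq_ref >= 1)) {
    stop("freq_ref must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.null(freq_target) && any(freq_target <= 0 | freq_target >= 1)) {
    stop("freq_target must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(divergence_f >= 0, divergence_f < 1,
            missing_rate >= 0, missing_rate < 1,
            all(is.finite(c(weights_gen, weights_gen_target, intercept))))
  structure(list(
    n_snps = n_snps, freq_ref = freq_ref, freq_target = freq_target,
    divergence_f = divergence_f, weights_gen = weights_gen,
    weights_gen_target = weights_gen_target, intercept = intercept,
    n_case = n_case, n_control = n_control,
    n_case_target = n_case_target, n_control_target = n_control_target,
    missing_rate = missing_rate, snp_failure_ids = snp_failure_ids,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @param config A `simulation_config`.
#' @param weights Analysis weights for the panel (default: the generative
#'   reference weights).
#' @return `simulation_panel()` returns the SNP weight panel matching the
#'   simulated markers (`snp01`, `snp02`, ..., risk allele A, other allele
#'   G).
#' @export
simulation_panel <- function(config, weights = config$weights_gen) {
  stopifnot(length(weights) == config$n_snps)
  tibble::tibble(
    snp_id = simulated_snp_ids(config$n_snps),
    chromosome = as.character(rep_len(1:22, config$n_snps)),
    locus_name = paste0("locus", seq_len(config$n_snps)),
    risk_allele = "A", other_allele = "G",
    weight = weights
  )
}

simulated_snp_ids <- function(n_snps) sprintf("snp%02d", seq_len(n_snps))

#' Simulate Hardy-Weinberg genotypes
#'
#' Risk-allele counts under Hardy-Weinberg equilibrium: independent
#' binomial(2, `freq`) draws.
#'
#' @param n Number of genotypes to draw.
#' @param freq Risk-allele frequency in (0, 1).
#' @return An integer vector of 0/1/2 counts.
#' @export
simulate_genotypes <- function(n, freq) {
  stopifnot(freq > 0, freq < 1)
  stats::rbinom(n, 2L, freq)
}

#' Balding-Nichols frequency divergence
#'
#' Draws a derived population's allele frequencies around an ancestral
#' frequency vector: per SNP a Beta variate with mean `freq_ref` and
#' variance `f_div * freq_ref * (1 - freq_ref)` (shape parameters
#' `freq * (1 - F) / F` and `(1 - freq) * (1 - F) / F`), truncated to
#' (0.001, 0.999). `f_div = 0` returns the input unchanged.
#'
#' @param freq_ref Ancestral frequency vector in (0, 1).
#' @param f_div Divergence parameter F in \[0, 1).
#' @param seed Optional seed for a reproducible draw.
#' @return A frequency vector of the same length.
#' @export
diverge_frequencies <- function(freq_ref, f_div, seed = NULL) {
  stopifnot(f_div >= 0, f_div < 1, all(freq_ref > 0), all(freq_ref < 1))
  if (f_div == 0) return(freq_ref)
  draw <- function() {
    k <- (1 - f_div) / f_div
    out <- stats::rbeta(length(freq_ref), freq_ref * k, (1 - freq_ref) * k)
    pmin(pmax(out, 0.001), 0.999)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Rejection-sampling ascertainment: draw HWE genotype batches, assign case
# status under the logistic model, accumulate until the case and control
# quotas are filled.
ascertain_cohort <- function(freqs, weights, intercept, n_case, n_control,
                             max_draws = 1e7) {
  n_snps <- length(freqs)
  case_rows <- vector("list", 0)
  control_rows <- vector("list", 0)
  got_case <- 0L
  got_control <- 0L
  total <- 0
  batch <- max(1000L, 2L * (n_case + n_control))
  while (got_case < n_case || got_control < n_control) {
    total <- total + batch
    if (total > max_draws) {
      stop("case-control ascertainment needed more than ", max_draws,
           " draws; increase the intercept (baseline disease log-odds) or ",
           "reduce the requested cohort size", call. = FALSE)
    }
    g <- matrix(stats::rbinom(batch * n_snps, 2L,
                              rep(freqs, each = batch)),
                nrow = batch, ncol = n_snps)
    eta <- intercept + as.vector(g %*% weights)
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    if (got_case < n_case) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L), n_case - got_case))]
      if (length(take) > 0) {
        case_rows[[length(case_rows) + 1]] <- g[take, , drop = FALSE]
        got_case <- got_case + length(take)
      }
    }
    if (got_control < n_control) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                         n_control - got_control))]
      if (length(take) > 0) {
        control_rows[[length(control_rows) + 1]] <- g[take, , drop = FALSE]
        got_control <- got_control + length(take)
      }
    }
  }
  list(case = do.call(rbind, case_rows),
       control = do.call(rbind, control_rows))
}

matrix_to_long <- function(g, phenotype, cohort, snp_ids, id_offset = 0L) {
  n <- nrow(g)
  sample_id <- sprintf("%s_%s%04d", cohort, substr(phenotype, 1, 4),
                       seq_len(n) + id_offset)
  tibble::tibble(
    sample_id = rep(sample_id, each = length(snp_ids)),
    phenotype = phenotype, cohort = cohort,
    snp_id = rep(snp_ids, times = n),
    counted_allele = "A", other_allele = "G",
    dosage = as.integer(t(g))
  )
}

#' Simulate one ascertained case-control cohort
#'
#' Individuals are generated by drawing Hardy-Weinberg genotypes at the
#' cohort's frequencies, assigning case status with probability
#' `plogis(intercept + sum(weights_gen * g))`, and retaining draws until the
#' requested numbers of cases and controls are collected. MCAR missingness
#' is then applied at `missing_rate`, and any SNP in `snp_failure_ids` is
#' set fully missing.
#'
#' @param config A [simulation_config()].
#' @param which `"reference"` or `"target"` — selects frequencies, weights
#'   and cohort sizes.
#' @param seed Optional seed for a reproducible draw (when `NULL` the
#'   current RNG stream is used).
#' @param cohort Cohort label (defaults to `which`).
#' @return A long genotype tibble.
#' @export
simulate_cohort <- function(config, which = c("reference", "target"),
                            seed = NULL, cohort = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  which <- match.arg(which)
  if (is.null(cohort)) cohort <- which
  run <- function() {
    if (which == "reference") {
      freqs <- config$freq_ref
      weights <- config$weights_gen
      n_case <- config$n_case
      n_control <- config$n_control
    } else {
      freqs <- config$freq_target
      if (is.null(freqs)) {
        freqs <- diverge_frequencies(config$freq_ref, config$divergence_f)
      }
      weights <- config$weights_gen_target
      n_case <- config$n_case_target
      n_control <- config$n_control_target
    }
    snp_ids <- simulated_snp_ids(config$n_snps)
    drawn <- ascertain_cohort(freqs, weights, config$intercept,
                              n_case, n_control)
    out <- dplyr::bind_rows(
      matrix_to_long(drawn$case, "case", cohort, snp_ids),
      matrix_to_long(drawn$control, "control", cohort, snp_ids)
    )
    if (config$missing_rate > 0) {
      drop <- stats::runif(nrow(out)) < config$missing_rate
      out$dosage[drop] <- NA_integer_
    }
    if (length(config$snp_failure_ids) > 0) {
      out$dosage[out$snp_id %in% config$snp_failure_ids] <- NA_integer_
    }
    out
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  validate_genotypes(out)
  out
}

#' Simulate a full two-population study
#'
#' Draws the reference and target cohorts of a [simulation_config()] under
#' the config's master seed (target frequencies are resolved first, so the
#' same config always yields the same divergence draw). Identical seeds
#' produce identical studies.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_study` with elements `reference` and
#'   `target` (genotype tibbles), `panel` (the generative weight panel) and
#'   `truth` (the config, with `freq_target` resolved).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    if (is.null(config$freq_target)) {
      config$freq_target <- diverge_frequencies(config$freq_ref,
                                                config$divergence_f)
    }
    reference <- simulate_cohort(config, "reference")
    target <- simulate_cohort(config, "target")
    structure(list(reference = reference, target = target,
                   panel = simulation_panel(config), truth = config),
              class = "simulated_study")
  })
}

#' Built-in simulation scenarios
#'
#' Two ready-made study configurations:
#'
#' * `"uk-like"` — reference and target drawn from the same population: 28
#'   markers with per-allele odds ratios spread over 1.1-1.4, reference
#'   ascertained at 500 cases / 430 controls (a down-scaled large
#'   consortium cohort), target at 43 cases / 163 controls, no frequency
#'   divergence. The calibration scenario: the score should transfer.
#' * `"africa-null"` — same reference; the target population's frequencies
#'   diverge with F = 0.2 and four markers are driven below 2% frequency,
#'   and the markers carry no effect in the target (all-null generative
#'   weights). The discrimination scenario: the score should not transfer.
#'
#' Both use a 2% MCAR genotype dropout rate.
#'
#' @param name Scenario name.
#' @param seed Master seed stored in the config.
#' @return A [simulation_config()].
#' @export
scenario_config <- function(name = c("uk-like", "africa-null"), seed = 1) {
  name <- match.arg(name)
  n_snps <- 28
  freq_ref <- seq(0.05, 0.45, length.out = n_snps)
  weights <- log(seq(1.1, 1.4, length.out = n_snps))
  if (name == "uk-like") {
    simulation_config(
      n_snps = n_snps, freq_ref = freq_ref, freq_target = freq_ref,
      weights_gen = weights, intercept = -4,
      n_case = 500, n_control = 430,
      n_case_target = 43, n_control_target = 163,
      missing_rate = 0.02, seed = seed
    )
  } else {
    freq_target <- diverge_frequencies(freq_ref, 0.2, seed = seed)
    freq_target[1:4] <- c(0.010, 0.015, 0.012, 0.018)
    simulation_config(
      n_snps = n_snps, freq_ref = freq_ref, freq_target = freq_target,
      weights_gen = weights, weights_gen_target = rep(0, n_snps),
      intercept = -4,
      n_case = 500, n_control = 430,
      n_case_target = 43, n_control_target = 163,
      missing_rate = 0.02, seed = seed
    )
  }
}

#' @rdname simulate_study
#' @param study A `simulated_study`.
#' @param dir Output directory; writes `reference.tsv`, `target.tsv`,
#'   `panel.tsv` and `truth.json`.
#' @return `write_study()` returns `dir` invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes(study$reference, file.path(dir, "reference.tsv"))
  write_genotypes(study$target, file.path(dir, "target.tsv"))
  panel <- study$panel
  readr::write_tsv(panel, file.path(dir, "panel.tsv"), progress = FALSE)
  truth <- unclass(study$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
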