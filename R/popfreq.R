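#' Per-cohort allele frequencies
#'
#' Frequency of each SNP's counted allele among non-missing calls of the
#' selected samples. A SNP with no called genotype gets `frequency = NA`
#' (explicitly undefined) with `n_called = 0`.
#'
#' @inheritParams sample_missingness
#' @param cohort A single cohort label to restrict to, or `"all"` (default)
#'   to use every sample. An absent label is an error.
#' @return A tibble with one row per SNP: `cohort`, `snp_id`,
#'   `counted_allele`, `other_allele`, `frequency`, `n_called`.
#' @export
allele_frequencies <- function(genotypes, cohort = "all") {
  validate_genotypes(genotypes)
  stopifnot(length(cohort) == 1)
  sel <- genotypes
  if (!identical(cohort, "all")) {
    if (!cohort %in% genotypes$cohort) {
      stop("cohort label '", cohort, "' not present in genotype table",
           call. = FALSE)
    }
    sel <- dplyr::filter(genotypes, .data$cohort == !!cohort)
  }
  sel |>
    dplyr::group_by(.data$snp_id, .data$counted_allele, .data$other_allele) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$dosage)),
      frequency = ifelse(.data$n_called > 0,
                         sum(.data$dosage, na.rm = TRUE) / (2 * .data$n_called),
                         NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(cohort = !!cohort) |>
    dplyr::select("cohort", "snp_id", "counted_allele", "other_allele",
                  "frequency", "n_called") |>
    dplyr::arrange(match(.data$snp_id, unique(genotypes$snp_id)))
}

#' Published allele-frequency table
#'
#' Builds an allele-frequency table from published per-SNP frequencies for a
#' cohort without individual-level genotypes (for example frequencies
#' retrieved from a public browser). Such tables carry `n_called = NA` and
#' can be used in [maf_correlation()] and [maf_difference_bins()] but not in
#' pooling or risk-score computation.
#'
#' @param cohort Cohort label.
#' @param snp_id Character vector of SNP ids.
#' @param counted_allele Allele each frequency refers to.
#' @param frequency Frequencies in \[0, 1\].
#' @param other_allele Optional opposite-allele labels (default `NA`).
#' @return A tibble with the same columns as [allele_frequencies()].
#' @export
published_frequencies <- function(cohort, snp_id, counted_allele, frequency,
                                  other_allele = NA_character_) {
  if (any(!is.na(frequency) & (frequency < 0 | frequency > 1))) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(cohort = cohort, snp_id = snp_id,
                 counted_allele = counted_allele,
                 other_allele = other_allele,
                 frequency = frequency, n_called = NA_integer_)
}

#' Minor-allele designation relative to a reference cohort
#'
#' Designates, per SNP, the allele whose frequency in the reference cohort is
#' below 0.5 as the minor allele; at exactly 0.5 the counted allele is
#' designated minor (a deterministic tie-break). The designation is fixed by
#' the reference and carried across populations when frequencies are
#' compared, so the "minor" allele's frequency may exceed 0.5 elsewhere.
#'
#' @param reference An allele-frequency table (see [allele_frequencies()])
#'   for the reference cohort; frequencies must be defined for every SNP.
#' @return A tibble with `snp_id`, `minor_allele` (label, `NA` when the
#'   counted allele is major and the other allele label is unknown), and
#'   `minor_is_counted` (logical).
#' @export
minor_allele_map <- function(reference) {
  if (any(is.na(reference$frequency))) {
    stop("reference frequency undefined for SNP '",
         reference$snp_id[is.na(reference$frequency)][1], "'", call. = FALSE)
  }
  reference |>
    dplyr::mutate(
      minor_is_counted = .data$frequency <= 0.5,
      minor_allele = ifelse(.data$minor_is_counted,
                            .data$counted_allele, .data$other_allele)
    ) |>
    dplyr::select("snp_id", "minor_allele", "minor_is_counted")
}

#' Align frequency tables on a reference cohort's minor allele
#'
#' Joins one or more allele-frequency tables on SNP id and re-expresses every
#' cohort's frequency as the frequency of the reference cohort's minor allele
#' (`1 - f` where the minor allele is the non-counted allele). All tables
#' must count the same allele per SNP.
#'
#' @param reference Allele-frequency table defining the minor allele.
#' @param ... Further allele-frequency tables to align.
#' @return A tibble with `snp_id`, `minor_allele`, and one `maf_<cohort>`
#'   column per input table (reference first).
#' @export
align_minor_frequencies <- function(reference, ...) {
  tables <- c(list(reference), list(...))
  map <- minor_allele_map(reference)
  aligned <- purrr::map(tables, function(tbl) {
    joined <- dplyr::inner_join(tbl, map, by = "snp_id")
    mismatch <- joined$counted_allele != reference$counted_allele[
      match(joined$snp_id, reference$snp_id)]
    if (any(mismatch, na.rm = TRUE)) {
      stop("cohort '", joined$cohort[which(mismatch)[1]],
           "' counts a different allele than the reference at SNP '",
           joined$snp_id[which(mismatch)[1]], "'", call. = FALSE)
    }
    joined |>
      dplyr::transmute(
        .data$snp_id, cohort = .data$cohort[1],
        maf = ifelse(.data$minor_is_counted, .data$frequency,
                     1 - .data$frequency)
      )
  })
  out <- purrr::reduce(
    purrr::map(aligned, function(a) {
      stats::setNames(a[c("snp_id", "maf")],
                      c("snp_id", paste0("maf_", a$cohort[1])))
    }),
    dplyr::inner_join, by = "snp_id"
  )
  dplyr::inner_join(dplyr::select(map, "snp_id", "minor_allele"), out,
                    by = "snp_id")
}

#' Cross-population MAF correlation
#'
#' Pearson correlation between two aligned minor-allele-frequency vectors
#' with the two-sided p-value from the t statistic of the regression slope on
#' n - 2 degrees of freedom (equivalently, the standard correlation test).
#'
#' @param freqs_a,freqs_b Numeric frequency vectors of equal length (at least
#'   3), aligned on the same SNPs and the same (reference-minor) allele.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
maf_correlation <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b)) {
    stop("frequency vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(freqs_a) & !is.na(freqs_b)
  freqs_a <- freqs_a[keep]
  freqs_b <- freqs_b[keep]
  if (length(freqs_a) < 3) {
    stop("need at least 3 paired frequencies", call. = FALSE)
  }
  if (stats::sd(freqs_a) == 0 || stats::sd(freqs_b) == 0) {
    stop("correlation undefined: a frequency vector is constant",
         call. = FALSE)
  }
  ct <- stats::cor.test(freqs_a, freqs_b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(freqs_a))
}

#' Bin absolute cross-population MAF differences
#'
#' Counts SNPs whose absolute frequency difference is strictly below the low
#' cutoff, between the cutoffs (inclusive), and strictly above the high
#' cutoff. The three bins partition the panel.
#'
#' @param freqs_ref,freqs_other Aligned frequency vectors of equal length.
#' @param cutoffs Two increasing cutoffs, default `c(0.10, 0.20)`.
#' @return A one-row tibble: `n_below_low`, `n_between`, `n_above_high`.
#' @export
maf_difference_bins <- function(freqs_ref, freqs_other,
                                cutoffs = c(0.10, 0.20)) {
  if (length(freqs_ref) != length(freqs_other)) {
    stop("frequency vectors must have equal length", call. = FALSE)
  }
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  d <- abs(freqs_ref - freqs_other)
  d <- d[!is.na(d)]
  tibble::tibble(
    n_below_low = sum(d < cutoffs[1]),
    n_between = sum(d >= cutoffs[1] & d <= cutoffs[2]),
    n_above_high = sum(d > cutoffs[2])
  )
}

#' Pool genotype cohorts
#'
#' Row-concatenates genotype tables, restricted to the SNPs common to all of
#' them. Tables must count the same allele at every shared SNP. When sample
#' ids collide across tables, ids are disambiguated by prefixing each with
#' its cohort label (`<cohort>:<sample_id>`); tables with globally unique
#' ids are concatenated unchanged. Empty tables are ignored, so pooling with
#' an empty table is the identity.
#'
#' @param tables A list of long genotype tibbles.
#' @return A single pooled genotype tibble.
#' @export
pool_cohorts <- function(tables) {
  stopifnot(is.list(tables))
  tables <- purrr::keep(tables, \(t) nrow(t) > 0)
  if (length(tables) == 0) stop("no non-empty tables to pool", call. = FALSE)
  purrr::walk(tables, validate_genotypes)
  if (length(tables) == 1) return(tables[[1]])

  common <- purrr::reduce(purrr::map(tables, \(t) unique(t$snp_id)),
                          intersect)
  if (length(common) == 0) {
    stop("no SNPs are shared by all cohorts; cannot pool", call. = FALSE)
  }
  tables <- purrr::map(tables, \(t) dplyr::filter(t, .data$snp_id %in% common))

  alleles <- purrr::map(tables, snp_alleles)
  ref <- alleles[[1]] |> dplyr::arrange(.data$snp_id)
  for (a in alleles[-1]) {
    a <- dplyr::arrange(a, .data$snp_id)
    clash <- !is.na(a$counted_allele) & !is.na(ref$counted_allele) &
      a$counted_allele != ref$counted_allele
    if (any(clash)) {
      stop("cohorts count different alleles at SNP '",
           a$snp_id[clash][1], "'; orient tables to a common panel first",
           call. = FALSE)
    }
  }

  ids <- purrr::map(tables, \(t) unique(t$sample_id))
  if (anyDuplicated(unlist(ids)) > 0) {
    tables <- purrr::map(tables, function(t) {
      dplyr::mutate(t, sample_id = paste0(.data$cohort, ":", .data$sample_id))
    })
    if (anyDuplicated(unlist(purrr::map(tables, \(t) unique(t$sample_id)))) > 0) {
      stop("sample ids are not unique even after cohort prefixing",
           call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(tables)
  validate_genotypes(out)
  out
}

#' Assemble the analysis panel from per-dataset genotyping status
#'
#' Restricts a SNP weight panel to the markers genotyped successfully in
#' every dataset, preserving panel order. Markers that failed genotyping or
#' whose genotypes (or proxies) were unavailable in any one dataset are
#' dropped.
#'
#' @param panel A SNP weight panel (see [read_weights()]).
#' @param availability A tibble with columns `snp_id`, `dataset`, `status`
#'   (`"genotyped"`, `"failed"` or `"unavailable"`); every panel SNP must
#'   have a status in every dataset.
#' @return The panel restricted to SNPs genotyped in all datasets.
#' @export
intersect_panel <- function(panel, availability) {
  stopifnot(all(c("snp_id", "dataset", "status") %in% names(availability)))
  bad_status <- setdiff(unique(availability$status),
                        c("genotyped", "failed", "unavailable"))
  if (length(bad_status) > 0) {
    stop("unknown availability status: ", bad_status[1], call. = FALSE)
  }
  datasets <- unique(availability$dataset)
  grid <- tidyr::expand_grid(snp_id = panel$snp_id, dataset = datasets)
  joined <- dplyr::left_join(grid, availability,
                             by = c("snp_id", "dataset"))
  if (any(is.na(joined$status))) {
    miss <- joined[is.na(joined$status), ]
    stop("no availability status for SNP '", miss$snp_id[1],
         "' in dataset '", miss$dataset[1], "'", call. = FALSE)
  }
  keep <- joined |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(ok = all(.data$status == "genotyped"),
                     .groups = "drop")
  dplyr::filter(panel, .data$snp_id %in% keep$snp_id[keep$ok])
}
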