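#' Genotype tables
#'
#' `grstransfer` represents genotype data as a long ("tidy") tibble with one
#' row per sample-by-SNP call and the columns
#'
#' * `sample_id` — unique sample identifier,
#' * `phenotype` — one of `"case"`, `"control"`, `"unknown"`,
#' * `cohort` — cohort label,
#' * `snp_id` — marker identifier (rsID),
#' * `counted_allele` — the allele whose copies `dosage` counts (constant
#'   within a SNP),
#' * `other_allele` — the opposite allele (may be `NA` when never observed,
#'   e.g. for a monomorphic marker),
#' * `dosage` — number of copies of the counted allele: 0, 1, 2 or `NA`
#'   for a missing call.
#'
#' Every sample carries a row for every SNP (a complete grid), so missing
#' genotypes are explicit `NA` dosages, never absent rows. All genotype
#' functions in the package take and return tibbles of this shape.
#'
#' @param genotypes A data frame to validate.
#' @return `validate_genotypes()` returns its input invisibly (as a tibble)
#'   or throws an informative error.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   phenotype = rep(c("case", "control"), each = 2),
#'   cohort = "demo",
#'   snp_id = rep(c("rs1", "rs2"), 2),
#'   counted_allele = rep(c("A", "C"), 2),
#'   other_allele = rep(c("G", "T"), 2),
#'   dosage = c(0L, 1L, 2L, NA)
#' )
#' validate_genotypes(g)
#' @export
validate_genotypes <- function(genotypes) {
  required <- c("sample_id", "phenotype", "cohort", "snp_id",
                "counted_allele", "other_allele", "dosage")
  missing_cols <- setdiff(required, names(genotypes))
  if (length(missing_cols) > 0) {
    stop("genotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  genotypes <- tibble::as_tibble(genotypes)

  bad_dosage <- !is.na(genotypes$dosage) & !genotypes$dosage %in% c(0, 1, 2)
  if (any(bad_dosage)) {
    stop("dosage entries must be 0, 1, 2 or NA; offending value(s): ",
         paste(utils::head(unique(genotypes$dosage[bad_dosage]), 3),
               collapse = ", "), call. = FALSE)
  }
  bad_pheno <- !genotypes$phenotype %in% c("case", "control", "unknown")
  if (any(bad_pheno)) {
    stop("phenotype must be 'case', 'control' or 'unknown'; got: ",
         paste(utils::head(unique(genotypes$phenotype[bad_pheno]), 3),
               collapse = ", "), call. = FALSE)
  }

  cell_key <- paste(genotypes$sample_id, genotypes$snp_id, sep = "\r")
  dup_at <- anyDuplicated(cell_key)
  if (dup_at > 0) {
    stop("duplicated sample/SNP cell(s), e.g. sample '",
         genotypes$sample_id[dup_at], "' at SNP '",
         genotypes$snp_id[dup_at], "'", call. = FALSE)
  }

  # complete grid: every sample must carry every SNP
  n_samples <- length(unique(genotypes$sample_id))
  n_snps <- length(unique(genotypes$snp_id))
  if (nrow(genotypes) != n_samples * n_snps) {
    stop("genotype table is not a complete sample-by-SNP grid (",
         nrow(genotypes), " rows for ", n_samples, " samples x ",
         n_snps, " SNPs)", call. = FALSE)
  }

  first <- !duplicated(genotypes$snp_id)
  allele_key <- paste(genotypes$snp_id, genotypes$counted_allele,
                      genotypes$other_allele, sep = "\r")
  if (length(unique(allele_key)) != n_snps) {
    stop("counted_allele/other_allele must be constant within each SNP",
         call. = FALSE)
  }
  same <- first & !is.na(genotypes$other_allele) &
    genotypes$counted_allele == genotypes$other_allele
  if (any(same, na.rm = TRUE)) {
    stop("counted_allele equals other_allele at SNP '",
         genotypes$snp_id[which(same)[1]], "'", call. = FALSE)
  }

  pheno_key <- paste(genotypes$sample_id, genotypes$phenotype,
                     genotypes$cohort, sep = "\r")
  if (length(unique(pheno_key)) != n_samples) {
    stop("phenotype/cohort must be constant within each sample", call. = FALSE)
  }

  invisible(genotypes)
}

#' @rdname validate_genotypes
#' @return `snp_alleles()` returns a tibble with one row per SNP and columns
#'   `snp_id`, `counted_allele`, `other_allele`.
#' @export
snp_alleles <- function(genotypes) {
  genotypes |>
    dplyr::distinct(.data$snp_id, .data$counted_allele, .data$other_allele)
}

#' @rdname validate_genotypes
#' @return `sample_info()` returns a tibble with one row per sample and
#'   columns `sample_id`, `phenotype`, `cohort`.
#' @export
sample_info <- function(genotypes) {
  genotypes |>
    dplyr::distinct(.data$sample_id, .data$phenotype, .data$cohort)
}

#' Pivot a genotype table to a wide sample-by-SNP dosage matrix
#'
#' Convenience view: one row per sample, one column of 0/1/2/`NA` dosages per
#' SNP, preceded by `sample_id`, `phenotype`, `cohort`. The allele labels are
#' dropped, so this view is for inspection and numeric work, not for
#' serialization (see [write_genotypes()]).
#'
#' @param genotypes A long genotype tibble (see [validate_genotypes()]).
#' @return A wide tibble.
#' @export
genotypes_wide <- function(genotypes) {
  genotypes |>
    dplyr::select("sample_id", "phenotype", "cohort", "snp_id", "dosage") |>
    tidyr::pivot_wider(names_from = "snp_id", values_from = "dosage")
}
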