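#' Read genotype data
#'
#' Reads individual-level genotype calls into the package's long genotype
#' tibble (see [validate_genotypes()]). Two text dialects are supported:
#'
#' * `"tsv"` — a tab-separated file with header
#'   `sample_id  phenotype  cohort  <rsID1>  <rsID2> ...` and genotype cells
#'   written as two-letter allele pairs (`"AG"`, `"CC"`, ...) or `NA` for a
#'   missing call.
#' * `"plink_text"` — PLINK text `.ped`/`.map` pair. `path` may be either the
#'   `.ped` file or the common prefix. The `.ped` file carries six leading
#'   columns (FID, IID, PAT, MAT, SEX, PHENO with 1 = control, 2 = case,
#'   0/-9 = unknown) followed by two allele columns per SNP; FID is used as
#'   the cohort label and IID as the sample id. The `.map` columns are
#'   chromosome, snp_id, genetic distance (ignored), position (ignored).
#'
#' Allele codes must be A/C/G/T; the codes `0` and `N` mark a missing allele
#' (a call with either allele missing is treated as entirely missing) and any
#' other code is a parse error naming the offending line. The counted allele
#' of each SNP is the alphabetically first allele observed at that SNP, so
#' reading is deterministic regardless of row order.
#'
#' @param path Path to the genotype file (for `plink_text`, the `.ped` file
#'   or the prefix of the `.ped`/`.map` pair).
#' @param dialect `"tsv"` or `"plink_text"`.
#' @return A long genotype tibble.
#' @seealso [write_genotypes()], [orient_to_risk_allele()]
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_text")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = read_genotypes_tsv(path),
         plink_text = read_genotypes_plink(path))
}

MISSING_ALLELE_CODES <- c("0", "N")
VALID_ALLELES <- c("A", "C", "G", "T")

# Turn parallel allele-call vectors (a1, a2 per call) for one SNP into
# dosages of the alphabetically first observed allele.
count_counted_allele <- function(a1, a2, snp_id, line_no) {
  miss <- a1 %in% MISSING_ALLELE_CODES | a2 %in% MISSING_ALLELE_CODES |
    is.na(a1) | is.na(a2)
  bad <- (!miss) & (!(a1 %in% VALID_ALLELES) | !(a2 %in% VALID_ALLELES))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("parse error at line ", line_no[i], ": invalid allele call '",
         a1[i], a2[i], "' for SNP '", snp_id, "'", call. = FALSE)
  }
  observed <- sort(unique(c(a1[!miss], a2[!miss])))
  if (length(observed) > 2) {
    i <- which(!miss)[1]
    stop("parse error: more than two alleles (", paste(observed, collapse = "/"),
         ") observed at SNP '", snp_id, "'", call. = FALSE)
  }
  counted <- if (length(observed) >= 1) observed[1] else NA_character_
  other <- if (length(observed) == 2) observed[2] else NA_character_
  dosage <- ifelse(miss, NA_integer_,
                   (a1 == counted) + (a2 == counted))
  list(counted_allele = counted, other_allele = other,
       dosage = as.integer(dosage))
}

assert_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate ", what, " id(s): ",
         paste(utils::head(dup, 3), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
  lead <- c("sample_id", "phenotype", "cohort")
  if (!identical(names(wide)[seq_along(lead)], lead)) {
    stop("parse error: TSV genotype header must start with ",
         paste(lead, collapse = ", "), call. = FALSE)
  }
  snp_ids <- setdiff(names(wide), lead)
  if (length(snp_ids) == 0) stop("no SNP columns in ", path, call. = FALSE)
  assert_unique_ids(snp_ids, "SNP")
  assert_unique_ids(wide$sample_id, "sample")
  if (!all(wide$phenotype %in% c("case", "control", "unknown"))) {
    stop("parse error: phenotype must be case/control/unknown", call. = FALSE)
  }
  line_no <- seq_len(nrow(wide)) + 1L  # header is line 1

  per_snp <- purrr::map(snp_ids, function(snp) {
    cell <- wide[[snp]]
    is_na <- is.na(cell) | cell %in% c("NA", "")
    if (any(!is_na & nchar(cell) != 2)) {
      i <- which(!is_na & nchar(cell) != 2)[1]
      stop("parse error at line ", line_no[i], ": genotype cell '", cell[i],
           "' for SNP '", snp, "' is not a two-letter allele pair",
           call. = FALSE)
    }
    a1 <- ifelse(is_na, NA_character_, substr(cell, 1, 1))
    a2 <- ifelse(is_na, NA_character_, substr(cell, 2, 2))
    counts <- count_counted_allele(a1, a2, snp, line_no)
    tibble::tibble(
      sample_id = wide$sample_id, phenotype = wide$phenotype,
      cohort = wide$cohort, snp_id = snp,
      counted_allele = counts$counted_allele,
      other_allele = counts$other_allele, dosage = counts$dosage
    )
  })
  out <- dplyr::bind_rows(per_snp) |>
    dplyr::arrange(match(.data$sample_id, wide$sample_id),
                   match(.data$snp_id, snp_ids))
  validate_genotypes(out)
  out
}

plink_pair_paths <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  if (!file.exists(ped)) stop("file not found: ", ped, call. = FALSE)
  if (!file.exists(map)) stop("file not found: ", map, call. = FALSE)
  list(ped = ped, map = map)
}

read_genotypes_plink <- function(path) {
  paths <- plink_pair_paths(path)
  map_lines <- readLines(paths$map)
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  n_fields <- lengths(map_fields)
  if (any(n_fields < 4)) {
    stop("parse error at line ", which(n_fields < 4)[1], " of ", paths$map,
         ": expected 4 columns (chrom, snp_id, cM, position)", call. = FALSE)
  }
  snp_ids <- vapply(map_fields, `[[`, character(1), 2)
  assert_unique_ids(snp_ids, "SNP")
  n_snps <- length(snp_ids)

  ped_lines <- readLines(paths$ped)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "\\s+")
  expected <- 6L + 2L * n_snps
  bad <- which(lengths(fields) != expected)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], " of ", paths$ped, ": expected ",
         expected, " fields (6 + 2 per SNP for ", n_snps, " SNPs), found ",
         lengths(fields)[bad[1]], call. = FALSE)
  }
  ped <- do.call(rbind, fields)
  sample_id <- ped[, 2]
  assert_unique_ids(sample_id, "sample")
  cohort <- ped[, 1]
  phenotype <- dplyr::case_match(ped[, 6],
                                 "1" ~ "control", "2" ~ "case",
                                 c("0", "-9") ~ "unknown")
  if (any(is.na(phenotype))) {
    i <- which(is.na(phenotype))[1]
    stop("parse error at line ", i, " of ", paths$ped,
         ": phenotype code '", ped[i, 6], "' is not 1/2/0/-9", call. = FALSE)
  }
  line_no <- seq_along(sample_id)

  per_snp <- purrr::map(seq_len(n_snps), function(j) {
    a1 <- toupper(ped[, 6 + 2 * j - 1])
    a2 <- toupper(ped[, 6 + 2 * j])
    counts <- count_counted_allele(a1, a2, snp_ids[j], line_no)
    tibble::tibble(
      sample_id = sample_id, phenotype = phenotype, cohort = cohort,
      snp_id = snp_ids[j], counted_allele = counts$counted_allele,
      other_allele = counts$other_allele, dosage = counts$dosage
    )
  })
  out <- dplyr::bind_rows(per_snp) |>
    dplyr::arrange(match(.data$sample_id, sample_id),
                   match(.data$snp_id, snp_ids))
  validate_genotypes(out)
  out
}

#' Write a genotype table in the TSV dialect
#'
#' Serializes a long genotype tibble as the tab-separated wide dialect read
#' back by `read_genotypes(dialect = "tsv")`: genotype cells are two-letter
#' allele pairs built from `counted_allele`/`other_allele` (heterozygotes
#' written with the alphabetically first allele first) and `NA` for missing
#' calls. Note that [read_genotypes()] canonicalizes the counted allele to
#' the alphabetically first observed allele, so a write/read round trip
#' reproduces the table exactly when the input is in that canonical
#' orientation (as every freshly read table is).
#'
#' @param genotypes A long genotype tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  validate_genotypes(genotypes)
  needs_other <- !is.na(genotypes$dosage) & genotypes$dosage < 2 &
    is.na(genotypes$other_allele)
  if (any(needs_other)) {
    stop("cannot serialize SNP '", genotypes$snp_id[needs_other][1],
         "': dosage < 2 requires a known other_allele", call. = FALSE)
  }
  cell <- dplyr::case_when(
    is.na(genotypes$dosage) ~ "NA",
    genotypes$dosage == 2L ~ strrep(genotypes$counted_allele, 2),
    genotypes$dosage == 0L ~ strrep(genotypes$other_allele, 2),
    TRUE ~ paste0(pmin(genotypes$counted_allele, genotypes$other_allele),
                  pmax(genotypes$counted_allele, genotypes$other_allele))
  )
  wide <- genotypes |>
    dplyr::mutate(cell = cell) |>
    dplyr::select("sample_id", "phenotype", "cohort", "snp_id", "cell") |>
    tidyr::pivot_wider(names_from = "snp_id", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP weight table
#'
#' Reads the risk-marker panel used to build the genetic risk score: one row
#' per SNP with columns `snp_id`, `chromosome`, `locus_name`, `risk_allele`,
#' `other_allele`, and exactly one of
#'
#' * `weight` — the per-allele log odds ratio, used as is, or
#' * `or` — the per-allele odds ratio, converted to `log(or)` on read.
#'
#' @param path Path to a tab-separated weight table.
#' @return A tibble of SNP records in file order, with a `weight` column on
#'   the natural-log-odds-ratio scale.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = "c", chromosome = "c", locus_name = "c",
    risk_allele = "c", other_allele = "c", .default = "d"
  ), progress = FALSE)
  required <- c("snp_id", "chromosome", "locus_name", "risk_allele",
                "other_allele")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("weight table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_w <- "weight" %in% names(tbl)
  has_or <- "or" %in% names(tbl)
  if (has_w == has_or) {
    stop("weight table must have exactly one of the columns 'weight' ",
         "(ln OR) or 'or'", call. = FALSE)
  }
  if (has_or) {
    if (any(!is.finite(tbl$or) | tbl$or <= 0)) {
      stop("odds ratios must be finite and > 0", call. = FALSE)
    }
    tbl$weight <- log(tbl$or)
    tbl$or <- NULL
  }
  validate_panel(tbl)
  dplyr::select(tbl, "snp_id", "chromosome", "locus_name",
                "risk_allele", "other_allele", "weight")
}

#' @rdname read_weights
#' @param panel A data frame of SNP records to validate (columns as above,
#'   with `weight` on the log scale).
#' @return `validate_panel()` returns its input invisibly or errors.
#' @export
validate_panel <- function(panel) {
  assert_unique_ids(panel$snp_id, "SNP")
  if (any(!nzchar(panel$snp_id))) stop("empty snp_id", call. = FALSE)
  if (any(!is.finite(panel$weight))) {
    stop("weights must be finite", call. = FALSE)
  }
  ok_allele <- function(a) a %in% VALID_ALLELES
  bad <- !ok_allele(panel$risk_allele) | !ok_allele(panel$other_allele) |
    panel$risk_allele == panel$other_allele
  if (any(bad)) {
    stop("invalid allele pair at SNP '", panel$snp_id[bad][1],
         "': risk and other allele must be distinct A/C/G/T", call. = FALSE)
  }
  invisible(panel)
}

#' Orient genotype dosages to the panel's risk alleles
#'
#' Restricts a genotype table to the SNPs of a weight panel and recodes
#' dosages so that every count refers to the risk allele: where the table's
#' counted allele is the panel's other allele the dosage is complemented
#' (`2 - dosage`); missing stays missing. The counted allele of a table SNP
#' must match either panel allele — no strand flipping is attempted, so
#' palindromic (A/T, C/G) markers are matched by label only.
#'
#' @param genotypes A long genotype tibble.
#' @param panel A SNP weight panel (see [read_weights()]).
#' @return A genotype tibble restricted to panel SNPs, with
#'   `counted_allele == risk_allele` everywhere.
#' @export
orient_to_risk_allele <- function(genotypes, panel) {
  validate_genotypes(genotypes)
  validate_panel(panel)
  absent <- setdiff(panel$snp_id, unique(genotypes$snp_id))
  if (length(absent) > 0) {
    stop("panel SNP(s) absent from genotype table: ",
         paste(utils::head(absent, 3), collapse = ", "), call. = FALSE)
  }
  out <- genotypes |>
    dplyr::inner_join(
      dplyr::select(panel, "snp_id", "risk_allele",
                    panel_other = "other_allele"),
      by = "snp_id"
    )
  counted <- out$counted_allele
  mismatch <- !is.na(counted) &
    counted != out$risk_allele & counted != out$panel_other
  if (any(mismatch)) {
    stop("allele mismatch at SNP '", out$snp_id[mismatch][1],
         "': counted allele '", counted[mismatch][1],
         "' matches neither panel allele (",
         out$risk_allele[mismatch][1], "/", out$panel_other[mismatch][1],
         ")", call. = FALSE)
  }
  flip <- !is.na(counted) & counted == out$panel_other
  out$dosage[flip] <- 2L - out$dosage[flip]
  out$counted_allele <- out$risk_allele
  out$other_allele <- out$panel_other
  out |>
    dplyr::select(-"risk_allele", -"panel_other") |>
    dplyr::arrange(match(.data$snp_id, panel$snp_id)) |>
    dplyr::arrange(match(.data$sample_id, unique(genotypes$sample_id)))
}
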