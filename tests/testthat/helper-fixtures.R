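# Build a long genotype tibble from a samples-by-SNPs dosage matrix.
make_geno <- function(dosage, phenotype, cohort = "demo",
                      sample_ids = NULL, snp_ids = NULL,
                      counted = "A", other = "G") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- sprintf("m%02d", seq_len(m))
  counted <- rep_len(counted, m)
  other <- rep_len(other, m)
  tibble::tibble(
    sample_id = rep(sample_ids, each = m),
    phenotype = rep(rep_len(phenotype, n), each = m),
    cohort = rep(rep_len(cohort, n), each = m),
    snp_id = rep(snp_ids, times = n),
    counted_allele = rep(counted, times = n),
    other_allele = rep(other, times = n),
    dosage = as.integer(t(dosage))
  )
}

make_panel <- function(snp_ids, weights, risk = "A", other = "G") {
  tibble::tibble(
    snp_id = snp_ids,
    chromosome = "1",
    locus_name = paste0("locus_", snp_ids),
    risk_allele = rep_len(risk, length(snp_ids)),
    other_allele = rep_len(other, length(snp_ids)),
    weight = weights
  )
}

# Independent brute-force oracle for the exact HWE test: enumerate every
# heterozygote count compatible with the observed allele counts, weight each
# configuration by its multinomial count of orderings (choose-based, a
# different route than the package's closed-form factorial formula),
# normalize, and sum the probabilities no larger than the observed one.
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  n <- n_hom1 + n_het + n_hom2
  hs <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  w <- vapply(hs, function(h) {
    choose(n, (n_a - h) / 2) * choose(n - (n_a - h) / 2, h) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  p_obs <- p[hs == n_het]
  sum(p[p <= p_obs * (1 + 1e-12)])
}
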