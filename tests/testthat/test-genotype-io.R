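test_that("TSV genotype files parse to counted-allele dosages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tphenotype\tcohort\trs1\trs2",
    "s1\tcase\tcam\tAA\tGG",
    "s2\tcontrol\tcam\tAG\tNA"
  ), path)
  g <- read_genotypes(path, dialect = "tsv")
  expect_equal(nrow(g), 4)
  # counted allele is the alphabetically first observed allele
  alleles <- snp_alleles(g)
  expect_equal(alleles$counted_allele, c("A", "G"))
  expect_equal(g$dosage[g$sample_id == "s1"], c(2L, 2L))
  expect_equal(g$dosage[g$sample_id == "s2"], c(1L, NA))
})

test_that("TSV parse errors name the offending line and value", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tphenotype\tcohort\trs1",
    "s1\tcase\tcam\tAA",
    "s2\tcontrol\tcam\tAX"
  ), path)
  expect_error(read_genotypes(path), "line 3.*AX|AX.*line 3")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tphenotype\tcohort\trs1",
    "s1\tcase\tcam\tAA",
    "s1\tcontrol\tcam\tAG"
  ), dup)
  expect_error(read_genotypes(dup), "duplicate sample")
})

test_that("PLINK ped/map pairs parse with missing codes and phenotype map", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  writeLines(c(
    "1 rs1 0 1000",
    "1 rs2 0 2000"
  ), map)
  writeLines(c(
    "cam id1 0 0 1 2 A A G G",
    "cam id2 0 0 2 1 A G 0 0",
    "cam id3 0 0 1 0 G G G T"
  ), ped)
  g <- read_genotypes(ped, dialect = "plink_text")
  info <- sample_info(g)
  expect_equal(info$phenotype, c("case", "control", "unknown"))
  expect_equal(unique(info$cohort), "cam")
  expect_equal(g$dosage[g$snp_id == "rs1"], c(2L, 1L, 0L))
  expect_equal(g$dosage[g$snp_id == "rs2"], c(2L, NA, 1L))
})

test_that("a ped row with the wrong genotype count is a parse error", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  writeLines(c("1 rs1 0 1", "1 rs2 0 2", "1 rs3 0 3"), map)
  writeLines("cam id1 0 0 1 2 A A G G", ped)  # 2 pairs for 3 SNPs
  expect_error(read_genotypes(ped, dialect = "plink_text"),
               "expected 12 fields")
})

test_that("weight tables convert OR columns to the log scale", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tchromosome\tlocus_name\trisk_allele\tother_allele\tor",
    "rs1\t1\tLOC1\tA\tG\t1.5",
    "rs2\t2\tLOC2\tC\tT\t1.0"
  ), path)
  w <- read_weights(path)
  expect_equal(w$weight, c(log(1.5), 0))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tchromosome\tlocus_name\trisk_allele\tother_allele\tor",
    "rs1\t1\tLOC1\tA\tG\t-2"
  ), bad)
  expect_error(read_weights(bad), "odds ratios")

  both <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tchromosome\tlocus_name\trisk_allele\tother_allele\tor\tweight",
    "rs1\t1\tLOC1\tA\tG\t1.5\t0.4"
  ), both)
  expect_error(read_weights(both), "exactly one")
})

test_that("the shipped synthetic panel loads with 29 markers", {
  w <- read_weights(system.file("extdata", "ra_panel_weights_synthetic.tsv",
                                package = "grstransfer"))
  expect_equal(nrow(w), 29)
  expect_true(all(is.finite(w$weight) & w$weight > 0))
  expect_true("rs6910071" %in% w$snp_id)  # the HLA tag row
})

test_that("orientation flips counts where the counted allele is the other allele", {
  g <- make_geno(rbind(c(2L, 1L), c(0L, NA)), c("case", "control"),
                 snp_ids = c("rs1", "rs2"),
                 counted = c("G", "A"), other = c("A", "G"))
  panel <- make_panel(c("rs1", "rs2"), c(0.1, 0.2),
                      risk = c("A", "A"), other = c("G", "G"))
  oriented <- orient_to_risk_allele(g, panel)
  expect_equal(snp_alleles(oriented)$counted_allele, c("A", "A"))
  # rs1 counted G -> flipped; rs2 counted A = risk -> unchanged
  expect_equal(oriented$dosage[oriented$snp_id == "rs1"], c(0L, 2L))
  expect_equal(oriented$dosage[oriented$snp_id == "rs2"], c(1L, NA))
})

test_that("orientation errors when the counted allele matches neither panel allele", {
  g <- make_geno(matrix(1L, 1, 1), "case", snp_ids = "rs1",
                 counted = "T", other = "C")
  panel <- make_panel("rs1", 0.1, risk = "A", other = "G")
  expect_error(orient_to_risk_allele(g, panel), "allele mismatch.*rs1")
})

test_that("orientation is an involution under swapped panel allele labels", {
  set.seed(42)
  for (i in 1:5) {
    d <- matrix(sample(c(0:2, NA), 12, replace = TRUE), 4, 3)
    g <- make_geno(d, c("case", "control"), counted = "G", other = "A")
    panel <- make_panel(sprintf("m%02d", 1:3), runif(3),
                        risk = "A", other = "G")
    swapped <- dplyr::mutate(panel, tmp = risk_allele,
                             risk_allele = other_allele,
                             other_allele = tmp, tmp = NULL)
    twice <- orient_to_risk_allele(orient_to_risk_allele(g, panel), swapped)
    expect_equal(twice$dosage, g$dosage)
    expect_equal(snp_alleles(twice)$counted_allele, rep("G", 3))
  }
})

test_that("TSV write/read round trip reproduces a canonical table exactly", {
  set.seed(7)
  for (i in 1:5) {
    d <- matrix(sample(c(0:2, NA), 20, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 5, 4)
    d[1, ] <- 1L  # keep both alleles observed at every SNP
    g <- make_geno(d, c("case", "control", "unknown"), cohort = "coh")
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(g, path)
    back <- read_genotypes(path)
    # read canonicalizes column order/types; compare sorted contents
    key <- function(t) dplyr::arrange(t, sample_id, snp_id)
    expect_equal(key(back), key(g))
  }
})
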