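test_that("F1 (zero selfing generations) is uniformly heterozygous", {
  set.seed(1)
  cfg <- tiny_config(n_selfing_generations = 0)
  truth <- simulate_ril_genotypes(cfg)
  expect_true(all(truth$genotypes == 1L))
})

test_that("residual heterozygosity matches the selfing expectation (1/2)^g", {
  set.seed(2)
  cfg <- sim_config(n_lines = 10000, n_bulk = 10, n_chromosomes = 1,
                    chrom_length_bp = 1e6, n_snps = 1,
                    n_selfing_generations = 5, qtl_list = NULL)
  truth <- simulate_ril_genotypes(cfg)
  het <- mean(truth$genotypes == 1L)
  p <- 0.5^5
  tol <- 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(het - p), tol)
})

test_that("selfing is symmetric: both homozygote classes equally frequent", {
  set.seed(3)
  cfg <- sim_config(n_lines = 500, n_bulk = 30, n_chromosomes = 4,
                    chrom_length_bp = 10e6, n_snps = 200, qtl_list = NULL)
  truth <- simulate_ril_genotypes(cfg)
  f_p1 <- mean(truth$genotypes == 0L)
  f_p2 <- mean(truth$genotypes == 2L)
  expected <- (1 - 0.5^5) / 2
  expect_lt(abs(f_p1 - expected), 0.02)
  expect_lt(abs(f_p2 - expected), 0.02)
})

test_that("zero chromosomes or loci is an error", {
  expect_error(sim_config(n_chromosomes = 0), "n_chromosomes")
  expect_error(sim_config(n_snps = 0), "n_snps")
})

test_that("phenotypes follow the additive model exactly when noise is zero", {
  set.seed(4)
  cfg <- tiny_config(qtl_list = NULL, phenotype_noise_sd = 0, baseline = 5)
  truth <- simulate_ril_genotypes(cfg)
  truth <- simulate_phenotypes(truth, cfg)
  expect_true(all(truth$phenotype == 5))

  cfg1 <- tiny_config(qtl_list = tibble::tibble(chrom = "chr1", pos = 2.5e6,
                                                effect = 28, origin = "P2"),
                      phenotype_noise_sd = 0, baseline = 5)
  set.seed(4)
  truth1 <- simulate_ril_genotypes(cfg1)
  truth1 <- simulate_phenotypes(truth1, cfg1)
  expect_true(all(truth1$phenotype %in% c(5, 19, 33)))
  expect_equal(max(truth1$phenotype) - min(truth1$phenotype), 28)
})

test_that("QTL positions off the marker grid are snapped and recorded", {
  set.seed(5)
  cfg <- tiny_config()
  truth <- simulate_ril_genotypes(cfg)
  truth <- simulate_phenotypes(truth, cfg)
  expect_true(truth$qtl$snapped_pos %in%
                truth$loci$pos[truth$loci$chrom == "chr1"])
  expect_equal(truth$loci$pos[truth$qtl$locus_index], truth$qtl$snapped_pos)
})

test_that("antagonistic QTLs produce bidirectional transgressive segregation", {
  set.seed(6)
  cfg <- sim_config(n_lines = 300, n_bulk = 30, n_chromosomes = 2,
                    chrom_length_bp = 10e6, n_snps = 200,
                    qtl_list = tibble::tibble(
                      chrom = c("chr1", "chr2"), pos = c(5e6, 5e6),
                      effect = c(10, 8), origin = c("P2", "P1")),
                    phenotype_noise_sd = 0, baseline = 2)
  truth <- simulate_ril_genotypes(cfg)
  truth <- simulate_phenotypes(truth, cfg)
  p1_value <- 2 + 8    # all-P1 genome carries the P1-origin effect
  p2_value <- 2 + 10
  expect_lt(min(truth$phenotype), min(p1_value, p2_value))
  expect_gt(max(truth$phenotype), max(p1_value, p2_value))
})

test_that("bulk selection takes disjoint extreme tails with index tie-break", {
  pheno <- stats::rnorm(204)
  b <- select_bulks(pheno, 30)
  expect_equal(sum(b == "high"), 30)
  expect_equal(sum(b == "low"), 30)
  expect_equal(sum(b == "high" & b == "low"), 0)
  expect_true(min(pheno[b == "high"]) >= max(pheno[b == "none"]))
  expect_true(max(pheno[b == "low"]) <= min(pheno[b == "none"]))

  tied <- rep(1, 204)
  bt <- select_bulks(tied, 30)
  expect_equal(which(bt == "low"), 1:30)
  expect_equal(which(bt == "high"), 175:204)

  expect_error(select_bulks(pheno, 103), "n_bulk")
})

test_that("a bulk fixed for the alternate allele yields pure alt reads", {
  cfg <- tiny_config(error_rate = 0)
  truth <- list(loci = tibble::tibble(chrom = "chr1", pos = c(1e5, 2e5)),
                genotypes = matrix(2L, nrow = 20, ncol = 2),
                qtl = tibble::tibble(locus_index = integer()),
                bulk = c(rep("high", 10), rep("low", 10)),
                config = cfg)
  class(truth) <- "sim_truth"
  set.seed(7)
  adt <- simulate_allele_depths(truth, cfg)
  expect_true(all(adt$ad_high_ref == 0))
  expect_true(all(adt$ad_low_ref == 0))
  expect_true(all(adt$ad_high_alt + adt$ad_high_ref ==
                    adt$ad_high_alt))
})

test_that("bulk allele-frequency divergence is large at the QTL, small away", {
  cfg <- sim_config(n_lines = 204, n_bulk = 30, n_chromosomes = 2,
                    chrom_length_bp = 20e6, n_snps = 300,
                    qtl_list = tibble::tibble(chrom = "chr1", pos = 10e6,
                                              effect = 15, origin = "P2"),
                    phenotype_noise_sd = 3, seed = 8)
  sim <- simulate_bsa(cfg)
  adt <- sim$depths
  fh <- adt$ad_high_alt / (adt$ad_high_ref + adt$ad_high_alt)
  fl <- adt$ad_low_alt / (adt$ad_low_ref + adt$ad_low_alt)
  df <- abs(fh - fl)
  at_qtl <- which(adt$chrom == "chr1" &
                    abs(adt$pos - sim$truth$qtl$snapped_pos) < 5e5)
  far <- which(adt$chrom == "chr2")    # unlinked chromosome
  expect_gt(mean(df[at_qtl], na.rm = TRUE), 0.5)
  expect_lt(mean(df[far], na.rm = TRUE), 0.3)
  expect_gt(mean(df[at_qtl], na.rm = TRUE), 2 * mean(df[far], na.rm = TRUE))
  # sign follows the effect direction: high bulk enriched for the P2 allele
  expect_gt(mean((fh - fl)[at_qtl], na.rm = TRUE), 0.5)
})

test_that("simulator outputs are byte-identical for a fixed seed", {
  cfg <- tiny_config()
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_bsa(cfg, outdir = d1)
  simulate_bsa(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth and VCF are mutually consistent", {
  # with no sequencing error and deep bulks, bulk read frequencies must
  # track the allele frequencies recomputable from genotypes + membership
  cfg <- tiny_config(error_rate = 0, bulk_depth_mean = 2000)
  sim <- simulate_bsa(cfg)
  truth <- sim$truth
  hi <- truth$bulk == "high"
  f_true <- colMeans(truth$genotypes[hi, , drop = FALSE]) / 2
  f_obs <- sim$depths$ad_high_alt /
    (sim$depths$ad_high_ref + sim$depths$ad_high_alt)
  expect_lt(max(abs(f_true - f_obs)), 0.05)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_bulk = 150), "n_bulk")
  expect_error(sim_config(impact_probs = c(HIGH = 0.5, MODERATE = 0.5,
                                           LOW = 0.5, MODIFIER = 0.5)),
               "sum to 1")
  expect_error(sim_config(qtl_list = tibble::tibble(
    chrom = "chr1", pos = 99e6, effect = 1, origin = "P2")), "position")
  expect_error(sim_config(parent_depth_mean = 0), "depths")
})
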