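# Small shared fixtures built in code.

# A fast, small simulation design for unit tests.
tiny_config <- function(...) {
  args <- list(n_lines = 60, n_bulk = 10, n_chromosomes = 2,
               chrom_length_bp = 5e6, n_snps = 120,
               qtl_list = tibble::tibble(chrom = "chr1", pos = 2.5e6,
                                         effect = 12, origin = "P2"),
               phenotype_noise_sd = 3, seed = 42)
  args <- utils::modifyList(args, list(...), keep.null = TRUE)
  do.call(sim_config, args)
}

# Hand-built allele-depth rows; every AD defaults to a clean polymorphic,
# well-covered SNP so individual fields can be perturbed per test.
make_adt <- function(n = 1, chrom = "chr1", pos = seq_len(n) * 1000,
                     p1 = c(10, 0), p2 = c(0, 10),
                     high = c(15, 15), low = c(15, 15),
                     variant_class = "SNP", impact = "MODIFIER") {
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = pos,
    ref = "A", alt = "C",
    variant_class = rep_len(variant_class, n),
    impact = rep_len(impact, n),
    ad_p1_ref = rep_len(p1[1], n), ad_p1_alt = rep_len(p1[2], n),
    ad_p2_ref = rep_len(p2[1], n), ad_p2_alt = rep_len(p2[2], n),
    ad_high_ref = rep_len(high[1], n), ad_high_alt = rep_len(high[2], n),
    ad_low_ref = rep_len(low[1], n), ad_low_alt = rep_len(low[2], n))
}

# Minimal genome_scan stand-in for region-calling tests.
make_scan <- function(chrom, pos, above, method = "ED4") {
  scan <- list(
    loci = tibble::tibble(chrom = chrom, pos = pos,
                          raw_stat = as.numeric(above),
                          smoothed_stat = as.numeric(above),
                          above_threshold = above),
    method = method, window_bp = 1e6, step_bp = 5e4,
    threshold_quantile = 0.995, threshold = 0.5,
    n_zero_depth_dropped = 0L)
  class(scan) <- "genome_scan"
  scan
}

# Independent G oracle: algebraic entropy form of the 2x2 likelihood-ratio
# statistic, G = 2 * (sum n ln n - sum row ln row - sum col ln col + N ln N).
g_oracle <- function(n11, n12, n21, n22) {
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  N <- n11 + n12 + n21 + n22
  2 * (xlx(n11) + xlx(n12) + xlx(n21) + xlx(n22) -
         xlx(n11 + n12) - xlx(n21 + n22) -
         xlx(n11 + n21) - xlx(n12 + n22) + xlx(N))
}
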