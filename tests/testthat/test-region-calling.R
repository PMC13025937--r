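test_that("contiguous above-threshold loci become one region; <10 loci none", {
  pos <- seq(1e6, 1e6 + 11 * 5e4, by = 5e4)          # 12 loci, 50 kb apart
  scan <- make_scan(rep("chr1", 12), pos, rep(TRUE, 12))
  r <- call_regions(scan)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, pos[1])
  expect_equal(r$end, pos[12])
  expect_equal(r$n_loci_above_threshold, 12L)

  scan9 <- make_scan(rep("chr1", 9), pos[1:9], rep(TRUE, 9))
  r9 <- call_regions(scan9)
  expect_equal(nrow(r9), 0L)
  expect_equal(attr(r9, "n_removed_min_loci"), 1L)
})

test_that("runs separated by more than the merge gap split into regions", {
  pos <- c(seq(1e6, 1e6 + 10 * 5e4, by = 5e4),
           seq(5e6, 5e6 + 10 * 5e4, by = 5e4))       # two 11-locus runs, 3.5 Mb apart
  scan <- make_scan(rep("chr1", 22), pos, rep(TRUE, 22))
  r <- call_regions(scan, merge_gap = 1e6)
  expect_equal(nrow(r), 2L)
  r_merged <- call_regions(scan, merge_gap = 5e6)
  expect_equal(nrow(r_merged), 1L)
})

test_that("effective-variant filter retains only regions with HIGH/MODERATE", {
  regions <- tibble::tibble(
    chrom = c("chr1", "chr1"), start = c(1e6, 5e6), end = c(2e6, 6e6),
    span_mb = c(1, 1), method = "ED4",
    n_loci_above_threshold = c(12L, 12L))
  variants <- make_adt(n = 3, pos = c(1.5e6, 5.2e6, 5.8e6),
                       impact = c("MODERATE", "MODIFIER", "LOW"))
  kept <- effective_variant_filter(regions, variants)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 1e6)
  expect_equal(kept$n_effective_variants, 1L)
  expect_equal(attr(kept, "n_removed_no_effective"), 1L)

  # filters: output subset of input, idempotent, empty in -> empty out
  again <- effective_variant_filter(kept, variants)
  expect_equal(as.data.frame(again), as.data.frame(kept),
               ignore_attr = TRUE)
  empty <- effective_variant_filter(regions[0, ], variants)
  expect_equal(nrow(empty), 0L)
})

test_that("region intersection reproduces the two-method consensus interval", {
  ed <- tibble::tibble(chrom = "chr4", start = 44205775, end = 45290843,
                       span_mb = span_mb(44205775, 45290843), method = "ED4")
  gp <- tibble::tibble(chrom = "chr4", start = 44205775, end = 49493701,
                       span_mb = span_mb(44205775, 49493701), method = "Gprime")
  cons <- intersect_regions(ed, gp)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 44205775)
  expect_equal(cons$end, 45290843)
  expect_equal(cons$method, "consensus")

  disjoint <- tibble::tibble(chrom = "chr4", start = 1e6, end = 2e6,
                             span_mb = 1, method = "Gprime")
  expect_equal(nrow(intersect_regions(ed, disjoint)), 0L)
  identical_in <- intersect_regions(ed, ed)
  expect_equal(identical_in$start, ed$start)
  expect_equal(identical_in$end, ed$end)
  # different chromosomes never intersect
  other <- tibble::tibble(chrom = "chr5", start = 44205775, end = 49493701,
                          span_mb = 5.29, method = "Gprime")
  expect_equal(nrow(intersect_regions(ed, other)), 0L)
})

test_that("consensus intervals are contained in both parents' intervals", {
  set.seed(3)
  mk <- function(n, chrom) {
    s <- sort(sample.int(2e7, n))
    tibble::tibble(chrom = chrom, start = s, end = s + sample.int(3e6, n),
                   span_mb = 0, method = "x")
  }
  a <- rbind(mk(8, "chr1"), mk(8, "chr2"))
  b <- rbind(mk(8, "chr1"), mk(8, "chr2"))
  cons <- intersect_regions(a, b)
  for (i in seq_len(nrow(cons))) {
    in_a <- any(a$chrom == cons$chrom[i] & a$start <= cons$start[i] &
                  a$end >= cons$end[i])
    in_b <- any(b$chrom == cons$chrom[i] & b$start <= cons$start[i] &
                  b$end >= cons$end[i])
    expect_true(in_a && in_b)
  }
})

test_that("interval spans reproduce reported megabase arithmetic", {
  expect_equal(span_mb(6250656, 6744665), 0.49)
  expect_equal(span_mb(135428709, 136732132), 1.30)
  expect_equal(span_mb(5e6, 5e6), 0)
})

test_that("gene counting uses any-overlap on closed intervals", {
  regions <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6,
                            span_mb = 1, method = "consensus")
  genes <- tibble::tibble(
    gene_id = c("inside", "edge_left", "edge_right", "outside_left",
                "outside_right", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1.4e6, 0.9e6, 2e6, 0.5e6, 2.1e6, 1.4e6),
    end = c(1.5e6, 1e6, 2.4e6, 0.99e6, 2.5e6, 1.5e6))
  out <- count_genes(regions, genes)
  expect_equal(out$n_genes, 3L)
  expect_setequal(out$gene_ids[[1]], c("inside", "edge_left", "edge_right"))
})

test_that("raising the threshold quantile never grows the called span", {
  sim <- simulate_bsa(sim_config(n_lines = 120, n_bulk = 20,
                                 n_chromosomes = 2, chrom_length_bp = 20e6,
                                 n_snps = 500,
                                 qtl_list = tibble::tibble(
                                   chrom = "chr1", pos = 10e6,
                                   effect = 12, origin = "P2"),
                                 seed = 31))
  adt <- filter_loci(sim$depths)
  spans <- sapply(c(0.95, 0.98, 0.995, 0.999), function(q) {
    scan <- genome_scan(adt, "ED4", threshold_quantile = q)
    r <- call_regions(scan, min_loci = 10)
    sum(r$end - r$start)
  })
  expect_true(all(diff(spans) <= 0))
})

test_that("region calling is deterministic for identical inputs", {
  sim <- simulate_bsa(tiny_config())
  adt <- filter_loci(sim$depths)
  s1 <- genome_scan(adt, "Gprime")
  s2 <- genome_scan(adt, "Gprime")
  expect_equal(call_regions(s1, min_loci = 1), call_regions(s2, min_loci = 1))
})
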