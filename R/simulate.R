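#' Simulate RIL genotypes by recurrent selfing with recombination
#'
#' Starts from a uniformly heterozygous F1 (one haplotype from each inbred
#' parent) and applies `n_selfing_generations` rounds of selfing. Every
#' meiosis draws a Poisson number of crossovers per chromosome under the
#' Haldane map (`cm_per_mb` converts physical to genetic length), so lines
#' are mosaics of parental blocks with the expected residual per-locus
#' heterozygosity of (1/2)^g after g selfing generations.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_truth` list with `loci` (tibble: `chrom`, `pos`) and
#'   `genotypes` (integer matrix, lines x loci; 0 = P1 homozygote,
#'   1 = heterozygote, 2 = P2 homozygote).
#' @export
simulate_ril_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_chromosomes < 1L || config$n_snps < 1L)
    stop("need at least one chromosome and one locus", call. = FALSE)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  morgan_len <- config$chrom_length_bp / 1e6 * config$cm_per_mb / 100

  loci_list <- vector("list", length(chroms))
  geno_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(config$chrom_length_bp, config$n_snps))
    # F1 haplotypes: 0 = P1 allele, 1 = P2 allele
    h1 <- matrix(0L, config$n_lines, config$n_snps)
    h2 <- matrix(1L, config$n_lines, config$n_snps)
    g <- 0L
    while (g < config$n_selfing_generations) {
      g1 <- meiosis_gametes(h1, h2, pos, morgan_len, config$chrom_length_bp)
      g2 <- meiosis_gametes(h1, h2, pos, morgan_len, config$chrom_length_bp)
      h1 <- g1
      h2 <- g2
      g <- g + 1L
    }
    loci_list[[ci]] <- tibble::tibble(chrom = chroms[ci], pos = pos)
    geno_list[[ci]] <- h1 + h2
  }

  truth <- list(
    loci = do.call(rbind, loci_list),
    genotypes = do.call(cbind, geno_list),
    config = config
  )
  class(truth) <- "sim_truth"
  truth
}

# One gamete per line from haplotype matrices h1/h2 (lines x loci).
# Crossover count ~ Poisson(morgan_len); breakpoints uniform on [0, len_bp].
meiosis_gametes <- function(h1, h2, pos, morgan_len, len_bp) {
  n <- nrow(h1)
  k <- stats::rpois(n, morgan_len)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  out <- matrix(0L, n, ncol(h1))
  plain <- k == 0L
  if (any(plain & start == 0L))
    out[plain & start == 0L, ] <- h1[plain & start == 0L, , drop = FALSE]
  if (any(plain & start == 1L))
    out[plain & start == 1L, ] <- h2[plain & start == 1L, , drop = FALSE]
  for (i in which(!plain)) {
    xp <- sort(stats::runif(k[i], min = 0, max = len_bp))
    seg <- findInterval(pos, xp)
    use2 <- (seg + start[i]) %% 2L == 1L
    row <- h1[i, ]
    row[use2] <- h2[i, use2]
    out[i, ] <- row
  }
  out
}

#' Add additive phenotypes to a simulated population
#'
#' Phenotype (mg g^-1 soluble-sugar reduction over 0-72 h of storage) is
#' `baseline + sum over QTLs of effect * dosage + N(0, phenotype_noise_sd)`,
#' with dosage 0 / 0.5 / 1 counting the origin parent's allele. A QTL whose
#' position is not a simulated locus is snapped to the nearest locus on its
#' chromosome; the snapped position is recorded in `truth$qtl`.
#'
#' @param truth A `sim_truth` from [simulate_ril_genotypes()].
#' @param config The same [sim_config()].
#' @return `truth` with `phenotype` (numeric vector per line) and `qtl`
#'   (tibble with `locus_index` and `snapped_pos`) added.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- nrow(truth$genotypes)
  pheno <- rep(config$baseline, n)
  qtl <- config$qtl_list
  if (!is.null(qtl) && nrow(qtl) > 0) {
    qtl$locus_index <- NA_integer_
    qtl$snapped_pos <- NA_real_
    for (i in seq_len(nrow(qtl))) {
      on_chrom <- which(truth$loci$chrom == qtl$chrom[i])
      if (length(on_chrom) == 0L)
        stop("no simulated loci on QTL chromosome ", qtl$chrom[i],
             call. = FALSE)
      j <- on_chrom[which.min(abs(truth$loci$pos[on_chrom] - qtl$pos[i]))]
      qtl$locus_index[i] <- j
      qtl$snapped_pos[i] <- truth$loci$pos[j]
      dosage <- truth$genotypes[, j] / 2           # dose of the P2 allele
      if (qtl$origin[i] == "P1") dosage <- 1 - dosage
      pheno <- pheno + qtl$effect[i] * dosage
    }
  } else {
    qtl <- tibble::tibble(chrom = character(), pos = numeric(),
                          effect = numeric(), origin = character(),
                          locus_index = integer(), snapped_pos = numeric())
  }
  pheno <- pheno + stats::rnorm(n, 0, config$phenotype_noise_sd)
  truth$phenotype <- pheno
  truth$qtl <- tibble::as_tibble(qtl)
  truth
}

#' Select extreme-phenotype bulks
#'
#' The high bulk is the `n_bulk` lines with the largest sugar reduction and
#' the low bulk the `n_bulk` smallest. Ties are broken by line index
#' (ascending), so with all phenotypes equal the low bulk is the first
#' `n_bulk` lines and the high bulk the last `n_bulk`.
#'
#' @param phenotypes Numeric vector of per-line phenotypes.
#' @param n_bulk Lines per bulk; must not exceed `length(phenotypes)/2`.
#' @return Character vector (`"low"`, `"high"`, `"none"`) per line.
#' @export
select_bulks <- function(phenotypes, n_bulk) {
  n <- length(phenotypes)
  n_bulk <- as.integer(n_bulk)
  if (n_bulk < 1L || n_bulk > n / 2)
    stop("n_bulk must be between 1 and n_lines/2", call. = FALSE)
  ord <- order(phenotypes, seq_len(n))
  membership <- rep("none", n)
  membership[ord[seq_len(n_bulk)]] <- "low"
  membership[ord[seq.int(n - n_bulk + 1L, n)]] <- "high"
  membership
}

#' Simulate pooled sequencing allele depths
#'
#' Parent 1 carries the reference allele and parent 2 the alternate allele
#' at every locus. Per locus, each parent's depth is Poisson with mean
#' `parent_depth_mean` and reads are drawn with per-read error
#' `error_rate`; each bulk's alternate-allele frequency is the mean P2
#' dosage over its member lines, its depth Poisson with mean
#' `bulk_depth_mean` and its alternate read count Binomial(depth,
#' error-adjusted frequency). Impact classes are drawn from
#' `impact_probs`, except causal QTL loci which receive `qtl_impact`;
#' a fraction `indel_fraction` of non-causal loci is labelled InDel.
#' Zero-depth samples are possible and written as `0,0`.
#'
#' @param truth A `sim_truth` with `phenotype` and `bulk` (or `bulk` set by
#'   [select_bulks()]; [simulate_bsa()] wires these together).
#' @param config The [sim_config()].
#' @return An allele-depth tibble with one row per locus: `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class`, `impact`, and `ad_*_ref` / `ad_*_alt`
#'   counts for `p1`, `p2`, `high`, `low`.
#' @export
simulate_allele_depths <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), !is.null(truth$bulk))
  n_loci <- nrow(truth$loci)
  e <- config$error_rate

  dp1 <- stats::rpois(n_loci, config$parent_depth_mean)
  a1 <- stats::rbinom(n_loci, dp1, e)               # P1 is ref-fixed
  dp2 <- stats::rpois(n_loci, config$parent_depth_mean)
  r2 <- stats::rbinom(n_loci, dp2, e)               # P2 is alt-fixed

  high <- truth$bulk == "high"
  low <- truth$bulk == "low"
  f_high <- colMeans(truth$genotypes[high, , drop = FALSE]) / 2
  f_low <- colMeans(truth$genotypes[low, , drop = FALSE]) / 2
  fh <- f_high * (1 - 2 * e) + e
  fl <- f_low * (1 - 2 * e) + e
  dph <- stats::rpois(n_loci, config$bulk_depth_mean)
  dpl <- stats::rpois(n_loci, config$bulk_depth_mean)
  ah <- stats::rbinom(n_loci, dph, fh)
  al <- stats::rbinom(n_loci, dpl, fl)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3L, n_loci, replace = TRUE) - 1L) %% 4L + 1L]
  variant_class <- ifelse(stats::runif(n_loci) < config$indel_fraction,
                          "InDel", "SNP")
  alt[variant_class == "InDel"] <- paste0(ref[variant_class == "InDel"], "T")
  impact <- sample(names(config$impact_probs), n_loci, replace = TRUE,
                   prob = config$impact_probs)
  if (nrow(truth$qtl) > 0) {
    idx <- truth$qtl$locus_index
    variant_class[idx] <- "SNP"
    alt[idx] <- bases[(match(ref[idx], bases)) %% 4L + 1L]
    impact[idx] <- config$qtl_impact
  }

  tibble::tibble(
    chrom = truth$loci$chrom, pos = truth$loci$pos,
    ref = ref, alt = alt,
    variant_class = variant_class, impact = impact,
    ad_p1_ref = dp1 - a1, ad_p1_alt = a1,
    ad_p2_ref = r2, ad_p2_alt = dp2 - r2,
    ad_high_ref = dph - ah, ad_high_alt = ah,
    ad_low_ref = dpl - al, ad_low_alt = al
  )
}

#' Write an allele-depth table as a four-sample VCF
#'
#' Emits VCF 4.2 with samples `P1`, `P2`, `HighBulk`, `LowBulk`, FORMAT
#' `AD` (ref,alt) and INFO keys `IMPACT` and `VT` (SNP/InDel).
#'
#' @param adt Allele-depth tibble from [simulate_allele_depths()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(adt, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan",
    '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted variant impact (HIGH/MODERATE/LOW/MODIFIER)">',
    '##INFO=<ID=VT,Number=1,Type=String,Description="Variant class (SNP or InDel)">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">'
  )
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "P1", "P2", "HighBulk", "LowBulk",
                      sep = "\t"))
  body <- paste(
    adt$chrom, format(adt$pos, scientific = FALSE, trim = TRUE), ".",
    adt$ref, adt$alt, ".", "PASS",
    paste0("IMPACT=", adt$impact, ";VT=", adt$variant_class), "AD",
    paste0(adt$ad_p1_ref, ",", adt$ad_p1_alt),
    paste0(adt$ad_p2_ref, ",", adt$ad_p2_alt),
    paste0(adt$ad_high_ref, ",", adt$ad_high_alt),
    paste0(adt$ad_low_ref, ",", adt$ad_low_alt),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Synthetic gene models tiled along the simulated genome
#'
#' Non-overlapping genes of fixed length placed on a regular grid, dense
#' enough (one gene per 50 kb by default) that candidate intervals contain
#' gene sets of the same order as real crop annotations.
#'
#' @param config A [sim_config()].
#' @param gene_length Gene span in bp.
#' @param gene_spacing Distance between gene starts in bp.
#' @return A gene tibble: `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
gene_annotation_table <- function(config, gene_length = 4000,
                                  gene_spacing = 50000) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  per_chrom <- lapply(chroms, function(ch) {
    starts <- seq(10001, config$chrom_length_bp - gene_length, by = gene_spacing)
    tibble::tibble(
      gene_id = sprintf("SYNGENE_%s_%05d", ch, seq_along(starts)),
      chrom = ch,
      start = starts,
      end = starts + gene_length - 1
    )
  })
  do.call(rbind, per_chrom)
}

#' Write the synthetic gene annotation as GFF3
#'
#' @param genes Gene tibble from [gene_annotation_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    paste(genes$chrom, "bsascan", "gene",
          format(genes$start, scientific = FALSE, trim = TRUE),
          format(genes$end, scientific = FALSE, trim = TRUE),
          ".", "+", ".",
          paste0("ID=", genes$gene_id, ";Name=", genes$gene_id),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete BSA-seq experiment
#'
#' One call covering the whole generator: seeds the RNG from
#' `config$seed`, simulates genotypes, phenotypes, bulk membership and
#' pooled allele depths, and (optionally) writes the VCF, GFF3, phenotype
#' table, truth tables and resolved config to `outdir`. With the seed
#' fixed all outputs are byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory; created if missing.
#' @return A list with `truth` (`sim_truth`: loci, genotypes, phenotype,
#'   bulk, qtl), `depths` (allele-depth tibble) and `genes` (gene tibble).
#' @export
simulate_bsa <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed)
  truth <- simulate_ril_genotypes(config)
  truth <- simulate_phenotypes(truth, config)
  truth$bulk <- select_bulks(truth$phenotype, config$n_bulk)
  depths <- simulate_allele_depths(truth, config)
  genes <- gene_annotation_table(config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    contigs <- stats::setNames(rep(config$chrom_length_bp,
                                   config$n_chromosomes),
                               paste0("chr", seq_len(config$n_chromosomes)))
    write_sim_vcf(depths, file.path(outdir, "bulks.vcf"), contigs)
    write_gene_annotation(genes, file.path(outdir, "genes.gff3"))
    utils::write.table(
      phenotype_table_from_truth(truth),
      file.path(outdir, "phenotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      tibble::tibble(line_id = sprintf("RIL_%03d", seq_len(config$n_lines)),
                     phenotype = truth$phenotype, bulk = truth$bulk),
      file.path(outdir, "truth_lines.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$qtl, file.path(outdir, "truth_qtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_out <- truth$config
    cfg_out$qtl_list <- if (is.null(cfg_out$qtl_list)) NULL else
      as.data.frame(cfg_out$qtl_list)
    yaml::write_yaml(unclass(cfg_out), file.path(outdir, "config.yaml"))
  }

  list(truth = truth, depths = depths, genes = genes)
}

#' Absolute sugar contents derived from simulated reductions
#'
#' The simulator's phenotype is the 0-72 h soluble-sugar reduction; for the
#' phenotype table, absolute contents are derived around a 0 h content of
#' 84.47 mg g^-1 (population mean reported for the emulated design), with
#' 60% of the total reduction realized by 8 h.
#'
#' @param truth A `sim_truth` with phenotypes.
#' @param c0_mean Mean 0 h soluble-sugar content, mg g^-1.
#' @param c0_sd Between-line SD of the 0 h content, mg g^-1.
#' @return Tibble `line_id`, `sugar_0h`, `sugar_8h`, `sugar_72h`.
#' @export
phenotype_table_from_truth <- function(truth, c0_mean = 84.47, c0_sd = 6) {
  n <- length(truth$phenotype)
  c0 <- stats::rnorm(n, c0_mean, c0_sd)
  red <- truth$phenotype
  tibble::tibble(
    line_id = sprintf("RIL_%03d", seq_len(n)),
    sugar_0h = round(c0, 2),
    sugar_8h = round(c0 - 0.6 * red, 2),
    sugar_72h = round(c0 - red, 2)
  )
}
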