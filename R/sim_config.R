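#' Default QTL panel for the simulator
#'
#' Three additive QTLs emulating a multi-locus postharvest sugar-degradation
#' architecture: two degradation-promoting alleles contributed by the
#' high-degradation parent (P2) and one by the low-degradation parent (P1),
#' which produces the bidirectional transgressive segregation seen in
#' biparental RIL populations for this trait.
#'
#' @return A tibble with columns `chrom`, `pos` (bp), `effect`
#'   (mg g^-1 sugar reduction added per dose of the origin parent's allele)
#'   and `origin` (`"P1"` or `"P2"`).
#' @export
default_qtl_list <- function() {
  tibble::tibble(
    chrom  = c("chr4", "chr2", "chr10"),
    pos    = c(15e6, 6.5e6, 22.5e6),
    effect = c(12, 8, 6),
    origin = c("P2", "P2", "P1")
  )
}

#' Simulation configuration for a RIL BSA-seq experiment
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults describe the emulated study design: an F6 RIL population of 204
#' lines from two inbred parents, extreme bulks of 30 lines per tail, and
#' pooled whole-genome sequencing at ~10x (parents) / ~30x (bulks), on a
#' scaled-down 10-chromosome genome (30 Mb per chromosome, 600 SNP loci
#' each, so a 1 Mb smoothing window holds ~20 markers).
#'
#' @param n_lines Number of RIL families (default 204).
#' @param n_bulk Lines per extreme bulk (default 30); must be <= n_lines/2.
#' @param n_chromosomes Number of chromosomes, named `chr1..chrN`.
#' @param chrom_length_bp Physical length of every chromosome in bp.
#' @param n_snps Variant loci per chromosome (uniformly placed).
#' @param n_selfing_generations Selfing generations after the F1; 5 gives an
#'   F6 with expected residual heterozygosity (1/2)^5 per locus.
#' @param cm_per_mb Recombination rate used by the Haldane map (cM per Mb).
#' @param qtl_list Tibble of QTLs (`chrom`, `pos`, `effect`, `origin`) or
#'   `NULL` for a null (no-QTL) population.
#' @param baseline Phenotype intercept, mg g^-1 soluble-sugar reduction over
#'   0-72 h for a line carrying zero effect alleles.
#' @param phenotype_noise_sd Residual (environmental) SD, mg g^-1.
#' @param parent_depth_mean Mean Poisson sequencing depth per parent sample.
#' @param bulk_depth_mean Mean Poisson sequencing depth per bulk.
#' @param impact_probs Named probability vector over SnpEff-style impact
#'   classes HIGH/MODERATE/LOW/MODIFIER for non-causal loci.
#' @param indel_fraction Fraction of loci labelled InDel. InDels are kept
#'   out of the genome scans and used only for effective-variant
#'   bookkeeping.
#' @param error_rate Per-read allele flip probability (sequencing error).
#' @param qtl_impact Impact class assigned to causal QTL loci; the default
#'   `"MODERATE"` encodes that a causal variant is itself a functional
#'   (effective) variant.
#' @param seed Integer seed consumed by [simulate_bsa()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_bsa()] for the one-call generator.
#' @export
sim_config <- function(n_lines = 204L,
                       n_bulk = 30L,
                       n_chromosomes = 10L,
                       chrom_length_bp = 30e6,
                       n_snps = 600L,
                       n_selfing_generations = 5L,
                       cm_per_mb = 1,
                       qtl_list = default_qtl_list(),
                       baseline = 1.0,
                       phenotype_noise_sd = 5,
                       parent_depth_mean = 10,
                       bulk_depth_mean = 30,
                       impact_probs = c(HIGH = 0.002, MODERATE = 0.01,
                                        LOW = 0.05, MODIFIER = 0.938),
                       indel_fraction = 0.1,
                       error_rate = 0.001,
                       qtl_impact = "MODERATE",
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines),
    n_bulk = as.integer(n_bulk),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps = as.integer(n_snps),
    n_selfing_generations = as.integer(n_selfing_generations),
    cm_per_mb = as.numeric(cm_per_mb),
    qtl_list = qtl_list,
    baseline = as.numeric(baseline),
    phenotype_noise_sd = as.numeric(phenotype_noise_sd),
    parent_depth_mean = as.numeric(parent_depth_mean),
    bulk_depth_mean = as.numeric(bulk_depth_mean),
    impact_probs = impact_probs,
    indel_fraction = as.numeric(indel_fraction),
    error_rate = as.numeric(error_rate),
    qtl_impact = as.character(qtl_impact),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lines >= 2L, cfg$n_chromosomes >= 1L, cfg$n_snps >= 1L,
            cfg$chrom_length_bp >= 1, cfg$n_selfing_generations >= 0L,
            cfg$cm_per_mb >= 0, cfg$phenotype_noise_sd >= 0)
  if (cfg$n_bulk < 1L || cfg$n_bulk > cfg$n_lines / 2)
    stop("n_bulk must be between 1 and n_lines/2", call. = FALSE)
  if (cfg$parent_depth_mean <= 0 || cfg$bulk_depth_mean <= 0)
    stop("sequencing depths must be > 0", call. = FALSE)
  p <- cfg$impact_probs
  if (!setequal(names(p), c("HIGH", "MODERATE", "LOW", "MODIFIER")))
    stop("impact_probs must be named HIGH, MODERATE, LOW, MODIFIER",
         call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("impact_probs must be non-negative and sum to 1", call. = FALSE)
  if (cfg$indel_fraction < 0 || cfg$indel_fraction >= 1)
    stop("indel_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  if (!cfg$qtl_impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER"))
    stop("qtl_impact must be one of HIGH/MODERATE/LOW/MODIFIER", call. = FALSE)
  if (!is.null(cfg$qtl_list) && nrow(cfg$qtl_list) > 0) {
    q <- cfg$qtl_list
    stopifnot(all(c("chrom", "pos", "effect", "origin") %in% names(q)))
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    if (!all(q$chrom %in% chroms))
      stop("QTL chromosome not among simulated chromosomes", call. = FALSE)
    if (any(q$pos < 1 | q$pos > cfg$chrom_length_bp))
      stop("QTL position outside chromosome length", call. = FALSE)
    if (!all(q$origin %in% c("P1", "P2")))
      stop("QTL origin must be 'P1' or 'P2'", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  n_qtl <- if (is.null(x$qtl_list)) 0L else nrow(x$qtl_list)
  cat("BSA-seq simulation config\n")
  cat(sprintf("  population : %d F%d RIL lines, bulks of %d + %d\n",
              x$n_lines, x$n_selfing_generations + 1L, x$n_bulk, x$n_bulk))
  cat(sprintf("  genome     : %d chromosomes x %.0f Mb, %d loci each (%.1f cM/Mb)\n",
              x$n_chromosomes, x$chrom_length_bp / 1e6, x$n_snps, x$cm_per_mb))
  cat(sprintf("  sequencing : parents %.0fx, bulks %.0fx, error %.4f\n",
              x$parent_depth_mean, x$bulk_depth_mean, x$error_rate))
  cat(sprintf("  trait      : %d QTL(s), baseline %.2f, noise sd %.2f mg/g\n",
              n_qtl, x$baseline, x$phenotype_noise_sd))
  invisible(x)
}
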