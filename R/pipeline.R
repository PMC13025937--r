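#' Run the full BSA-seq association pipeline on a simulated experiment
#'
#' Orchestrates simulate -> filter -> scan (ED^4 and G') -> threshold ->
#' call regions -> effective-variant filter -> intersect -> count genes,
#' entirely in memory, and optionally writes every table to `outdir`.
#' The funnel log records locus and region counts at each stage.
#'
#' The minimum-marker rule (>= `min_loci_ed` above-threshold loci per
#' region) is applied to ED^4 regions; for G' regions it is off by
#' default (`min_loci_gprime = 1`), matching the asymmetric description
#' of the two methods' filters.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @param outdir Optional directory for simulator files and result
#'   tables.
#' @param window_bp,step_bp Smoothing window and ED^4 anchor step, bp.
#' @param threshold_quantile Empirical threshold quantile (default
#'   0.995).
#' @param merge_gap Region merge gap, bp (default 1 Mb).
#' @param min_loci_ed,min_loci_gprime Minimum above-threshold loci per
#'   region for each method.
#' @param min_depth_parent,min_depth_bulk,homozygosity_tol Locus filter
#'   settings (see [filter_loci()]).
#' @return List with `sim` (simulator output), `loci` (filtered scan
#'   table), `scans` (`ed4`, `gprime`), `regions` (`ed4`, `gprime`,
#'   `consensus`, all effective-variant-filtered, consensus with gene
#'   lists), and `funnel` (named counts).
#' @export
run_bsa_pipeline <- function(config = sim_config(),
                             outdir = NULL,
                             window_bp = 1e6, step_bp = 5e4,
                             threshold_quantile = 0.995,
                             merge_gap = 1e6,
                             min_loci_ed = 10, min_loci_gprime = 1,
                             min_depth_parent = 4, min_depth_bulk = 10,
                             homozygosity_tol = 0.1) {
  sim <- simulate_bsa(config, outdir = outdir)

  scan_loci <- filter_loci(sim$depths,
                           min_depth_parent = min_depth_parent,
                           min_depth_bulk = min_depth_bulk,
                           homozygosity_tol = homozygosity_tol,
                           snp_only = TRUE)
  # SNPs + InDels with the same quality filters, for effective-variant
  # assessment inside candidate intervals
  effect_loci <- filter_loci(sim$depths,
                             min_depth_parent = min_depth_parent,
                             min_depth_bulk = min_depth_bulk,
                             homozygosity_tol = homozygosity_tol,
                             snp_only = FALSE)

  ed <- genome_scan(scan_loci, "ED4", window_bp, step_bp,
                    threshold_quantile)
  gp <- genome_scan(scan_loci, "Gprime", window_bp, step_bp,
                    threshold_quantile)

  ed_called <- call_regions(ed, merge_gap, min_loci_ed)
  gp_called <- call_regions(gp, merge_gap, min_loci_gprime)
  ed_regions <- effective_variant_filter(ed_called, effect_loci)
  gp_regions <- effective_variant_filter(gp_called, effect_loci)
  consensus <- intersect_regions(ed_regions, gp_regions)
  consensus <- count_genes(consensus, sim$genes)

  funnel <- c(
    loci_simulated = nrow(sim$depths),
    loci_scanned = nrow(scan_loci),
    ed_regions_called = nrow(ed_called),
    ed_regions_retained = nrow(ed_regions),
    gprime_regions_called = nrow(gp_called),
    gprime_regions_retained = nrow(gp_regions),
    consensus_regions = nrow(consensus))

  res <- list(sim = sim,
              loci = scan_loci,
              scans = list(ed4 = ed, gprime = gp),
              regions = list(ed4 = ed_regions, gprime = gp_regions,
                             consensus = consensus),
              funnel = funnel)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_scan_track(ed, file.path(outdir, "scan_ed4.tsv"))
    write_scan_track(gp, file.path(outdir, "scan_gprime.tsv"))
    write_region_table(ed_regions, file.path(outdir, "regions_ed4.tsv"))
    write_region_table(gp_regions, file.path(outdir, "regions_gprime.tsv"))
    write_region_table(consensus, file.path(outdir, "regions_consensus.tsv"))
    writeLines(paste(names(funnel), funnel, sep = "\t"),
               file.path(outdir, "funnel.tsv"))
  }
  res
}

#' Write a genome-scan track as TSV
#'
#' Columns: chromosome, position, raw and smoothed statistic, and the
#' above-threshold flag.
#'
#' @param scan A `genome_scan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_track <- function(scan, path) {
  utils::write.table(scan$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a region table as TSV
#'
#' The `gene_ids` list-column, when present, is flattened to a
#' comma-separated string.
#'
#' @param regions Region tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  if ("gene_ids" %in% names(regions))
    regions$gene_ids <- vapply(regions$gene_ids, paste, character(1),
                               collapse = ",")
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
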