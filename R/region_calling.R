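#' Interval span in megabases
#'
#' `(end - start) / 1e6`, rounded to 2 decimal places (standard
#' round-half-even).
#'
#' @param start,end 1-based inclusive interval bounds in bp.
#' @return Span in Mb, 2 dp.
#' @export
span_mb <- function(start, end) {
  round((end - start) / 1e6, 2)
}

#' Call candidate regions from a thresholded genome scan
#'
#' Above-threshold loci on the same chromosome are merged into one region
#' while consecutive hits are no more than `merge_gap` bp apart; region
#' boundaries are the first and last above-threshold locus positions.
#' Regions supported by fewer than `min_loci` above-threshold loci are
#' discarded (count in attribute `n_removed_min_loci`).
#'
#' @param scan A `genome_scan` object from [genome_scan()].
#' @param merge_gap Maximum gap between consecutive hits in one region,
#'   bp (default 1 Mb, one smoothing window).
#' @param min_loci Minimum above-threshold loci per retained region
#'   (default 10).
#' @return Region tibble: `chrom`, `start`, `end`, `span_mb`, `method`,
#'   `n_loci_above_threshold`.
#' @export
call_regions <- function(scan, merge_gap = 1e6, min_loci = 10) {
  loci <- scan$loci[scan$loci$above_threshold, , drop = FALSE]
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    span_mb = numeric(), method = character(),
    n_loci_above_threshold = integer())
  if (nrow(loci) == 0L) {
    attr(empty, "n_removed_min_loci") <- 0L
    return(empty)
  }
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  parts <- split(loci, loci$chrom)
  regions <- lapply(parts, function(d) {
    cl <- cumsum(c(1, diff(d$pos) > merge_gap))
    do.call(rbind, lapply(split(d$pos, cl), function(p) {
      tibble::tibble(chrom = d$chrom[1], start = min(p), end = max(p),
                     n_loci_above_threshold = length(p))
    }))
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  small <- out$n_loci_above_threshold < min_loci
  out <- out[!small, , drop = FALSE]
  out$span_mb <- span_mb(out$start, out$end)
  out$method <- scan$method
  out <- out[, c("chrom", "start", "end", "span_mb", "method",
                 "n_loci_above_threshold")]
  out <- tibble::as_tibble(out)
  attr(out, "n_removed_min_loci") <- sum(small)
  out
}

#' Retain regions containing at least one effective variant
#'
#' An effective variant is a SNP or InDel with predicted HIGH or MODERATE
#' impact. A region is retained iff it contains at least `min_effective`
#' such variants within its closed interval; the count is recorded in
#' `n_effective_variants`. The filter is idempotent and its output is a
#' subset of its input.
#'
#' @param regions Region tibble (from [call_regions()] or
#'   [intersect_regions()]).
#' @param variants Allele-depth tibble with `chrom`, `pos`, `impact`
#'   (SNPs and InDels; impacts may be NA).
#' @param effective_impacts Impact classes counted as effective.
#' @param min_effective Minimum effective variants to retain a region.
#' @return Retained regions with `n_effective_variants` added; removed
#'   count in attribute `n_removed_no_effective`.
#' @export
effective_variant_filter <- function(regions, variants,
                                     effective_impacts = c("HIGH", "MODERATE"),
                                     min_effective = 1L) {
  if (nrow(regions) == 0L) {
    out <- regions
    out$n_effective_variants <- integer(0)
    attr(out, "n_removed_no_effective") <- 0L
    return(out)
  }
  eff <- variants[!is.na(variants$impact) &
                    variants$impact %in% effective_impacts, , drop = FALSE]
  n_eff <- vapply(seq_len(nrow(regions)), function(i) {
    sum(eff$chrom == regions$chrom[i] &
          eff$pos >= regions$start[i] & eff$pos <= regions$end[i])
  }, integer(1))
  regions$n_effective_variants <- n_eff
  keep <- n_eff >= min_effective
  out <- regions[keep, , drop = FALSE]
  attr(out, "n_removed_no_effective") <- sum(!keep)
  out
}

#' Intersect two methods' region sets into consensus regions
#'
#' For every pair of regions on the same chromosome whose closed intervals
#' overlap, the intersection interval is emitted with method
#' `"consensus"`; regions without a partner in the other set are dropped.
#'
#' @param regions_a,regions_b Region tibbles (e.g. ED^4 and G' regions).
#' @return Consensus region tibble: `chrom`, `start`, `end`, `span_mb`,
#'   `method`.
#' @export
intersect_regions <- function(regions_a, regions_b) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), span_mb = numeric(),
                          method = character())
  if (nrow(regions_a) == 0L || nrow(regions_b) == 0L) return(empty)
  lev <- union(regions_a$chrom, regions_b$chrom)
  ga <- GenomicRanges::GRanges(factor(regions_a$chrom, levels = lev),
                               IRanges::IRanges(regions_a$start,
                                                regions_a$end))
  gb <- GenomicRanges::GRanges(factor(regions_b$chrom, levels = lev),
                               IRanges::IRanges(regions_b$start,
                                                regions_b$end))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0L) return(empty)
  pin <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                   gb[S4Vectors::subjectHits(hits)])
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(pin)),
    start = GenomicRanges::start(pin),
    end = GenomicRanges::end(pin))
  out$span_mb <- span_mb(out$start, out$end)
  out$method <- "consensus"
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Attach gene lists to candidate regions
#'
#' A gene belongs to a region iff its interval overlaps the region's
#' closed interval by any extent (a 1 bp edge overlap counts).
#'
#' @param regions Region tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return `regions` with list-column `gene_ids` and count `n_genes`.
#' @export
count_genes <- function(regions, genes) {
  if (nrow(regions) == 0L) {
    regions$gene_ids <- list()
    regions$n_genes <- integer(0)
    return(regions)
  }
  lev <- union(regions$chrom, genes$chrom)
  gr <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(factor(genes$chrom, levels = lev),
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr, gg)
  ids <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_len(nrow(regions))))
  regions$gene_ids <- unname(lapply(ids, as.character))
  regions$n_genes <- lengths(regions$gene_ids)
  regions
}
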