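#' Bulk allele frequencies from read depths
#'
#' The alternate-allele frequency of a bulk at a locus is the fraction of
#' its reads supporting the alternate allele.
#'
#' @param ref,alt Non-negative integer vectors of ref / alt read counts.
#' @return Numeric vector of alt-allele frequencies (NaN at zero depth).
#' @export
allele_frequency <- function(ref, alt) {
  alt / (ref + alt)
}

#' Euclidean distance between bulk allele-frequency vectors
#'
#' For a biallelic locus with bulk alt frequencies `f_high`, `f_low`, the
#' distance over the two-allele frequency vectors is
#' `sqrt((f_high - f_low)^2 + ((1 - f_high) - (1 - f_low))^2)`, i.e.
#' `sqrt(2) * |f_high - f_low|`. The fourth power (ED^4) suppresses
#' background noise from individual loci before window smoothing.
#'
#' @param f_high,f_low Alt-allele frequencies in the high / low bulk.
#' @return Tibble with columns `ed` and `ed4`.
#' @export
ed_statistic <- function(f_high, f_low) {
  ed <- sqrt((f_high - f_low)^2 + ((1 - f_high) - (1 - f_low))^2)
  tibble::tibble(ed = ed, ed4 = ed^4)
}

#' Per-locus G statistic from the two bulks' read counts
#'
#' The log-likelihood-ratio statistic on the 2x2 table of (ref, alt) x
#' (high bulk, low bulk) observed read counts: `G = 2 * sum n * ln(n/e)`
#' with expected counts `e` from the row/column margins under independence
#' and `0 * ln(0) = 0`.
#'
#' @param high_ref,high_alt,low_ref,low_alt Read-count vectors.
#' @return Numeric vector of G values; NA where all four counts are zero.
#' @export
g_statistic <- function(high_ref, high_alt, low_ref, low_alt) {
  n1 <- as.numeric(high_ref); n2 <- as.numeric(high_alt)
  n3 <- as.numeric(low_ref); n4 <- as.numeric(low_alt)
  tot <- n1 + n2 + n3 + n4
  rh <- n1 + n2; rl <- n3 + n4
  cr <- n1 + n3; ca <- n2 + n4
  term <- function(n, e) ifelse(n > 0, n * log(n / e), 0)
  g <- 2 * (term(n1, rh * cr / tot) + term(n2, rh * ca / tot) +
            term(n3, rl * cr / tot) + term(n4, rl * ca / tot))
  g[tot == 0] <- NA_real_
  g
}

#' Sliding-window mean smoothing of ED^4
#'
#' Windows of width `window_bp` are anchored every `step_bp` along each
#' chromosome; a window's value is the unweighted mean of ED^4 over loci
#' with position in `[anchor, anchor + window_bp)`, and windows holding no
#' locus emit no value. Each locus is assigned the value of the window
#' whose center is nearest its position (that window always contains the
#' locus since `step_bp <= window_bp`).
#'
#' @param chrom,pos Locus coordinates (pos need not be pre-sorted).
#' @param ed4 Raw ED^4 values.
#' @param window_bp Window size in bp (default 1 Mb).
#' @param step_bp Step between window anchors in bp (default 50 kb).
#' @return Numeric vector of smoothed values, aligned with the input.
#' @export
smooth_ed4 <- function(chrom, pos, ed4, window_bp = 1e6, step_bp = 5e4) {
  stopifnot(step_bp <= window_bp, step_bp > 0)
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(pos[i])]
    p <- pos[o]
    v <- ed4[o]
    cs <- cumsum(v)
    k_max <- floor(max(p) / step_bp)
    # nearest-center window index per locus, clamped to the anchor grid
    k <- round((p - window_bp / 2) / step_bp)
    k <- pmin(pmax(k, 0), k_max)
    a <- k * step_bp
    lo <- findInterval(a - 0.5, p) + 1L
    hi <- findInterval(a + window_bp - 0.5, p)
    m <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
    out[o] <- m
  }
  out
}

#' Tricube-smoothed G' track
#'
#' G' at each locus is the tricube-weighted average of the per-locus G
#' values within `window_bp / 2` on either side: with `d` the distance to
#' a neighbor and `h = window_bp / 2`, weights are `(1 - (d/h)^3)^3`,
#' normalized to sum to one. An isolated locus keeps its own G.
#'
#' @param chrom,pos Locus coordinates.
#' @param g Raw G values.
#' @param window_bp Full window size in bp (default 1 Mb).
#' @return Numeric vector of G' values aligned with the input.
#' @export
smooth_gprime <- function(chrom, pos, g, window_bp = 1e6) {
  h <- window_bp / 2
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(pos[i])]
    p <- pos[o]
    v <- g[o]
    lo <- findInterval(p - h, p) + 1L   # first index with pos > p - h
    hi <- findInterval(p + h, p)        # last index with pos <= p + h
    sm <- numeric(length(p))
    for (j in seq_along(p)) {
      idx <- lo[j]:hi[j]
      d <- abs(p[idx] - p[j]) / h
      w <- (1 - d^3)^3
      w[d >= 1] <- 0
      sm[j] <- sum(w * v[idx]) / sum(w)
    }
    out[o] <- sm
  }
  out
}

#' Empirical genome-wide threshold for a smoothed track
#'
#' The linear-interpolation empirical quantile (R's default type 7) of the
#' smoothed statistic; loci strictly above it are scan hits.
#'
#' @param values Smoothed statistic values.
#' @param quantile Quantile level (default 0.995, a 99.5% threshold).
#' @return The threshold value.
#' @export
scan_threshold <- function(values, quantile = 0.995) {
  stats::quantile(values, probs = quantile, type = 7, names = FALSE,
                  na.rm = TRUE)
}

#' Genome-wide association scan over bulk allele depths
#'
#' Computes the chosen per-locus statistic (ED^4 or G), its smoothed track
#' (window mean on a step grid for ED^4; tricube kernel for G'), and the
#' empirical quantile threshold. Loci with zero read depth in either bulk
#' are excluded first (count kept in `n_zero_depth_dropped`).
#'
#' @param adt Filtered allele-depth tibble (see [filter_loci()]).
#' @param method `"ED4"` or `"Gprime"`.
#' @param window_bp Smoothing window, bp (default 1 Mb).
#' @param step_bp Anchor step for ED^4 windows, bp (default 50 kb).
#' @param threshold_quantile Empirical quantile for the threshold
#'   (default 0.995).
#' @return A `genome_scan` object: list with `loci` (tibble `chrom`,
#'   `pos`, `raw_stat`, `smoothed_stat`, `above_threshold`), `method`,
#'   `window_bp`, `step_bp`, `threshold_quantile`, `threshold`,
#'   `n_zero_depth_dropped`.
#' @export
genome_scan <- function(adt, method = c("ED4", "Gprime"),
                        window_bp = 1e6, step_bp = 5e4,
                        threshold_quantile = 0.995) {
  method <- match.arg(method)
  dph <- adt$ad_high_ref + adt$ad_high_alt
  dpl <- adt$ad_low_ref + adt$ad_low_alt
  usable <- dph > 0 & dpl > 0
  n_dropped <- sum(!usable)
  adt <- adt[usable, , drop = FALSE]

  if (method == "ED4") {
    fh <- allele_frequency(adt$ad_high_ref, adt$ad_high_alt)
    fl <- allele_frequency(adt$ad_low_ref, adt$ad_low_alt)
    raw <- ed_statistic(fh, fl)$ed4
    smoothed <- smooth_ed4(adt$chrom, adt$pos, raw, window_bp, step_bp)
  } else {
    raw <- g_statistic(adt$ad_high_ref, adt$ad_high_alt,
                       adt$ad_low_ref, adt$ad_low_alt)
    smoothed <- smooth_gprime(adt$chrom, adt$pos, raw, window_bp)
  }
  thr <- scan_threshold(smoothed, threshold_quantile)

  scan <- list(
    loci = tibble::tibble(
      chrom = adt$chrom, pos = adt$pos,
      raw_stat = raw, smoothed_stat = smoothed,
      above_threshold = smoothed > thr),
    method = method,
    window_bp = window_bp,
    step_bp = if (method == "ED4") step_bp else NA_real_,
    threshold_quantile = threshold_quantile,
    threshold = thr,
    n_zero_depth_dropped = n_dropped)
  class(scan) <- "genome_scan"
  scan
}

#' @export
#' @method print genome_scan
print.genome_scan <- function(x, ...) {
  cat(sprintf("%s genome scan: %d loci on %d chromosome(s)\n",
              x$method, nrow(x$loci), length(unique(x$loci$chrom))))
  cat(sprintf("  window %.0f kb%s; %.1f%% threshold = %.4g; %d loci above\n",
              x$window_bp / 1e3,
              if (!is.na(x$step_bp)) sprintf(", step %.0f kb", x$step_bp / 1e3)
              else "",
              100 * x$threshold_quantile, x$threshold,
              sum(x$loci$above_threshold)))
  invisible(x)
}

#' Plot a genome scan with fitted line and threshold
#'
#' Per-chromosome panels of the raw statistic (points), the smoothed track
#' (black line) and the association threshold (red line).
#'
#' @param scan A `genome_scan` object.
#' @return A ggplot object.
#' @export
plot_genome_scan <- function(scan) {
  df <- scan$loci
  df$mb <- df$pos / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = mb)) +
    ggplot2::geom_point(ggplot2::aes(y = raw_stat),
                        colour = "grey70", size = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = smoothed_stat),
                       colour = "black") +
    ggplot2::geom_hline(yintercept = scan$threshold, colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)",
                  y = if (scan$method == "ED4") "ED4" else "G / G'",
                  title = sprintf("%s scan (%.1f%% threshold)",
                                  scan$method,
                                  100 * scan$threshold_quantile)) +
    ggplot2::theme_bw()
}
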