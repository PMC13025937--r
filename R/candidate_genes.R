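#' Tissue-expression screen over an FPKM matrix
#'
#' Flags genes whose FPKM strictly exceeds `cutoff` in at least one of
#' the configured tissues (default seed and endosperm, the tissues
#' relevant to kernel sugar metabolism). FPKM exactly at the cutoff
#' fails.
#'
#' @param fpkm Tibble with `gene_id` and one numeric column per tissue.
#' @param tissues Tissue columns to screen (default
#'   `c("seed", "endosperm")`).
#' @param cutoff Strict FPKM threshold (default 1.0).
#' @param genes Optional character vector restricting the screen to these
#'   gene IDs (input order preserved).
#' @return Tibble `gene_id`, `max_fpkm_screened`,
#'   `passes_expression_screen`.
#' @export
expression_screen <- function(fpkm, tissues = c("seed", "endosperm"),
                              cutoff = 1.0, genes = NULL) {
  if (!is.null(genes)) fpkm <- fpkm[fpkm$gene_id %in% genes, , drop = FALSE]
  missing <- setdiff(tissues, names(fpkm))
  if (length(missing) > 0)
    stop("tissue column(s) not in FPKM table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mat <- as.matrix(fpkm[, tissues, drop = FALSE])
  mx <- apply(mat, 1, max)
  tibble::tibble(
    gene_id = fpkm$gene_id,
    max_fpkm_screened = mx,
    passes_expression_screen = mx > cutoff)
}

#' Keyword screen over functional annotation text
#'
#' Purely mechanical case-insensitive substring match of a keyword set
#' against a gene's annotation text; no biological inference. The default
#' set targets sugar-metabolism vocabulary.
#'
#' @param annotation Tibble with `gene_id` and `description`.
#' @param keywords Character keyword set; an empty set flags nothing.
#' @return Tibble `gene_id`, `description`, `sugar_metabolism_flag`.
#' @export
keyword_screen <- function(annotation,
                           keywords = c("sugar", "sucrose", "carbohydrate",
                                        "kinase", "glycosyl", "amylase",
                                        "invertase", "FGGY")) {
  flag <- rep(FALSE, nrow(annotation))
  for (kw in keywords)
    flag <- flag | grepl(kw, annotation$description, ignore.case = TRUE)
  tibble::tibble(
    gene_id = annotation$gene_id,
    description = annotation$description,
    sugar_metabolism_flag = flag)
}

#' Rank candidate genes deterministically
#'
#' Orders genes by (1) sugar-metabolism keyword flag, (2) tissue-expression
#' screen, (3) absolute low-vs-high-line qRT-PCR contrast (mean 2^-dCT
#' difference, descriptive only). The sort is stable, so all-tied
#' candidates keep their input order.
#'
#' @param report Tibble with `gene_id`, `sugar_metabolism_flag`,
#'   `passes_expression_screen`.
#' @param qpcr Optional tibble with `gene`, `line_class` ("low"/"high"),
#'   `ct_target`, `ct_reference`; one row per replicate.
#' @return `report` ordered by rank, with `expression_contrast` and
#'   `rank` columns.
#' @export
rank_candidates <- function(report, qpcr = NULL) {
  contrast <- rep(0, nrow(report))
  if (!is.null(qpcr) && nrow(qpcr) > 0) {
    qpcr$rel <- relative_expression(qpcr$ct_target, qpcr$ct_reference)
    for (i in seq_len(nrow(report))) {
      g <- qpcr[qpcr$gene == report$gene_id[i], , drop = FALSE]
      if (nrow(g) == 0) next
      lo <- mean(g$rel[g$line_class == "low"])
      hi <- mean(g$rel[g$line_class == "high"])
      if (!is.nan(lo) && !is.nan(hi)) contrast[i] <- abs(lo - hi)
    }
  }
  report$expression_contrast <- contrast
  ord <- order(-as.integer(report$sugar_metabolism_flag),
               -as.integer(report$passes_expression_screen),
               -contrast)
  out <- report[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
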