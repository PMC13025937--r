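#' Read a four-sample BSA-seq VCF into an allele-depth table
#'
#' Parses per-sample `AD` (ref,alt read depths) for the two parents and
#' the two bulks. Multiallelic records (comma in ALT) are dropped with a
#' warning by default, mirroring common BSA practice of scanning biallelic
#' sites only. INFO keys `IMPACT` and `VT` are recovered when present;
#' otherwise the impact is `NA` and the variant class is inferred from
#' allele lengths.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples Sample names, in order parent 1, parent 2, high bulk,
#'   low bulk.
#' @param drop_multiallelic Drop records with >1 ALT allele (default TRUE).
#' @return Allele-depth tibble (same columns as
#'   [simulate_allele_depths()]), rows in file order. The number of
#'   dropped multiallelic records is attached as attribute
#'   `n_multiallelic_dropped`.
#' @export
read_bsa_vcf <- function(path,
                         samples = c("P1", "P2", "HighBulk", "LowBulk"),
                         drop_multiallelic = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  empty <- tibble::tibble(
    chrom = character(), pos = numeric(), ref = character(),
    alt = character(), variant_class = character(), impact = character(),
    ad_p1_ref = integer(), ad_p1_alt = integer(),
    ad_p2_ref = integer(), ad_p2_alt = integer(),
    ad_high_ref = integer(), ad_high_alt = integer(),
    ad_low_ref = integer(), ad_low_alt = integer())
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(empty, "n_multiallelic_dropped") <- 0L
    return(empty)
  }

  have <- colnames(vcf@gt)[-1]
  missing <- setdiff(samples, have)
  if (length(missing) > 0)
    stop("sample(s) not found in VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  no_ad <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1))
  if (any(no_ad))
    stop("records without AD in FORMAT (first at row ", which(no_ad)[1],
         "); AD is required for samples ", paste(samples, collapse = ", "),
         call. = FALSE)

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    if (!drop_multiallelic)
      stop(n_multi, " multiallelic record(s); set drop_multiallelic = TRUE ",
           "or split them upstream", call. = FALSE)
    warning(n_multi, " multiallelic record(s) dropped", call. = FALSE)
  }
  keep <- !multi

  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(sample) {
    parts <- strsplit(ad[keep, sample], ",", fixed = TRUE)
    r <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])),
                integer(1))
    a <- vapply(parts, function(p)
      if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_,
      integer(1))
    r[is.na(r)] <- 0L
    a[is.na(a)] <- 0L
    list(ref = r, alt = a)
  }
  p1 <- parse_ad(samples[1]); p2 <- parse_ad(samples[2])
  hb <- parse_ad(samples[3]); lb <- parse_ad(samples[4])

  info <- fix[keep, "INFO"]
  impact <- info_field(info, "IMPACT")
  vt <- info_field(info, "VT")
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  vt[is.na(vt)] <- ifelse(nchar(ref[is.na(vt)]) == 1 &
                            nchar(alt[is.na(vt)]) == 1, "SNP", "InDel")

  out <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.numeric(fix[keep, "POS"]),
    ref = ref, alt = alt,
    variant_class = vt, impact = impact,
    ad_p1_ref = p1$ref, ad_p1_alt = p1$alt,
    ad_p2_ref = p2$ref, ad_p2_alt = p2$alt,
    ad_high_ref = hb$ref, ad_high_alt = hb$alt,
    ad_low_ref = lb$ref, ad_low_alt = lb$alt)
  attr(out, "n_multiallelic_dropped") <- n_multi
  out
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Quality and parental-polymorphism locus filter
#'
#' Retains loci where (a) both parents reach `min_depth_parent` and each is
#' effectively homozygous (minor-allele read fraction <=
#' `homozygosity_tol`) for a *different* allele, (b) both bulks reach
#' `min_depth_bulk`, and (c) for the scan table, the variant is a SNP.
#' Row order is preserved and the filter is idempotent. Per-rule removal
#' counts are attached as attribute `filter_counts`.
#'
#' @param adt Allele-depth tibble.
#' @param min_depth_parent Minimum total reads per parent (default 4).
#' @param min_depth_bulk Minimum total reads per bulk (default 10).
#' @param homozygosity_tol Maximum parental minor-allele read fraction
#'   still called homozygous (default 0.1).
#' @param require_parent_polymorphism Require the parents to be fixed for
#'   different alleles (default TRUE).
#' @param snp_only Keep SNPs only (default TRUE); set FALSE to filter an
#'   InDel side table for effective-variant bookkeeping.
#' @return Filtered allele-depth tibble.
#' @export
filter_loci <- function(adt,
                        min_depth_parent = 4,
                        min_depth_bulk = 10,
                        homozygosity_tol = 0.1,
                        require_parent_polymorphism = TRUE,
                        snp_only = TRUE) {
  dp1 <- adt$ad_p1_ref + adt$ad_p1_alt
  dp2 <- adt$ad_p2_ref + adt$ad_p2_alt
  dph <- adt$ad_high_ref + adt$ad_high_alt
  dpl <- adt$ad_low_ref + adt$ad_low_alt

  ok_parent_depth <- dp1 >= min_depth_parent & dp2 >= min_depth_parent
  minor1 <- pmin(adt$ad_p1_ref, adt$ad_p1_alt) / pmax(dp1, 1L)
  minor2 <- pmin(adt$ad_p2_ref, adt$ad_p2_alt) / pmax(dp2, 1L)
  ok_hom <- minor1 <= homozygosity_tol & minor2 <= homozygosity_tol
  major1_alt <- adt$ad_p1_alt > adt$ad_p1_ref
  major2_alt <- adt$ad_p2_alt > adt$ad_p2_ref
  ok_poly <- if (require_parent_polymorphism) major1_alt != major2_alt
             else rep(TRUE, nrow(adt))
  ok_bulk <- dph >= min_depth_bulk & dpl >= min_depth_bulk
  ok_class <- if (snp_only) adt$variant_class == "SNP"
              else rep(TRUE, nrow(adt))

  keep <- ok_parent_depth & ok_hom & ok_poly & ok_bulk & ok_class
  out <- adt[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    n_input = nrow(adt),
    removed_parent_depth = sum(!ok_parent_depth),
    removed_parent_heterozygous = sum(ok_parent_depth & !ok_hom),
    removed_not_polymorphic = sum(ok_parent_depth & ok_hom & !ok_poly),
    removed_bulk_depth = sum(!ok_bulk),
    removed_not_snp = sum(!ok_class),
    n_retained = sum(keep))
  out
}

#' Per-sample sequencing summaries
#'
#' Arithmetic means over per-sample realized depths (and mapped-read
#' ratios when provided), rounded to 2 decimal places as reported in
#' sequencing summary tables.
#'
#' @param samples Tibble/data.frame with columns `sample`, `real_depth`
#'   and optionally `mapped_ratio` (percent).
#' @return List with `per_sample` (the input), `mean_depth` and
#'   `mean_mapped_ratio` (NA when ratios are absent).
#' @export
sample_summaries <- function(samples) {
  stopifnot(nrow(samples) >= 1, "real_depth" %in% names(samples))
  list(
    per_sample = tibble::as_tibble(samples),
    mean_depth = round(mean(samples$real_depth), 2),
    mean_mapped_ratio = if ("mapped_ratio" %in% names(samples))
      round(mean(samples$mapped_ratio), 2) else NA_real_
  )
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type features only; 1-based inclusive coordinates are
#' preserved.
#'
#' @param path GFF3 file.
#' @return Gene tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))
}

#' Read a phenotype table (line, sugar contents at 0/8/72 h)
#'
#' @param path Tab-delimited file with columns `line_id`, `sugar_0h`,
#'   `sugar_8h`, `sugar_72h` (mg g^-1).
#' @return Tibble with those columns.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("line_id", "sugar_0h", "sugar_72h") %in% names(df)))
  tibble::as_tibble(df)
}

#' Read a gene x tissue FPKM matrix
#'
#' @param path Tab-delimited file, first column `gene_id`, remaining
#'   columns tissue FPKM values.
#' @return Tibble, one row per gene.
#' @export
read_fpkm_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Read a qRT-PCR cycle-threshold table
#'
#' @param path Tab-delimited file with columns `gene`, `line_class`,
#'   `ct_target`, `ct_reference` (one row per replicate).
#' @return Tibble with those columns.
#' @export
read_ct_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}
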