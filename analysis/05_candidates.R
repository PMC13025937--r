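#!/usr/bin/env Rscript
# Candidate-gene funnel inside the consensus intervals: keyword screen
# over a curated (synthetic) functional annotation, FPKM > 1 tissue
# expression screen in seed/endosperm, and deterministic ranking with a
# descriptive qRT-PCR low-vs-high-line contrast.

suppressMessages(library(bsascan))

extdata <- function(f) system.file("extdata", f, package = "bsascan")
ann <- utils::read.delim(extdata("synthetic_gene_annotation.tsv"))
fpkm <- read_fpkm_table(extdata("synthetic_fpkm.tsv"))
qpcr <- read_ct_table(extdata("synthetic_qpcr_ct.tsv"))

cons <- utils::read.delim("results/regions/regions_consensus.tsv")
region_genes <- unlist(strsplit(cons$gene_ids, ","))
cat(sprintf("%d genes in %d consensus interval(s); %d with curated annotation\n",
            length(region_genes), nrow(cons),
            sum(ann$gene_id %in% region_genes)))

ann <- ann[ann$gene_id %in% region_genes, , drop = FALSE]
kw <- keyword_screen(ann)
expr <- expression_screen(fpkm, genes = ann$gene_id)
report <- merge(kw[, c("gene_id", "sugar_metabolism_flag")], expr,
                by = "gene_id", sort = FALSE)
ranked <- rank_candidates(report, qpcr)

cat(sprintf("%d gene(s) pass the sugar-metabolism keyword screen\n",
            sum(ranked$sugar_metabolism_flag)))
cat(sprintf("%d gene(s) pass the FPKM > 1 seed/endosperm screen\n",
            sum(ranked$passes_expression_screen)))
cat("\nRanked candidates:\n")
print(ranked)

dir.create("results/candidates", recursive = TRUE, showWarnings = FALSE)
utils::write.table(ranked, "results/candidates/candidate_report.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nReport written to results/candidates/candidate_report.tsv\n")
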