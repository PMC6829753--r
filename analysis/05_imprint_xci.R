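#!/usr/bin/env Rscript
## Stage 5: imprinted-DMR methylation status across the cohort; XCI-subject
## candidates from the non-reprogrammed cells, escape calls in the female
## reprogrammed lineage and the coupled expression derepression.

suppressMessages({ library(methylscape); library(GenomicRanges) })
cache <- readRDS("results/cache/cohort.rds")
genome <- cache$genome; cohort <- cache$cohort
design <- cohort$manifest
seed <- as.integer(Sys.getenv("METHYLSCAPE_SEED", "1"))

ist <- idmr_status(genome$idmrs, cohort$samples)
sm <- idmr_summary(ist$status)
write.table(sm, "results/idmr_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("iDMR hypermethylation by sample (% of the 50-iDMR catalogue):")
print(sm[, c("sample", "n_hyper", "pct_hyper")], row.names = FALSE)

tss <- tss_regions(genome, 500)
x_tss <- tss[as.character(seqnames(tss)) == genome$x_chrom]
nonrep <- design[!design$reprogrammed, ]
cand <- xci_candidates(x_tss,
                       cohort$samples[nonrep$sample_id[nonrep$sex == "F"]],
                       cohort$samples[nonrep$sample_id[nonrep$sex == "M"]])
message(sprintf("XCI: %d of %d callable X-linked genes are subject (%.0f%%)",
                sum(cand$status == "XCI-subject"), attr(cand, "n_callable"),
                100 * attr(cand, "fraction_subject")))

rep_f <- design$sample_id[design$reprogrammed & design$sex == "F"]
rl <- feature_means(cohort$samples[rep_f], x_tss, min_sites = 5)$levels
rownames(rl) <- S4Vectors::mcols(x_tss)$gene_id
esc <- xci_escape(cand, rl)
message(sprintf("escape: %d of %d subject genes (%.0f%%) hypomethylated in ",
                attr(esc, "n_escaped"), attr(esc, "n_subject"),
                100 * attr(esc, "fraction_escaped")),
        paste(rep_f, collapse = ", "))
write.table(cand, "results/xci_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(esc, "results/xci_escape.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fpkm <- simulate_expression(genome, design, seed = seed)
er <- expression_ratio(fpkm, "iRPE1", "cRPE4",
                       set_a = esc$gene_id[esc$escaped],
                       set_b = esc$gene_id[!esc$escaped])
message(sprintf(
  "escaped genes are %.1f-fold derepressed in iRPE1 vs cRPE4 (subject genes %.2f-fold; Wilcoxon p = %.2g)",
  2^attr(er, "median_a"), 2^attr(er, "median_b"), attr(er, "p_value")))
write.table(er, "results/xci_expression_ratio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
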