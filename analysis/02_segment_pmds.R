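#!/usr/bin/env Rscript
## Stage 2: change-point segmentation of every methylome, MDL tables, PMD
## calling, the fibroblast/iRPE/pan-cRPE Venn and the lineage classification
## of iRPE PMDs (recurrent vs persistent vs iRPE-specific).

suppressMessages({ library(methylscape); library(GenomicRanges) })
cache <- readRDS("results/cache/cohort.rds")
genome <- cache$genome; cohort <- cache$cohort

pmds <- list()
for (s in names(cohort$samples)) {
  dom <- segment_methylome(cohort$samples[[s]])
  write.table(mdl_table(dom), sprintf("results/mdl_%s.tsv", s),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pmd <- call_pmds(dom)
  gr <- domains_to_granges(pmd)
  pmds[[s]] <- gr[as.character(seqnames(gr)) != genome$x_chrom]
  message(sprintf("%-8s %4d domains, %5.1f Mb autosomal PMD", s, nrow(dom),
                  sum(width(reduce(pmds[[s]]))) / 1e6))
}

pan_crpe <- pmd_prone_regions(pmds[paste0("cRPE", 1:4)])
venn <- interval_overlap_mb(Fibro = pmds$Fibro1, iRPE = pmds$iRPE1,
                            panCRPE = pan_crpe)
write.table(venn, "results/pmd_venn_patient1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("PMD Venn (Mb): "); print(venn, row.names = FALSE)

cls <- classify_pmds(pmds$Fibro1, pmds$iPSC1, pmds$iRPE1, pan_crpe)
message("iRPE1 PMD lineage fractions (base-wise):")
print(round(cls$fractions, 3))
write_bed(cls$regions, "results/irpe1_pmd_classes.bed")

saveRDS(pmds, "results/cache/pmds.rds", compress = FALSE)
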