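#!/usr/bin/env Rscript
## Stage 4: iRPE-vs-nRPE DMR calling (autosomes; >= 20 CpGs, q < 0.01,
## |difference| > 30%), k-means profile clusters (5 hyper / 2 hypo),
## origin/fate tracing against an ESC-like reference, and DMR-proximal
## gene mapping with signature-gene enrichment.

suppressMessages({ library(methylscape); library(GenomicRanges) })
cache <- readRDS("results/cache/cohort.rds")
genome <- cache$genome; cohort <- cache$cohort
design <- cohort$manifest
seed <- as.integer(Sys.getenv("METHYLSCAPE_SEED", "1"))

irpe <- cohort$samples[design$sample_id[design$state == "iRPE"]]
nrpe <- cohort$samples[design$sample_id[design$state == "nRPE"]]
dmrs <- call_dmrs(irpe, nrpe)
message(nrow(dmrs), " DMRs: ", sum(dmrs$direction == "hyper"), " hyper / ",
        sum(dmrs$direction == "hypo"), " hypo (",
        round(sum(dmrs$end - dmrs$start) / 1e6, 2), " Mb)")

## per-state mean levels over DMR intervals (+ an ESC-like reference)
esc_ref <- simulate_methylome(genome, cell_state_params("ESC", genome = genome),
                              seed = seed + 7)
dgr <- dmrs_to_granges(dmrs)
by_state <- split(design$sample_id, design$state)
state_means <- sapply(c("Fibro", "iPSC", "iRPE", "xRPE", "cRPE", "nRPE"),
  function(st) rowMeans(feature_means(cohort$samples[by_state[[st]]],
                                      dgr)$levels, na.rm = TRUE))
state_means <- cbind(state_means,
                     esc = feature_means(list(esc = esc_ref), dgr)$levels[, 1])
colnames(state_means) <- c("fib", "ipsc", "irpe", "xrpe", "crpe", "nrpe", "esc")

## k-means profile clusters: 5 for hyper-, 2 for hypo-DMRs
hyper <- dmrs$direction == "hyper"
km_h <- kmeans_dmrs(state_means[hyper, ], k = 5, seed = seed)
km_l <- kmeans_dmrs(state_means[!hyper, ], k = 2, seed = seed)
dmrs$cluster <- NA_integer_
dmrs$cluster[hyper] <- km_h$cluster
dmrs$cluster[!hyper] <- km_l$cluster + 5L   # hypo clusters numbered 6 and 7
message("hyper-DMR cluster sizes: ", paste(km_h$sizes, collapse = ", "))
message("hypo-DMR cluster sizes:  ", paste(km_l$sizes, collapse = ", "))

of <- classify_origin_fate(state_means, dmrs$direction)
dmrs$origin <- of$origin; dmrs$fate <- of$fate
message("origins:"); print(table(dmrs$origin))
message("fates:"); print(table(dmrs$fate))

px <- proximal_genes(dmrs, genome$genes, max_dist = 5000)
hyper_g <- unique(px$gene_id[dmrs$direction[px$dmr] == "hyper"])
hypo_g <- unique(px$gene_id[dmrs$direction[px$dmr] == "hypo"])
s <- proximal_gene_summary(hyper_g, hypo_g)
message(sprintf("proximal genes: %d hyper + %d hypo - %d both = %d",
                s$n_hyper, s$n_hypo, s$n_both, s$n_union))

## genes near xeno-resolved hyper-DMRs are enriched for the RPE signature
resolved_g <- unique(px$gene_id[dmrs$fate[px$dmr] == "resolved-in-xRPE" &
                                  dmrs$direction[px$dmr] == "hyper"])
universe <- S4Vectors::mcols(genome$genes)$gene_id
fo <- fisher_overlap(resolved_g, genome$rpe_signature, universe)
message("RPE-signature enrichment near resolved hyper-DMRs: p = ",
        signif(fo$p_value, 3), ", OR = ", round(fo$odds_ratio, 1))

write_dmrs(dmrs, "results/dmrs.bed", "results/dmrs.tsv")
saveRDS(list(dmrs = dmrs, state_means = state_means),
        "results/cache/dmrs.rds", compress = FALSE)
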