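#!/usr/bin/env Rscript
## Stage 3: promoter-level feature matrix and the three sample-clustering
## workflows (raw levels, PCA, ICA); extraction of the components that
## discriminate RPE from non-RPE and reprogrammed from non-reprogrammed
## cells, with contributor enrichment against the RPE signature set.

suppressMessages({ library(methylscape); library(GenomicRanges) })
cache <- readRDS("results/cache/cohort.rds")
genome <- cache$genome; cohort <- cache$cohort
design <- cohort$manifest
seed <- as.integer(Sys.getenv("METHYLSCAPE_SEED", "1"))

prom <- autosomal_only(standard_features(genome)$promoters, genome$autosomes)
fm <- feature_means(cohort$samples, prom)
write_feature_matrix(fm, "results/promoter_levels.tsv")

labels <- setNames(design$state, design$sample_id)
hc_raw <- cluster_raw(fm)
pca <- run_pca(fm)
ica <- run_ica(fm, seed = seed)
write_newick(hc_raw, "results/dendro_raw.nwk")
write_newick(cluster_components(pca), "results/dendro_pca.nwk")
write_newick(cluster_components(ica), "results/dendro_ica.nwk")

message("six-state clade recovery: raw=", clades_recovered(hc_raw, labels),
        " pca=", clades_recovered(cluster_components(pca), labels),
        " ica=", clades_recovered(cluster_components(ica), labels))

rpe <- design$sample_id[design$state %in% c("iRPE", "xRPE", "cRPE", "nRPE")]
nonrpe <- design$sample_id[design$state %in% c("Fibro", "iPSC")]
dc_rpe <- discriminating_component(ica, rpe, nonrpe)
message("RPE-discriminating component: ", dc_rpe$component[1],
        " (Wilcoxon p = ", signif(dc_rpe$p_value[1], 3), ")")
contrib <- top_contributors(ica, dc_rpe$component[1], top_n = 50)
fo <- fisher_overlap(contrib$feature, genome$rpe_signature,
                     rownames(complete_features(fm)$levels))
message("RPE signature enrichment among its top 50 contributors: p = ",
        signif(fo$p_value, 3), ", OR = ", round(fo$odds_ratio, 1))

rep_s <- design$sample_id[design$reprogrammed]
non_s <- design$sample_id[!design$reprogrammed]
dc_rep <- discriminating_component(ica, rep_s, non_s)
message("reprogramming-memory component: ", dc_rep$component[1],
        " (Wilcoxon p = ", signif(dc_rep$p_value[1], 3), ")")
write.table(dc_rep, "results/component_discrimination.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(fm = fm, ica = ica), "results/cache/clustering.rds",
        compress = FALSE)
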