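#!/usr/bin/env Rscript
# Step 3: pan/core-genome statistics.
#
# From the presence matrix: core genome, core accumulation curve,
# gene-content clustering (Jaccard + UPGMA), a neighbor-joining SNP tree
# over the core genes of a strain subset, concordance between the two
# trees, COG partition of the non-core genes, and the dairy-vs-human
# shared-content comparison.

suppressMessages(library(panpheno))

SEED <- 1
m <- read_matrix("results/matrix.tsv")
cohort_dir <- "results/cohort"
ref <- read_reference(file.path(cohort_dir, "reference.fasta"),
                      file.path(cohort_dir, "reference.gff3"))
niches_df <- read.delim(file.path(cohort_dir, "niches.tsv"))
niches <- setNames(niches_df$niche, niches_df$strain_id)

core <- core_genome(m)
writeLines(core$core_tags, "results/core_genes.txt")
message(sprintf("Core genome: %d of %d genes (%.1f%%)",
                core$core_size, ncol(m), core$core_percent))

acc <- core_accumulation(m, n_permutations = 100, seed = SEED)
write.table(acc, "results/core_accumulation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
stable_from <- which(acc$mean_core - core$core_size < 0.05 * core$core_size)[1]
message("Core accumulation curve stabilises near the final core size from ~",
        stable_from, " genomes")

cl <- gene_content_clustering(m, k = 4)
write_newick(ape::as.phylo(cl$hclust), "results/gene_content_tree.nwk")
write.table(data.frame(strain_id = names(cl$clusters),
                       cluster = cl$clusters, niche = niches[names(cl$clusters)]),
            "results/gene_content_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Gene-content dendrogram (4 clusters) vs niches:")
print(table(cl$clusters, niches[names(cl$clusters)]))

# SNP tree on a 12-strain subset (pairwise core-gene substitution distance)
sub_ids <- rownames(m)[round(seq(1, nrow(m), length.out = 12))]
strains <- lapply(sub_ids, function(id) {
  strain_genome(id, niches[[id]], Biostrings::readDNAStringSet(
    file.path(cohort_dir, "strains", paste0(id, ".fasta"))))
})
snp <- snp_distance_tree(strains, ref, core$core_tags)
write_newick(snp$tree, "results/snp_tree.nwk")
conc <- tree_concordance(gene_content_clustering(m[sub_ids, ])$hclust,
                         snp$tree)
message(sprintf("Gene-content vs SNP tree concordance (12 strains): %.2f",
                conc))

cog <- cog_partition(ref, core$core_tags)
write.table(cog, "results/cog_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
g <- cog[cog$cog_category == "G", ]
message(sprintf("COG G (carbohydrate transport/metabolism): %d/%d genes non-core (%.1f%%)",
                g$non_core, g$total, g$percent_non_core))

cmp <- niche_content_comparison(shared_content(m), niches)
message(sprintf("Mean shared content: dairy %.1f%% vs human %.2f%% (Mann-Whitney p = %.3g, clinical excluded)",
                cmp$group_means[["dairy"]], cmp$group_means[["human"]],
                cmp$p_value))
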