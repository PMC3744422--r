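#!/usr/bin/env Rscript
# Step 5: CRISPR spacer oligotyping.
#
# Types all 24 reference spacers and 4 cas genes in every strain
# (conserved / partially conserved / absent), summarises shared-spacer
# counts per niche, and searches the spacers against a synthetic
# phage/plasmid database with planted protospacers (word-size-7
# seed-and-extend, hits at >= 85% identity over >= 80% length).

suppressMessages(library(panpheno))

SEED <- 1
cohort_dir <- "results/cohort"
crispr <- reference_crispr(file.path(cohort_dir, "spacers.fasta"),
                           file.path(cohort_dir, "cas.fasta"))
niches_df <- read.delim(file.path(cohort_dir, "niches.tsv"))
strains <- lapply(seq_len(nrow(niches_df)), function(i) {
  id <- niches_df$strain_id[i]
  strain_genome(id, niches_df$niche[i], Biostrings::readDNAStringSet(
    file.path(cohort_dir, "strains", paste0(id, ".fasta"))))
})

message("Oligotyping ", length(strains), " strains ...")
oli <- oligotype_cohort(crispr, strains)
write_crispr_profiles(oli, "results/crispr_profiles.tsv")

niches <- setNames(niches_df$niche, niches_df$strain_id)
message("Median shared (conserved) spacers per niche:")
for (n in unique(niches)) {
  ids <- names(niches)[niches == n]
  message(sprintf("  %s: %.0f of %d", n,
                  median(oli$shared_counts[ids]), length(crispr$spacers)))
}

# synthetic phage database with protospacers planted for spacers 1-8;
# seeded on its own stream so the random phage backbones cannot reproduce
# the reference stream that generated the spacers
set.seed(SEED + 104729)
db_seqs <- vapply(1:4, function(i) {
  paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
}, character(1))
for (i in 1:8) {
  tgt <- (i - 1) %% 4 + 1
  at <- sample(10000, 1)
  db_seqs[tgt] <- paste0(substr(db_seqs[tgt], 1, at),
                         as.character(crispr$spacers[[i]]),
                         substr(db_seqs[tgt], at + 1, nchar(db_seqs[tgt])))
}
db <- Biostrings::DNAStringSet(setNames(db_seqs, paste0("phage_", 1:4)))
hits <- protospacer_search(crispr$spacers, db)
write.table(hits, "results/protospacer_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(hits), " protospacer hits; spacers with hits: ",
        paste(sort(unique(hits$spacer_index)), collapse = ", "))
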