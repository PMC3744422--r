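#!/usr/bin/env Rscript
# Step 4: hyper-variable chromosomal regions.
#
# Computes the per-gene loss frequency across the cohort and segments the
# reference into contiguous variable regions (loss frequency >= 0.10, >= 5
# genes, gaps of one conserved gene tolerated), annotating each with
# overlapping genomic islands and IS-element counts.

suppressMessages(library(panpheno))

m <- read_matrix("results/matrix.tsv")
cohort_dir <- "results/cohort"
ref <- read_reference(file.path(cohort_dir, "reference.fasta"),
                      file.path(cohort_dir, "reference.gff3"))

lp <- loss_profile(m)
write.table(data.frame(locus_tag = names(lp), loss_frequency = lp),
            "results/loss_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("Genes never lost (core): %d; max loss frequency: %.2f",
                sum(lp == 0), max(lp)))

regions <- region_report(detect_regions(lp, ref), ref)
write.table(regions, "results/variable_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_regions_gff(regions, ref, "results/variable_regions.gff3")

message("Detected ", nrow(regions), " variable regions:")
for (i in seq_len(nrow(regions))) {
  message(sprintf("  region %d: %s (%d genes, mean loss %.2f%s%s)",
                  regions$region_id[i], regions$locus_range[i],
                  regions$gene_count[i], regions$mean_loss[i],
                  ifelse(is.na(regions$gi_overlap[i]), "",
                         paste0(", ", regions$gi_overlap[i])),
                  ifelse(regions$is_count[i] > 0,
                         paste0(", ", regions$is_count[i], " IS"), "")))
}
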