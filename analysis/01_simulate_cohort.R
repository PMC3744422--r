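#!/usr/bin/env Rscript
# Step 1: build the study cohort.
#
# Simulates the annotated reference chromosome (300 genes, 6 genomic
# islands, a 24-spacer Type II-A-like CRISPR locus) and a 100-strain cohort
# mirroring the study collection (23 dairy, 16 intestinal, 3 oral,
# 8 vaginal, 31 clinical, 19 other), with phenotypes coupled to genotype.
# Everything downstream reads the files written here.

suppressMessages(library(panpheno))

SEED <- 1
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating reference genome ...")
ref <- simulate_reference(seed = SEED)
write_reference(ref, file.path(out, "reference.fasta"),
                file.path(out, "reference.gff3"))
Biostrings::writeXStringSet(ref$crispr$spacers,
                            file.path(out, "spacers.fasta"))
Biostrings::writeXStringSet(ref$crispr$cas, file.path(out, "cas.fasta"))
write.table(ref$islands, file.path(out, "islands.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulating 100-strain cohort ...")
cohort <- simulate_cohort(ref, default_niche_mix(),
                          default_niche_profiles(), seed = SEED)
write_cohort(cohort, out)
write_run_manifest(file.path(out, "manifest.json"), seed = SEED,
                   params = list(n_strains = length(cohort$strains),
                                 niche_mix = as.list(default_niche_mix())))

tab <- table(cohort$niches)
message("Cohort composition:")
for (n in names(tab)) message("  ", n, ": ", tab[[n]], " strains")
message("Reference: ", nrow(ref$genes), " genes, ",
        nrow(ref$islands), " islands, ",
        length(ref$crispr$spacers), " CRISPR spacers. Files in ", out)
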