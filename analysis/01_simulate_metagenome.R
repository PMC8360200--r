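#!/usr/bin/env Rscript
# Stage 1: build the synthetic study metagenome.
# 100 contigs (~2 kb), 20 planted SDR-family genes spanning 30-98% identity to
# the three seed enzymes, and 20 shuffled decoys, with a ground-truth table.

library(sdrmine)

out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seeds <- seed_proteins()
templates <- lapply(names(seeds), function(n) gene_template(n, seeds[[n]]))

contigs <- generate_contigs(100, length_mean = 2000, length_sd = 500,
                            gc = 0.45, seed = 11)
planted <- plant_genes(contigs, templates, round(seq(30, 98, length.out = 20)),
                       seed = 12, decoys = 20)

write_fasta(planted$contigs, file.path(out, "contigs.fa"), "DNA")
write_fasta(seeds, file.path(out, "seeds.faa"), "AA")
write_truth_table(planted$truth, file.path(out, "truth.tsv"))

cat(sprintf("wrote %d contigs (%.1f kb total), %d planted family genes, %d decoys\n",
            length(planted$contigs), sum(nchar(planted$contigs)) / 1000,
            sum(planted$truth$is_family), sum(!planted$truth$is_family)))
cat(sprintf("planted identities: %.0f-%.0f%% (mean %.0f%%)\n",
            min(planted$truth$planted_identity, na.rm = TRUE),
            max(planted$truth$planted_identity, na.rm = TRUE),
            mean(planted$truth$planted_identity, na.rm = TRUE)))
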