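#!/usr/bin/env Rscript
# Stage 5: the comparative view of the panel — neighbor-joining tree from
# identity-derived distances, three clades, and a tree-ordered identity
# matrix for heat-map rendering.

library(sdrmine)

out <- "results/comparative"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reps <- read_fasta("results/derep/representatives.faa", "AA")
names(reps) <- sub("\\|[^|]+\\|[0-9]+\\|[0-9]+\\|[+-]$", "", names(reps))

m <- identity_matrix(reps)
tree <- neighbor_joining(distance_from_identity(m))
writeLines(to_newick(tree), file.path(out, "tree.nwk"))

k <- min(3, length(reps))
clades <- assign_clades(tree, k)
write.table(data.frame(id = names(clades), clade = unname(clades)),
            file.path(out, "clades.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

ord <- heatmap_order(tree)
write_identity_matrix(m[ord, ord], file.path(out, "matrix_ordered.tsv"))

cat(sprintf("built NJ tree over %d representatives; %d clades: %s\n",
            length(reps), k, paste(table(clades), collapse = "/")))
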