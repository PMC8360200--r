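#!/usr/bin/env Rscript
# Stage 4: pairwise global identities over the passed hits and greedy
# dereplication at 99% into a non-redundant representative panel.

library(sdrmine)

out <- "results/derep"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

orfs <- read.delim("results/mining/orfs.tsv")
hits <- read.delim("results/search/hits.tsv")

passed <- orfs[orfs$orf_id %in% hits$orf_id[hits$passed], ]
prots <- setNames(passed$protein, passed$orf_id)

m <- identity_matrix(prots)
cl <- cluster_greedy(m, threshold = 99, seq_lengths = nchar(prots))
reps <- vapply(cl, `[[`, character(1), "representative")

write_identity_matrix(m, file.path(out, "identity_matrix.tsv"))
write_clusters(cl, file.path(out, "clusters.tsv"))
write_fasta(prots[reps], file.path(out, "representatives.faa"), "AA")

off <- m[upper.tri(m)]
cat(sprintf("%d hits -> %d clusters -> %d representatives at 99%%\n",
            length(prots), length(cl), length(reps)))
cat(sprintf("panel identity: mean %.1f%%, range %.1f-%.1f%%\n",
            mean(off), min(off), max(off)))
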