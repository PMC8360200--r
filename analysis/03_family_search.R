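#!/usr/bin/env Rscript
# Stage 3: score every candidate ORF against the seed enzymes by local
# alignment (self-score normalized) and the seed scoring profile; a candidate
# passes when either route clears its calibrated threshold.

library(sdrmine)

out <- "results/search"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seeds <- read_fasta("results/simulation/seeds.faa", "AA")
orfs <- read.delim("results/mining/orfs.tsv")
truth <- read.delim("results/simulation/truth.tsv")

hits <- score_orfs(orfs, seeds, build_profile(seeds))
write.table(hits, file.path(out, "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

key <- function(df) paste(df$contig_id, df$start, df$end, df$strand)
is_fam <- key(orfs) %in% key(truth[truth$is_family, ])
cat(sprintf("%d/%d ORFs pass the family search\n", sum(hits$passed), nrow(hits)))
cat(sprintf("sensitivity on planted family genes: %.2f (%d/%d)\n",
            mean(hits$passed[is_fam]), sum(hits$passed[is_fam]), sum(is_fam)))
cat(sprintf("false positives among non-family ORFs: %d/%d\n",
            sum(hits$passed[!is_fam]), sum(!is_fam)))
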