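#!/usr/bin/env Rscript
# Stage 7: Gibson primers for every representative gene against the mock
# expression vector, with full in-silico verification (PCR + assembly +
# His6 read-through).

library(sdrmine)

out <- "results/cloning"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

contigs <- read_fasta("results/simulation/contigs.fa", "DNA")
orfs <- read.delim("results/mining/orfs.tsv")
reps <- read_fasta("results/derep/representatives.faa", "AA")
rep_ids <- sub("\\|[^|]+\\|[0-9]+\\|[0-9]+\\|[+-]$", "", names(reps))

rows <- orfs[match(rep_ids, orfs$orf_id), ]
genes <- setNames(vapply(seq_len(nrow(rows)), function(i) {
  slice <- substr(contigs[[rows$contig_id[i]]], rows$start[i] + 1, rows$end[i])
  if (rows$strand[i] == "-") revcomp(slice) else slice
}, character(1)), rows$orf_id)

vec <- mock_vector()
primers <- primer_table(genes, vec)
write.table(primers, file.path(out, "primers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("designed %d primer pairs; %d/%d constructs validate with His6 read-through\n",
            nrow(primers), sum(primers$construct_valid), nrow(primers)))
cat(sprintf("annealing lengths %d-%d nt, Tm %.1f-%.1f C\n",
            min(primers$anneal_len_f, primers$anneal_len_r),
            max(primers$anneal_len_f, primers$anneal_len_r),
            min(primers$tm_f, primers$tm_r), max(primers$tm_f, primers$tm_r)))
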