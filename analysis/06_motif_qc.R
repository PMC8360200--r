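#!/usr/bin/env Rscript
# Stage 6: SDR hallmark QC on the representative panel — glycine-rich
# cofactor-binding motif and the Ser-Tyr-Lys (+Asn) catalytic constellation.

library(sdrmine)

out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reps <- read_fasta("results/derep/representatives.faa", "AA")
names(reps) <- sub("\\|[^|]+\\|[0-9]+\\|[0-9]+\\|[+-]$", "", names(reps))

qc <- qc_table(reps)
write.table(qc, file.path(out, "motif_qc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("motif QC: %d/%d representatives carry the glycine motif,\n",
            sum(qc$gly_pass), nrow(qc)))
cat(sprintf("          %d/%d the catalytic triad, %d/%d the full tetrad\n",
            sum(qc$triad_pass), nrow(qc), sum(qc$tetrad_pass), nrow(qc)))
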