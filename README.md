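# sdrmine

Sequence-directed metagenome mining for short-chain
dehydrogenase/reductase (SDR) carbonyl reductases, implemented as a tested
R package plus a numbered analysis workflow.

## The problem

SDRs are ~250-residue NAD(P)H-dependent oxidoreductases with a Rossmann
fold, a glycine-rich cofactor-binding motif (TGxxxGxG) and a catalytic
Ser-Tyr-Lys constellation (Tyr and Lys exactly four residues apart, often
with a supporting Asn). They reduce ketones to alcohols with high
stereoselectivity, which makes new family members valuable biocatalysts.
Assembled environmental DNA (contigs) can be mined for them directly:
find complete ORFs, score them against seed enzymes, collapse redundant
hits, check the family hallmarks, design cloning primers, and screen the
expressed panel by NAD(P)H depletion at 340 nm.

`sdrmine` implements that whole chain for people building or benchmarking
such screens:

| stage | functions |
|---|---|
| synthetic metagenome with ground truth | `generate_contigs()`, `mutate_protein()`, `plant_genes()` |
| six-frame ORF mining with screen filters | `find_orfs()`, `find_orfs_all()`, `filter_orfs()` |
| family search (local alignment + profile) | `smith_waterman()`, `build_profile()`, `score_orfs()` |
| dereplication | `global_identity()`, `identity_matrix()`, `cluster_greedy()` |
| comparative view | `neighbor_joining()`, `assign_clades()`, `heatmap_order()`, `to_newick()` |
| motif QC | `scan_gly_motif()`, `scan_catalytic()`, `qc_table()` |
| Gibson cloning in silico | `design_gibson_primers()`, `simulate_pcr()`, `simulate_gibson()` |
| plate-assay quantification | `delta_to_nadph()`, `conversion_percent()`, `screen_matrix()` |
| orchestration | `validate_config()`, `run_pipeline()` |

Key quantitative conventions (details and rationale in
`vignettes/sdr-mining.Rmd`): percent identity is identical columns over the
full global alignment length (gap columns included, EMBOSS-needle style);
local alignment is BLOSUM62 with affine gap cost `open + extend * L`
(11/1); candidates pass the family search when the self-score-normalized
local score reaches 0.18 or the ungapped profile score reaches 30% of its
maximum (both calibrated on planted-gene benchmarks and configurable);
dereplication is greedy longest-first clustering at 99% identity; the tree
is Saitou-Nei neighbor joining on `d = 1 - identity/100`; NAD(P)H
consumption is `(A0 - Aend)/(6220 * path)`.

## Worked example: the analysis workflow

The numbered scripts under `analysis/` reproduce the whole study flow on a
seeded synthetic metagenome — 100 contigs, 20 planted family genes spanning
30-98% identity to three seed enzymes, 20 shuffled decoys — writing tables
under `results/`:

```sh
Rscript analysis/01_simulate_metagenome.R
Rscript analysis/02_mine_orfs.R
Rscript analysis/03_family_search.R
Rscript analysis/04_dereplicate.R
Rscript analysis/05_phylogeny.R
Rscript analysis/06_motif_qc.R
Rscript analysis/07_design_primers.R
Rscript analysis/08_assay_screen.R
```

Output of a run:

```
wrote 100 contigs (193.8 kb total), 20 planted family genes, 20 decoys
mined 67 ORFs >= 230 aa from 100 contigs
planted-gene recovery at the length filter: 40/40
19/67 ORFs pass the family search
sensitivity on planted family genes: 0.95 (19/20)
false positives among non-family ORFs: 0/47
19 hits -> 19 clusters -> 19 representatives at 99%
panel identity: mean 32.8%, range 15.3-85.3%
built NJ tree over 19 representatives; 3 clades: 13/3/3
motif QC: 19/19 representatives carry the glycine motif,
          19/19 the catalytic triad, 19/19 the full tetrad
designed 19 primer pairs; 19/19 constructs validate with His6 read-through
screened 18 enzyme x substrate combinations in triplicate
hit recall 1.00, precision 1.00 at the 10% threshold
```

Reading: every planted gene survives the length filter; the search recovers
19/20 plants (the miss is the 30%-identity edge case) with zero false
positives among 47 decoy/background ORFs; nothing in the recovered panel is
redundant at 99% identity; all representatives carry the SDR hallmarks; and
every representative gene round-trips through primer design, in-silico PCR
and Gibson assembly into a validated His6 read-through construct. The same
flow runs on real data by pointing `run_pipeline()` at your own contig and
seed FASTA files:

```r
library(sdrmine)
cfg <- default_config("contigs.fa", "seeds.faa", out_dir = "run1")
run_pipeline(cfg)   # orfs.faa, hits.tsv, representatives.faa, tree.nwk,
                    # clades.tsv, motif_qc.tsv, primers.tsv, report.json
```

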