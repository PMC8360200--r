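---
title: "Sequence-directed mining of short-chain dehydrogenases/reductases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-directed mining of SDRs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrmine)
```

# The problem and the approach

Short-chain dehydrogenases/reductases (SDRs) are NAD(P)H-dependent
oxidoreductases of roughly 250 residues that reduce ketones and aldehydes to
alcohols, often with high stereoselectivity, which makes them attractive
biocatalysts. Environmental (metagenomic) DNA is a rich source of new family
members: assembled contigs can be mined *in silico* for candidate genes,
which are then cloned, expressed and screened. This package implements that
sequence-directed mining workflow end to end as testable code:

1. **ORF mining** — six-frame discovery of complete coding regions on
   contigs, with the screen's candidate filters (initiator methionine, stop
   codon inside the contig, minimum protein length);
2. **family search** — scoring candidates against a small set of seed
   enzymes by local alignment and by a position-specific scoring profile;
3. **dereplication** — pairwise global identities and greedy clustering into
   a non-redundant representative panel;
4. **comparative view** — a neighbor-joining tree on identity-derived
   distances, clade assignment, and a deterministic leaf ordering for
   heat-map rendering;
5. **motif QC** — verification of the family's sequence hallmarks
   (glycine-rich cofactor-binding motif, catalytic Ser-Tyr-Lys
   constellation);
6. **cloning** — Gibson-assembly primer design with stop-codon removal for
   His6 read-through, verified by in-silico PCR and assembly;
7. **assay quantification** — conversion of 340 nm plate-reader traces into
   NAD(P)H consumption, conversion percentages and hit calls.

Because the original environmental dataset is not redistributable, the
package carries its own **synthetic metagenome generator** that plants
divergence-controlled family genes and shuffled decoys into random contigs
with a ground-truth table. Every downstream claim in the test suite is made
against that ground truth.

# The synthetic metagenome: what it emulates, and what it does not

`generate_contigs()` draws contig lengths from a normal distribution
truncated at 300 bp and fills them with i.i.d. bases at a requested GC
fraction. The defaults (100 contigs, mean 2 kb, SD 0.5 kb, GC 0.45) are a
deliberately modest stand-in for an assembled oral-microbiome library, whose
true contig statistics were not reported; they are free parameters chosen
once so that a typical contig comfortably hosts one ~760 bp planted gene.

`plant_genes()` inserts each gene as a complete CDS — ATG, the
reverse-translated mutant protein, and a TAA stop — *overwriting* a random
non-overlapping window (coordinates of earlier plants therefore stay
stable), on a random strand by default. An in-frame TAA guard is placed
immediately before the ATG so that the six-frame scanner's
first-ATG-per-segment rule recovers exactly the planted protein. Decoys are
Fisher-Yates shuffles of family proteins: identical amino-acid composition,
destroyed order. This is the property that makes the benchmark meaningful —
a composition-only classifier cannot separate decoys from true family
members, so the alignment and profile machinery is genuinely exercised.

Divergence control (`mutate_protein()`) is substitution-only with an
adaptive step: random unprotected positions are replaced by a different
residue, achieved identity is measured with the package's own global
aligner, and the mutation count is adjusted until the measurement is within
±1 point of target (the contract guarantees ±2). Below roughly 15% identity
the chance identity of unrelated sequences under global alignment becomes
the floor and the generator refuses (`infeasible_target`) rather than
silently miss. With `keep_motifs` set, the full eight-residue TGxxxGxG
window, the five-residue Y-x-x-x-K window, the catalytic Ser and the
supporting Asn are protected. The spec of a "motif-protected" plant is
deliberately slightly wider than the two named patterns: the QC stage
requires a Ser upstream of the Tyr, so protecting the anchor but not the Ser
would make the 100%-pass benchmark claim vacuous.

What the generator does **not** emulate: sequencing error, assembly
artefacts, repeat structure, real codon usage (reverse translation uses the
most-frequent *E. coli* codon per residue — deterministic and sufficient for
DNA-level tests), operon context, or realistic intergenic composition.
Passing the planted-gene benchmarks therefore demonstrates correctness of
the mining machinery, not expected sensitivity on real environmental
assemblies.

# Alignment conventions and thresholds

All pairwise alignment goes through one documented convention. Local
(Smith-Waterman) alignment uses BLOSUM62 with affine gaps costing
`gap_open + gap_extend * L` (defaults 11/1); global (Needleman-Wunsch)
identity uses 10/0.5 and defines **percent identity as identical columns
over the full alignment length, terminal gaps included** (the
EMBOSS-needle convention). The denominator choice matters at low identity
and the original study did not state its tool, so the convention is explicit
and a `denominator = "shorter"` flag provides the alternative. Unknown
residues (`X`) score zero against everything. The engines are cross-checked
in the test suite against brute-force oracles: exhaustive enumeration of
alignments on short pairs, and enumeration of all substring pairs for the
local case.

The family search reports no E-values. A candidate's local-alignment score
is normalized by the self-score of its best seed, giving a scale-free
statistic in [0, 1]; the default pass threshold of 0.18 was calibrated on
planted-gene benchmarks (the original screen's BLAST cutoff is unpublished)
and is exposed in configuration, as is the profile-route threshold (0.3 of
the profile's maximum attainable score). The scoring profile is built from
the aligned seeds as log2 odds of pseudocounted column frequencies over a
uniform background (columns with more than 50% gaps dropped) and is slid
*ungapped* over the candidate; full profile-HMM machinery would be out of
proportion to its role here, since the gapped path is already covered by the
local aligner.

# Dereplication and the comparative view

Hits are clustered greedily, longest sequence first (ties lexicographic),
each joining the first cluster whose representative it matches at or above
the threshold — the CD-HIT recipe, chosen because it is deterministic and
standard. The default threshold is 99%: the original panel retained a
98%-identical pair as distinct entries, so the implied dereplication level
exceeds 98%. Representative choice is longest-then-lexicographic.

The tree is Saitou-Nei neighbor joining on `d = 1 - identity/100`. This is a
similarity display, not an evolutionary-rate estimate — no Poisson or other
saturation correction is applied, matching the figure the workflow
reproduces. Numerical details: the joined pair minimizes the Q criterion
with ties broken by the lexicographically smallest index pair; negative
branch lengths are clamped to zero with the deficit moved to the sister
branch so path lengths through the join are preserved; additive matrices are
therefore reproduced exactly (the suite checks path-length error below
1e-9 on random additive instances). Clades are produced by cutting branches
longest-first (internal before terminal) until the requested number of leaf
groups exists; `k = 3` by default, mirroring the three coloured clades of
the study's figure. Heat-map leaf order is a depth-first traversal with
children ordered by subtree size, ties by smallest leaf label — fully
deterministic and invariant to input row order.

# Motif QC

The glycine-rich motif is the leftmost TGxxxGxG whose T falls in the
N-terminal window (default positions 0-60). The catalytic scan anchors on
the canonical SDR geometry — every Tyr with a Lys exactly four residues
downstream — and accepts the first anchor that also has a Ser 10-25
residues upstream; an Asn 20-60 residues upstream of the Ser completes the
tetrad but its absence never fails the triad, since the fourth residue is
supporting evidence rather than a rejection criterion. The windows are
configurable: the original alignment-based confirmation published no
coordinates, so the defaults encode canonical SDR architecture rather than a
measured constraint. All positions are 0-based indices into the unmodified
input.

# Cloning simulation

`design_gibson_primers()` builds the forward primer as a 20 nt
vector-homology adapter plus the gene's 5' end from the ATG, and the reverse
primer as the reverse complement of the downstream vector arm plus the
reverse complement of the gene's 3' end *excluding the stop codon* — the
read-through construct places the vector's hexa-histidine tag in frame.
Annealing portions grow from 18 nt until the melting temperature reaches
60 °C or 30 nt is hit. The Tm model is deliberately simple and documented:
Wallace rule `2(A+T) + 4(G+C)` below 14 nt, otherwise
`64.9 + 41(GC - 16.4)/len`; both are composition-only, hence reverse
complement invariant. A gene without a terminal stop codon is rejected
(`invalid_argument`) because "remove the stop codon" would be undefined.

In-silico PCR requires both annealing sites to occur exactly once on the
template; assembly requires at least 15 nt of exact terminal homology per
junction and the validation asserts three things: the insert ATG sits at
the translation start site, no in-frame stop occurs before the tag, and the
fusion translates to insert-protein + Gly-Ser-Gly linker + HHHHHH + stop.
The bundled vector is a constructed mini-vector (synthetic; the true
expression-vector sequence is not printed in the source study);
`vector_spec()` accepts a real sequence when available.

# Assay quantification

Endpoint NAD(P)H consumption is `(A0 - Aend) / (6220 * path)` — the
standard 340 nm extinction coefficient, applied to both NADH and NADPH —
blank-corrected when a blank well is supplied and clipped into
`[0, cofactor]` with a warning. The optical path length is a *required*
input: vertical paths in plate wells depend on fill volume and silently
assuming one would bias every number downstream. Two conversion percentages
are always reported side by side: substrate-referenced (1:1 stoichiometry)
and cofactor-referenced. Without cofactor recycling the substrate-referenced
value is capped at `100 * cofactor / substrate` (20% at the screen's 1 mM /
5 mM conditions); endpoint screens in the literature are sometimes quoted on
either scale, and reporting both avoids guessing a convention. The endpoint
is the final cycle by default (fixed-duration incubation), with a
minimum-absorbance option for noisy traces. Initial rates are least-squares
slopes over the first n cycles (default 10).

# Problem sizes and determinism

Every generator and pipeline function is a pure function of its arguments
and an integer seed; reruns are byte-identical apart from timestamps in the
JSON run report. The benchmark sizes used by the test suite and the
acceptance script — 100 contigs of ~2 kb with 20 planted genes spanning
30-98% identity plus 20 decoys, a 37-member synthetic reference panel, 100
random additive matrices of 5-10 taxa, 200 random alignment pairs of length
at most 8 — were chosen as the smallest instances that still exercise every
code path and tie-break; they complete in a few minutes on one CPU.

# Known limitations

* Sensitivity/precision figures hold for the synthetic benchmark, not for
  real assemblies (no sequencing error or fragmented genes are modelled).
* The profile route is ungapped; a homolog with large insertions relative
  to the seeds is carried by the local-alignment route only.
* The search thresholds are calibrated, not canonical; re-screening with
  different thresholds only requires re-running the search stage.
* Neighbor joining on uncorrected identity distances understates deep
  divergences; the tree is an ordering/grouping device, not a dated
  phylogeny.
* The dereplication identity convention (full alignment length) depresses
  identities between sequences of very different lengths; the
  shorter-sequence denominator is available by flag.
* No cofactor-recycling kinetics are modelled; conversions above the
  stoichiometric ceiling are detectable only as the clipping warning.
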