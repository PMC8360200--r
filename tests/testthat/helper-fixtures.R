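# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fx_seeds <- function() cached("seeds", function() sdrmine::seed_proteins())

fx_templates <- function() cached("templates", function() {
  seeds <- fx_seeds()
  lapply(names(seeds), function(n) sdrmine::gene_template(n, seeds[[n]]))
})

# the 20-contig pipeline fixture: 6 planted family genes (40-90% identity),
# 6 shuffled decoys
fx_small_metagenome <- function() cached("small_mg", function() {
  ctg <- sdrmine::generate_contigs(20, 2500, 400, gc = 0.45, seed = 5)
  sdrmine::plant_genes(ctg, fx_templates(), round(seq(40, 90, length.out = 6)),
                       seed = 6, decoys = 6)
})

# the benchmark metagenome: 100 contigs, 20 planted family genes spanning
# 30-98% identity to the seeds, 20 shuffled decoys
fx_benchmark_metagenome <- function() cached("bench_mg", function() {
  ctg <- sdrmine::generate_contigs(100, 2000, 500, gc = 0.45, seed = 11)
  sdrmine::plant_genes(ctg, fx_templates(), round(seq(30, 98, length.out = 20)),
                       seed = 12, decoys = 20)
})

# match ORF records to truth records by exact (contig, start, end, strand)
truth_key <- function(df) paste(df$contig_id, df$start, df$end, df$strand)

# a valid CDS (ATG...TAA) for a given protein
cds_for <- function(protein) {
  paste0("ATG", sdrmine::reverse_translate(protein), "TAA")
}
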