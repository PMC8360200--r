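test_that("contig generation honours length, GC and seeded determinism", {
  one <- generate_contigs(1, length_mean = 1000, length_sd = 0, gc = 0.5, seed = 7)
  expect_length(one, 1)
  expect_equal(nchar(one[[1]]), 1000)

  many <- generate_contigs(100, length_mean = 1000, length_sd = 200, gc = 0.40, seed = 1)
  pooled <- paste(many, collapse = "")
  gc_frac <- mean(strsplit(pooled, "")[[1]] %in% c("G", "C"))
  expect_gte(gc_frac, 0.37)
  expect_lte(gc_frac, 0.43)
  expect_true(all(nchar(many) >= 300))

  a <- generate_contigs(5, 800, 150, 0.5, seed = 3)
  b <- generate_contigs(5, 800, 150, 0.5, seed = 3)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(a, f1, "DNA"); write_fasta(b, f2, "DNA")
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))

  expect_error(generate_contigs(0, 1000, 100, 0.5, 1), class = "invalid_argument")
  expect_error(generate_contigs(5, 100, 10, 0.5, 1), class = "invalid_argument")
  expect_error(generate_contigs(5, 1000, 100, 1.2, 1), class = "invalid_argument")
})

test_that("mutate_protein hits its identity target and respects motif protection", {
  tpl <- fx_templates()[[1]]
  expect_identical(as.character(mutate_protein(tpl, 100, seed = 1)), tpl$protein)

  m80 <- mutate_protein(tpl, 80, seed = 2)
  expect_gte(global_identity(m80, tpl$protein), 78)
  expect_lte(global_identity(m80, tpl$protein), 82)

  # identity control across the benchmark range, measured with the module's own aligner
  for (target in c(30, 50, 70, 90)) {
    m <- mutate_protein(tpl, target, seed = 100 + target)
    ach <- global_identity(m, tpl$protein)
    expect_gte(ach, target - 2)
    expect_lte(ach, target + 2)
  }

  # protected hallmark sites survive heavy mutation
  m30 <- mutate_protein(tpl, 30, seed = 9)
  q <- qc_table(setNames(as.character(m30), "m30"))
  expect_true(q$gly_pass)
  expect_true(q$triad_pass)

  expect_error(mutate_protein(tpl, 5, seed = 1), class = "infeasible_target")
})

test_that("gene templates validate alphabet and motif presence", {
  expect_error(gene_template("bad", "MKV1"), class = "invalid_argument")
  expect_error(gene_template("nomotif", strrep("A", 250), keep_motifs = TRUE),
               class = "invalid_argument")
  expect_s3_class(gene_template("ok", strrep("A", 50), keep_motifs = FALSE),
                  "gene_template")
})

test_that("planted genes translate to Met + mutant on their recorded strand", {
  pl <- fx_small_metagenome()
  expect_gt(nrow(pl$truth), 0)
  for (i in seq_len(nrow(pl$truth))) {
    r <- pl$truth[i, ]
    slice <- substr(pl$contigs[[r$contig_id]], r$start + 1, r$end)
    expect_equal((r$end - r$start) %% 3, 0)
    if (r$strand == "-") slice <- revcomp(slice)
    aa <- translate_dna(slice)
    expect_match(aa, "^M")
    expect_match(aa, "\\*$")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("six-frame mining recovers every planted gene (round trip)", {
  pl <- fx_small_metagenome()
  orfs <- find_orfs_all(pl$contigs, min_len_aa = 230)
  expect_true(all(truth_key(pl$truth) %in% truth_key(orfs)))
  # recovered protein equals Met + planted mutant for a - strand plant
  minus <- pl$truth[pl$truth$strand == "-", ][1, ]
  rec <- orfs[truth_key(orfs) == truth_key(minus), ]
  expect_equal(nrow(rec), 1)
  expect_equal(nchar(rec$protein), (minus$end - minus$start) / 3 - 1)
})

test_that("empty template list returns contigs unchanged with empty truth", {
  ctg <- generate_contigs(3, 500, 50, 0.5, seed = 2)
  out <- plant_genes(ctg, list(), numeric(0), seed = 1)
  expect_identical(out$contigs, ctg)
  expect_equal(nrow(out$truth), 0)
})

test_that("planting fails cleanly when no contig can host the gene", {
  ctg <- generate_contigs(2, 300, 0, 0.5, seed = 4)  # 300 bp < 759 bp cassette
  expect_error(plant_genes(ctg, fx_templates()[1], 90, seed = 1),
               class = "placement_error")
})

test_that("decoys keep composition but lose the motifs", {
  tpl <- fx_templates()[[1]]
  sh <- shuffle_protein(tpl$protein, seed = 3)
  expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(tpl$protein, "")[[1]]))
  expect_false(identical(sh, tpl$protein))
})
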