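test_that("melting temperature follows the documented two-regime formula", {
  expect_equal(melting_temp("AAAATTTT"), 16.0)
  expect_equal(melting_temp("ACGTACGTACGTACG"), 64.9 + 41 * (8 - 16.4) / 15)
  set.seed(37)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1), replace = TRUE),
               collapse = "")
    expect_equal(melting_temp(s), melting_temp(revcomp(s)))
  }
  expect_error(melting_temp("ACGTACG"), class = "invalid_argument")
  expect_error(melting_temp("ACGTNCGT"), class = "invalid_argument")
})

test_that("primer construction places adapters and annealing regions correctly", {
  v <- mock_vector()
  gene <- cds_for(random_protein(249))
  pp <- design_gibson_primers(gene, v)
  up_arm <- substr(v$sequence, v$site_start - 19, v$site_start)
  expect_equal(substr(pp$forward, 1, 20), up_arm)
  expect_equal(substr(pp$forward, 21, nchar(pp$forward)),
               substr(gene, 1, pp$anneal_len_f))
  # reverse anneal is the reverse complement of the gene 3' end minus the stop
  core <- substr(gene, 1, nchar(gene) - 3)
  expect_equal(substr(pp$reverse, 21, nchar(pp$reverse)),
               substr(revcomp(core), 1, pp$anneal_len_r))
  # the reverse annealing site on the gene stops short of the stop codon
  site <- revcomp(substr(pp$reverse, 21, nchar(pp$reverse)))
  pos <- regexpr(site, gene, fixed = TRUE)[1]
  expect_equal(pos + nchar(site) - 1, nchar(gene) - 3)
  expect_gte(pp$anneal_len_f, 18)
  expect_lte(pp$anneal_len_f, 30)
})

test_that("genes without a proper CDS structure are rejected", {
  v <- mock_vector()
  expect_error(design_gibson_primers("ATGAAACCC", v), class = "invalid_argument")  # no stop
  expect_error(design_gibson_primers(paste0("TTG", strrep("GCG", 20), "TAA"), v),
               class = "invalid_argument")  # no ATG start
  internal_stop <- paste0("ATG", strrep("GCG", 10), "TAA", strrep("GCG", 10), "TAA")
  expect_error(design_gibson_primers(internal_stop, v), class = "invalid_argument")
})

test_that("AT-rich genes need longer annealing regions at the same Tm target", {
  v <- mock_vector()
  at_rich <- paste0("ATG", strrep("AAT", 80), "TAA")   # asparagine repeat, GC = 0
  gc_rich <- paste0("ATG", strrep("GGC", 80), "TAA")   # glycine repeat, GC = 1
  pp_at <- design_gibson_primers(at_rich, v)
  pp_gc <- design_gibson_primers(gc_rich, v)
  expect_gt(pp_at$anneal_len_f, pp_gc$anneal_len_f)
})

test_that("simulated PCR yields adapter+CDS-without-stop+adapter exactly once", {
  v <- mock_vector()
  prot <- random_protein(249)
  gene <- cds_for(prot)
  pp <- design_gibson_primers(gene, v)
  amp <- simulate_pcr(gene, pp)
  expect_equal(nchar(amp), nchar(gene) - 3 + 2 * 20)
  # the internal CDS translates to the gene's protein with no stop
  inner <- substr(amp, 21, nchar(amp) - 20)
  expect_equal(translate_dna(inner), paste0("M", prot))
  # unrelated template fails amplification
  other <- cds_for(random_protein(249))
  expect_error(simulate_pcr(other, pp), class = "amplification_failure")
})

test_that("Gibson assembly validates the His6 read-through construct", {
  v <- mock_vector()
  prot <- random_protein(200)
  gene <- cds_for(prot)
  pp <- design_gibson_primers(gene, v)
  amp <- simulate_pcr(gene, pp)
  asm <- simulate_gibson(v, amp)
  expect_true(asm$valid)
  expect_equal(asm$fusion_protein, paste0("M", prot, "GSG", "HHHHHH"))

  # leaving the stop codon in flags a premature stop
  amp_stop <- paste0(substr(amp, 1, 20 + nchar(gene) - 3), "TAA",
                     substr(amp, 21 + nchar(gene) - 3, nchar(amp)))
  asm_stop <- simulate_gibson(v, amp_stop)
  expect_false(asm_stop$valid)
  expect_false(asm_stop$checks[["no_premature_stop"]])

  # trimming an overlap below the minimum names the failing junction
  short <- substr(amp, 11, nchar(amp))
  err <- tryCatch(simulate_gibson(v, short, overlap_min = 15), condition = identity)
  expect_s3_class(err, "assembly_failure")
  expect_match(conditionMessage(err), "upstream")
})

test_that("design -> PCR -> assembly round trip validates for all planted genes", {
  v <- mock_vector()
  pl <- fx_small_metagenome()
  orfs <- find_orfs_all(pl$contigs, min_len_aa = 230)
  fam <- orfs[truth_key(orfs) %in% truth_key(pl$truth[pl$truth$is_family, ]), ]
  expect_gt(nrow(fam), 0)
  for (i in seq_len(nrow(fam))) {
    slice <- substr(pl$contigs[[fam$contig_id[i]]], fam$start[i] + 1, fam$end[i])
    gene <- if (fam$strand[i] == "-") revcomp(slice) else slice
    pp <- design_gibson_primers(gene, v)
    asm <- simulate_gibson(v, simulate_pcr(gene, pp))
    expect_true(asm$valid)
    expect_true(startsWith(asm$fusion_protein, fam$protein[i]))
    expect_match(asm$fusion_protein, "HHHHHH$")
    # identical inputs give byte-identical primers
    pp2 <- design_gibson_primers(gene, v)
    expect_identical(pp, pp2)
  }
})
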