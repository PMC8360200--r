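#' Gibson-assembly primer design and in-silico cloning
#'
#' Each candidate gene is spliced into an expression vector the way the study
#' cloned its hits into pET29a: primers carry vector-homologous adapter tails
#' flanking the multiple-cloning-site span, the forward primer places the
#' initiator methionine at the translation start site, and the reverse primer
#' omits the endogenous stop codon so translation reads through into the
#' vector's hexa-histidine tag. PCR and Gibson assembly are then simulated
#' and the construct verified: insert ATG at the start site, no in-frame stop
#' before the tag, and a fusion protein ending ...HHHHHH-stop.
#'
#' The bundled [mock_vector()] is a constructed mini-vector (arbitrary
#' backbone, defined MCS span, Gly-Ser-Gly linker, His6, TAA); the real
#' vector sequence can be supplied through [vector_spec()] when available.
#'
#' @name primer_design
NULL

#' Describe an expression vector for Gibson cloning
#'
#' @param sequence Circular vector sequence, given linearized so that the
#'   insert replaces `[site_start, site_end)` (0-based half-open).
#' @param site_start,site_end MCS span replaced by the insert.
#' @param his6_offset_codons Codons from the insert's last sense codon to the
#'   first His codon (the in-frame linker length; default 3).
#' @return A `vector_spec` object (validated: His6 run present downstream of
#'   `site_end` in the declared frame).
#' @export
vector_spec <- function(sequence, site_start, site_end, his6_offset_codons = 3) {
  assert_that(site_start >= 0 && site_end >= site_start && site_end <= nchar(sequence),
              "invalid_argument", "MCS span outside the vector sequence")
  down <- substr(sequence, site_end + 1, nchar(sequence))
  tag_region <- substr(down, 1, 3 * (his6_offset_codons + 6))
  aa <- translate_dna(substr(tag_region, 1, 3 * (nchar(tag_region) %/% 3)))
  assert_that(grepl("HHHHHH", aa), "invalid_argument",
              "no in-frame His6 run downstream of the insertion site")
  structure(list(sequence = sequence, site_start = site_start, site_end = site_end,
                 his6_offset_codons = his6_offset_codons),
            class = "vector_spec")
}

#' A constructed mini expression vector for testing and simulation
#'
#' Synthetic stand-in for the (unpublished) expression-vector sequence: a
#' 360-bp backbone with a 24-bp MCS span, followed in frame by a GGT-AGC-GGT
#' (Gly-Ser-Gly) linker, six CAT/CAC His codons and a TAA stop.
#'
#' @return A [vector_spec()] object.
#' @export
mock_vector <- function() {
  up <- with_seed(29, paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE,
                                   prob = c(0.24, 0.26, 0.26, 0.24)), collapse = ""))
  mcs <- "GGATCCGAATTCAAGCTTCTCGAG"  # placeholder MCS span (replaced by insert)
  linker <- "GGTAGCGGT"
  his6 <- "CATCACCATCACCATCAC"
  tail <- with_seed(92, paste(sample(c("A", "C", "G", "T"), 140, replace = TRUE),
                              collapse = ""))
  seqv <- paste0(up, mcs, linker, his6, "TAA", tail)
  vector_spec(seqv, site_start = nchar(up), site_end = nchar(up) + nchar(mcs),
              his6_offset_codons = 3)
}

#' Primer melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` below 14 nt, otherwise
#' `64.9 + 41 * (GC - 16.4) / length`. Composition-only, hence invariant
#' under reverse complement.
#'
#' @param seq DNA sequence, ACGT only, length >= 8.
#' @return Temperature in degrees Celsius.
#' @export
melting_temp <- function(seq) {
  assert_that(nchar(seq) >= 8, "invalid_argument", "sequence must be >= 8 nt")
  assert_that(!grepl("[^ACGT]", seq), "invalid_argument",
              "ambiguous bases not allowed in melting_temp")
  b <- strsplit(seq, "")[[1]]
  gc <- sum(b %in% c("G", "C"))
  at <- length(b) - gc
  if (length(b) < 14) 2 * at + 4 * gc
  else 64.9 + 41 * (gc - 16.4) / length(b)
}

check_cds <- function(gene) {
  assert_that(nchar(gene) %% 3 == 0, "invalid_argument",
              "gene length must be a multiple of 3")
  assert_that(substr(gene, 1, 3) == "ATG", "invalid_argument",
              "gene must start with ATG")
  last <- substr(gene, nchar(gene) - 2, nchar(gene))
  assert_that(last %in% STOP_CODONS, "invalid_argument",
              "gene must end with a stop codon (found %s); stop removal is undefined otherwise", last)
  aa <- translate_dna(gene)
  assert_that(!grepl("\\*", substr(aa, 1, nchar(aa) - 1)), "invalid_argument",
              "gene has an internal in-frame stop codon")
  invisible(aa)
}

grow_anneal <- function(seq_from_5p, tm_target, anneal_min, anneal_max) {
  L <- anneal_min
  while (L < anneal_max && melting_temp(substr(seq_from_5p, 1, L)) < tm_target) L <- L + 1
  substr(seq_from_5p, 1, L)
}

#' Design a Gibson primer pair for one gene
#'
#' The forward primer is vector-homology adapter + the gene's 5' end starting
#' at the ATG; the reverse primer is the reverse complement of the vector's
#' downstream arm + the reverse complement of the gene's 3' end excluding the
#' stop codon. Annealing portions grow from `anneal_min` until the melting
#' temperature reaches `tm_target` or `anneal_max` is hit.
#'
#' @param gene DNA CDS including its stop codon (`ATG ... stop`).
#' @param vector A [vector_spec()] object.
#' @param adapter_len Vector-homology adapter length in nt (default 20).
#' @param tm_target Annealing-portion melting temperature target in C
#'   (default 60).
#' @param anneal_min,anneal_max Annealing length bounds in nt (default 18-30).
#' @return A `primer_pair`: list with `forward`, `reverse`, `anneal_len_f`,
#'   `anneal_len_r`, `tm_f`, `tm_r`, `adapter_len`.
#' @export
design_gibson_primers <- function(gene, vector, adapter_len = 20, tm_target = 60,
                                  anneal_min = 18, anneal_max = 30) {
  check_cds(gene)
  assert_that(inherits(vector, "vector_spec"), "invalid_argument",
              "vector must be a vector_spec")
  assert_that(vector$site_start >= adapter_len, "invalid_argument",
              "vector upstream arm shorter than adapter_len")
  core <- substr(gene, 1, nchar(gene) - 3)  # stop codon removed
  up_arm <- substr(vector$sequence, vector$site_start - adapter_len + 1, vector$site_start)
  down_arm <- substr(vector$sequence, vector$site_end + 1, vector$site_end + adapter_len)
  f_anneal <- grow_anneal(core, tm_target, anneal_min, anneal_max)
  r_anneal <- grow_anneal(revcomp(core), tm_target, anneal_min, anneal_max)
  structure(list(forward = paste0(up_arm, f_anneal),
                 reverse = paste0(revcomp(down_arm), r_anneal),
                 anneal_len_f = nchar(f_anneal), anneal_len_r = nchar(r_anneal),
                 tm_f = melting_temp(f_anneal), tm_r = melting_temp(r_anneal),
                 adapter_len = adapter_len),
            class = "primer_pair")
}

count_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Simulate PCR of a gene with an adapter-bearing primer pair
#'
#' @param gene Template DNA (the CDS the pair was designed for).
#' @param pair A [design_gibson_primers()] pair.
#' @return The amplicon: forward adapter + amplified gene span (stop codon
#'   excluded by the reverse primer) + downstream vector arm.
#' @export
simulate_pcr <- function(gene, pair) {
  f_ad <- substr(pair$forward, 1, pair$adapter_len)
  f_an <- substr(pair$forward, pair$adapter_len + 1, nchar(pair$forward))
  r_ad <- substr(pair$reverse, 1, pair$adapter_len)
  r_an <- substr(pair$reverse, pair$adapter_len + 1, nchar(pair$reverse))
  r_site <- revcomp(r_an)  # where the reverse primer anneals, on the + strand
  nf <- count_matches(f_an, gene)
  nr <- count_matches(r_site, gene)
  if (nf != 1L || nr != 1L) {
    stop_sdr("amplification_failure",
             "primer annealing not unique on template (forward: %d site(s), reverse: %d site(s))",
             nf, nr)
  }
  fpos <- regexpr(f_an, gene, fixed = TRUE)[1]
  rpos <- regexpr(r_site, gene, fixed = TRUE)[1] + nchar(r_site) - 1
  assert_that(fpos < rpos, "amplification_failure", "primers face away from each other")
  paste0(f_ad, substr(gene, fpos, rpos), revcomp(r_ad))
}

#' Simulate Gibson assembly and verify the construct
#'
#' @param vector A [vector_spec()] object.
#' @param amplicon Amplicon from [simulate_pcr()].
#' @param overlap_min Minimum exact terminal homology in nt (default 15).
#' @return A `plasmid_assembly`: list with `sequence` (assembled circle,
#'   linearized at the vector origin), `insert_start` (0-based ATG position),
#'   `fusion_protein`, `valid` flag and `checks` (named logicals:
#'   `atg_at_start`, `no_premature_stop`, `his6_read_through`).
#' @export
simulate_gibson <- function(vector, amplicon, overlap_min = 15) {
  U <- substr(vector$sequence, 1, vector$site_start)
  D <- substr(vector$sequence, vector$site_end + 1, nchar(vector$sequence))
  ov_u <- 0
  for (o in seq_len(min(nchar(U), nchar(amplicon)))) {
    if (substr(amplicon, 1, o) == substr(U, nchar(U) - o + 1, nchar(U))) ov_u <- o
  }
  if (ov_u < overlap_min) {
    stop_sdr("assembly_failure",
             "upstream junction overlap %d nt below the %d nt minimum", ov_u, overlap_min)
  }
  ov_d <- 0
  for (o in seq_len(min(nchar(D), nchar(amplicon)))) {
    if (substr(amplicon, nchar(amplicon) - o + 1, nchar(amplicon)) == substr(D, 1, o)) ov_d <- o
  }
  if (ov_d < overlap_min) {
    stop_sdr("assembly_failure",
             "downstream junction overlap %d nt below the %d nt minimum", ov_d, overlap_min)
  }
  core <- substr(amplicon, ov_u + 1, nchar(amplicon) - ov_d)
  plasmid <- paste0(U, core, D)
  ins0 <- vector$site_start  # 0-based expected ATG position
  atg_ok <- substr(plasmid, ins0 + 1, ins0 + 3) == "ATG"
  fusion <- ""
  his_ok <- FALSE
  stop_ok <- FALSE
  if (atg_ok) {
    rest <- substr(plasmid, ins0 + 1, nchar(plasmid))
    rest <- substr(rest, 1, 3 * (nchar(rest) %/% 3))
    aa <- translate_dna(rest)
    stop_at <- regexpr("*", aa, fixed = TRUE)[1]
    fusion <- if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
    his_ok <- grepl("HHHHHH$", fusion)
    expected_len <- nchar(core) / 3 + 3 + 6  # insert codons + linker + His6
    stop_ok <- stop_at > 0 && his_ok && nchar(fusion) == expected_len
  }
  structure(list(sequence = plasmid, insert_start = ins0, fusion_protein = fusion,
                 valid = atg_ok && stop_ok && his_ok,
                 checks = c(atg_at_start = atg_ok, no_premature_stop = stop_ok,
                            his6_read_through = his_ok)),
            class = "plasmid_assembly")
}

#' Design and verify primers for a table of genes
#'
#' @param genes Named character vector of CDS sequences (with stops).
#' @param vector A [vector_spec()] object.
#' @param ... Passed to [design_gibson_primers()].
#' @return data.frame: `gene_id`, `forward_seq`, `reverse_seq`,
#'   `anneal_len_f`, `anneal_len_r`, `tm_f`, `tm_r`, `construct_valid`.
#' @export
primer_table <- function(genes, vector, ...) {
  rows <- lapply(seq_along(genes), function(i) {
    pair <- design_gibson_primers(genes[[i]], vector, ...)
    amp <- simulate_pcr(genes[[i]], pair)
    asm <- simulate_gibson(vector, amp)
    data.frame(gene_id = names(genes)[i], forward_seq = pair$forward,
               reverse_seq = pair$reverse, anneal_len_f = pair$anneal_len_f,
               anneal_len_r = pair$anneal_len_r, tm_f = pair$tm_f, tm_r = pair$tm_r,
               construct_valid = asm$valid, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), forward_seq = character(),
                      reverse_seq = character(), anneal_len_f = integer(),
                      anneal_len_r = integer(), tm_f = numeric(), tm_r = numeric(),
                      construct_valid = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
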