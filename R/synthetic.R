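#' Synthetic metagenome with planted SDR genes
#'
#' The simulator stands in for the environmental (oral) metagenome: random
#' bacterial-like contigs into which divergence-controlled SDR-family genes
#' and shuffled decoys are planted on both strands, together with a
#' ground-truth table, so every downstream stage (ORF mining, family search,
#' dereplication, phylogeny, motif QC, cloning) can be benchmarked without
#' external data. Decoys are Fisher-Yates shuffles of family proteins: they
#' keep amino-acid composition but destroy order, so only alignment-based
#' search can separate them from true family members.
#'
#' @name synthetic_metagenome
NULL

# most-frequent E. coli K-12 codon per residue; deterministic reverse
# translation never introduces an internal stop codon
ECOLI_TOP_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG", E = "GAA",
  G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA", M = "ATG", F = "TTT",
  P = "CCG", S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")

#' Most-frequent-codon table used for reverse translation
#' @return Named character vector mapping residue to codon.
#' @export
most_frequent_codons <- function() ECOLI_TOP_CODON

#' Deterministic reverse translation
#'
#' @param protein Protein sequence (20 canonical residues).
#' @param codon_table Named residue-to-codon map
#'   (default [most_frequent_codons()]).
#' @return DNA coding sequence (no start or stop codon appended).
#' @export
reverse_translate <- function(protein, codon_table = most_frequent_codons()) {
  res <- strsplit(protein, "")[[1]]
  assert_that(all(res %in% names(codon_table)), "invalid_argument",
              "protein contains residues absent from the codon table")
  paste(codon_table[res], collapse = "")
}

#' A gene template for planting
#'
#' @param id Template identifier.
#' @param protein Protein sequence over the 20 canonical residues.
#' @param keep_motifs Protect the SDR hallmark sites (glycine-rich motif
#'   window, Y-x-x-x-K anchor, catalytic Ser and upstream Asn) from mutation.
#'   Requires both hallmarks to be present in the template.
#' @return A `gene_template` object.
#' @export
gene_template <- function(id, protein, keep_motifs = TRUE) {
  assert_that(nzchar(protein), "invalid_argument", "template protein must be non-empty")
  res <- strsplit(protein, "")[[1]]
  assert_that(all(res %in% AA20), "invalid_argument",
              "template protein must use the 20 canonical residues")
  if (keep_motifs) {
    g <- scan_gly_motif(protein)
    cat_ <- scan_catalytic(protein)
    assert_that(!is.na(g) && cat_$triad_pass, "invalid_argument",
                "keep_motifs requires both the TGxxxGxG and Ser..YxxxK motifs in '%s'", id)
  }
  structure(list(id = id, protein = protein, keep_motifs = keep_motifs),
            class = "gene_template")
}

# 1-based indices of residues protected from mutation: the full 8-residue
# glycine motif window, the 5-residue YxxxK window, the catalytic Ser and the
# supporting Asn when present
protected_positions <- function(protein) {
  g <- scan_gly_motif(protein)
  cat_ <- scan_catalytic(protein)
  idx <- integer(0)
  if (!is.na(g)) idx <- c(idx, (g + 1):(g + 8))
  if (cat_$triad_pass) {
    idx <- c(idx, (cat_$tyr_pos + 1):(cat_$tyr_pos + 5), cat_$ser_pos + 1)
    if (!is.na(cat_$asn_pos)) idx <- c(idx, cat_$asn_pos + 1)
  }
  sort(unique(idx))
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only mutagenesis with an adaptive step: random unprotected
#' positions are replaced by a different residue, the achieved identity is
#' measured with the package's own global aligner ([global_identity()]), and
#' the mutation count is adjusted until the measurement falls within the
#' tolerance. With `keep_motifs` set on the template, hallmark positions are
#' never touched.
#'
#' @param template A [gene_template()] (or plain protein string, treated as
#'   `keep_motifs = FALSE`).
#' @param target_identity Desired percent identity to the template, in
#'   \[10, 100\].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param tol Acceptance tolerance in percentage points (default 1; the
#'   contract guarantees +/- 2).
#' @return Mutated protein with attribute `achieved_identity`.
#' @export
mutate_protein <- function(template, target_identity, seed = NULL, tol = 1) {
  if (is.character(template)) template <- gene_template("template", template, keep_motifs = FALSE)
  if (!is.null(seed)) return(with_seed(seed, mutate_protein(template, target_identity, NULL, tol)))
  prot <- template$protein
  res <- strsplit(prot, "")[[1]]
  len <- length(res)
  prot_idx <- if (template$keep_motifs) protected_positions(prot) else integer(0)
  floor_identity <- 100 * length(prot_idx) / len
  assert_that(target_identity >= floor_identity, "infeasible_target",
              "target identity %.1f%% below the %.1f%% floor set by protected motif sites",
              target_identity, floor_identity)
  assert_that(target_identity >= 10 && target_identity <= 100, "invalid_argument",
              "target_identity must be in [10, 100]")
  if (target_identity == 100) {
    out <- prot
    attr(out, "achieved_identity") <- 100
    return(out)
  }
  mutable <- setdiff(seq_len(len), prot_idx)
  n_mut <- min(length(mutable), round(len * (1 - target_identity / 100)))
  best <- NULL; best_gap <- Inf
  for (iter in 1:40) {
    mut <- res
    if (n_mut > 0) {
      at <- sample(mutable, n_mut)
      mut[at] <- vapply(mut[at], function(r) sample(setdiff(AA20, r), 1), character(1))
    }
    cand <- paste(mut, collapse = "")
    ach <- global_identity(cand, prot)
    gap <- ach - target_identity
    if (abs(gap) < best_gap) { best <- cand; best_gap <- abs(gap); attr(best, "achieved_identity") <- ach }
    if (abs(gap) <= tol) break
    step <- round(gap / 100 * len)
    if (step == 0) step <- sign(gap)
    n_mut <- max(0, min(length(mutable), n_mut + step))
  }
  if (best_gap > 2) {
    stop_sdr("infeasible_target",
             "could not reach %.1f%% identity (closest achieved: off by %.1f points)",
             target_identity, best_gap)
  }
  best
}

#' Fisher-Yates shuffle of a protein (decoy construction)
#'
#' @param protein Protein sequence.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Shuffled protein (same composition, destroyed order).
#' @export
shuffle_protein <- function(protein, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, shuffle_protein(protein)))
  paste(sample(strsplit(protein, "")[[1]]), collapse = "")
}

#' Generate random bacterial-like contigs
#'
#' Contig lengths are drawn from a normal distribution truncated at `min_len`
#' (>= 300 bp); bases are i.i.d. with the requested GC content. Identical
#' arguments and seed give identical output.
#'
#' @param n Number of contigs (>= 1).
#' @param length_mean,length_sd Mean and SD of contig length in bp
#'   (`length_mean >= 300`, `length_sd >= 0`).
#' @param gc Target GC fraction, in (0, 1).
#' @param seed Integer seed.
#' @param min_len Lower truncation for contig length (default 300 bp).
#' @return Named character vector of DNA sequences (`contig_0001`, ...).
#' @export
generate_contigs <- function(n, length_mean = 2000, length_sd = 500, gc = 0.45,
                             seed = 1, min_len = 300) {
  assert_that(is.numeric(n) && n >= 1, "invalid_argument", "n must be >= 1")
  assert_that(gc > 0 && gc < 1, "invalid_argument", "gc must be in (0, 1)")
  assert_that(length_mean >= 300 && length_sd >= 0, "invalid_argument",
              "length_mean must be >= 300 and length_sd >= 0")
  with_seed(seed, {
    lens <- pmax(min_len, round(rnorm(n, length_mean, length_sd)))
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    setNames(seqs, sprintf("contig_%04d", seq_len(n)))
  })
}

# overwrite a window of equal length inside a contig (keeps coordinates of
# previously planted genes stable)
overwrite_at <- function(contig, pos1, cassette) {
  substr(contig, pos1, pos1 + nchar(cassette) - 1) <- cassette
  contig
}

#' Plant family genes and decoys into contigs
#'
#' Each planted gene is a complete CDS (ATG + reverse-translated mutant
#' protein + TAA) preceded by an in-frame TAA guard stop, so six-frame ORF
#' discovery recovers exactly the planted protein. Genes are overwritten into
#' random non-overlapping windows, on a random strand under
#' `strand_policy = "both"`. Decoys are planted the same way from shuffled
#' family proteins.
#'
#' @param contigs Named character vector of contigs.
#' @param templates List of [gene_template()] objects (recycled if shorter
#'   than `identities`).
#' @param identities Percent identity target for each planted gene.
#' @param strand_policy `"both"` (random strand) or `"forward"`.
#' @param codon_table Residue-to-codon map for reverse translation.
#' @param seed Integer seed.
#' @param decoys Number of shuffled decoy genes to plant (default 0).
#' @return List with `contigs` (modified) and `truth` (data.frame:
#'   `contig_id`, `gene_id`, `start`, `end`, `strand`, `planted_identity`,
#'   `is_family`; 0-based half-open coords spanning ATG..stop).
#' @export
plant_genes <- function(contigs, templates, identities,
                        strand_policy = c("both", "forward"),
                        codon_table = most_frequent_codons(),
                        seed = 1, decoys = 0) {
  strand_policy <- match.arg(strand_policy)
  empty_truth <- data.frame(contig_id = character(), gene_id = character(),
                            start = integer(), end = integer(), strand = character(),
                            planted_identity = numeric(), is_family = logical(),
                            stringsAsFactors = FALSE)
  if (length(identities) == 0 && decoys == 0) {
    return(list(contigs = contigs, truth = empty_truth))
  }
  assert_that(length(templates) >= 1, "invalid_argument",
              "at least one template is required to plant genes")
  with_seed(seed, {
    occupied <- lapply(contigs, function(x) matrix(numeric(0), ncol = 2))
    truth <- list()
    jobs <- list()
    for (i in seq_along(identities)) {
      tpl <- templates[[(i - 1) %% length(templates) + 1]]
      prot <- mutate_protein(tpl, identities[i])
      jobs[[length(jobs) + 1]] <- list(id = sprintf("fam_%02d", i), protein = prot,
                                       identity = as.numeric(attr(prot, "achieved_identity")),
                                       family = TRUE)
    }
    for (j in seq_len(decoys)) {
      tpl <- templates[[(j - 1) %% length(templates) + 1]]
      jobs[[length(jobs) + 1]] <- list(id = sprintf("decoy_%02d", j),
                                       protein = shuffle_protein(tpl$protein),
                                       identity = NA_real_, family = FALSE)
    }
    for (job in jobs) {
      cds <- paste0("ATG", reverse_translate(job$protein, codon_table), "TAA")
      cassette <- paste0("TAA", cds)  # in-frame guard stop before the ATG
      clen <- nchar(cassette)
      strand <- if (strand_policy == "forward") "+" else sample(c("+", "-"), 1)
      ins <- if (strand == "+") cassette else revcomp(cassette)
      placed <- FALSE
      order_try <- sample(seq_along(contigs))
      for (ci in order_try) {
        L <- nchar(contigs[[ci]])
        if (L < clen) next
        for (try in 1:200) {
          pos1 <- sample.int(L - clen + 1, 1)
          iv <- c(pos1, pos1 + clen - 1)
          occ <- occupied[[ci]]
          if (nrow(occ) > 0 && any(iv[1] <= occ[, 2] & iv[2] >= occ[, 1])) next
          contigs[[ci]] <- overwrite_at(contigs[[ci]], pos1, ins)
          occupied[[ci]] <- rbind(occ, iv)
          q <- pos1 - 1  # 0-based cassette start
          if (strand == "+") { gs <- q + 3; ge <- q + 3 + nchar(cds) }
          else { gs <- q; ge <- q + nchar(cds) }
          truth[[length(truth) + 1]] <- data.frame(
            contig_id = names(contigs)[ci], gene_id = job$id,
            start = gs, end = ge, strand = strand,
            planted_identity = job$identity, is_family = job$family,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) stop_sdr("placement_error", "no contig can host gene '%s' (%d bp)", job$id, clen)
    }
    list(contigs = contigs, truth = if (length(truth)) do.call(rbind, truth) else empty_truth)
  })
}

#' Write the ground-truth table as TSV
#' @param truth Truth data.frame from [plant_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) write_tsv(truth, path)

#' Synthetic SDR seed enzymes
#'
#' Three synthetic ~250-aa SDR-like proteins standing in for the study's seed
#' carbonyl reductases (which are not printed in the text). All carry the
#' canonical architecture: a TGxxxGxG glycine motif near the N-terminus and
#' the Asn..Ser..Tyr-x-x-x-Lys catalytic constellation. They are derived from
#' a common synthetic ancestor at roughly 55% identity to one another, so the
#' seed set is diverse but clearly one family.
#'
#' @return Named character vector of three proteins
#'   (`seed_1`, `seed_2`, `seed_3`).
#' @export
seed_proteins <- function() {
  with_seed(73, {
    len <- 250
    bg <- c(8.3, 5.5, 4.1, 5.5, 1.4, 3.9, 6.7, 7.1, 2.3, 6.0,
            9.7, 5.8, 2.4, 3.9, 4.7, 6.6, 5.4, 1.1, 2.9, 6.9)  # UniProt-like composition
    anc <- sample(AA20, len, replace = TRUE, prob = bg / sum(bg))
    anc[7:14] <- strsplit("TGASRGIG", "")[[1]]   # glycine-rich cofactor motif
    anc[101] <- "N"                               # tetrad Asn
    anc[139] <- "S"                               # catalytic Ser
    anc[153] <- "Y"; anc[157] <- "K"              # Y-x-x-x-K anchor
    anc <- paste(anc, collapse = "")
    tpl <- gene_template("ancestor", anc, keep_motifs = TRUE)
    seeds <- vapply(1:3, function(i) as.character(mutate_protein(tpl, 72)), character(1))
    setNames(seeds, c("seed_1", "seed_2", "seed_3"))
  })
}

#' Synthetic 37-member SDR reference panel
#'
#' A synthetic stand-in for the study's panel of retrieved enzymes: 37
#' proteins derived from the three synthetic seeds at planted identities
#' spanning distant (~15%) to near-duplicate (98%) levels, including one
#' engineered 98%-identity pair so dereplication behaviour near its threshold
#' is exercised. The panel is synthetic: its identity statistics follow from
#' this construction, not from the published sequences.
#'
#' @param seed Integer seed.
#' @return Named character vector of 37 proteins (`sSDR-01` ... `sSDR-37`)
#'   with attribute `parents` (data.frame of parent seed and target identity).
#' @export
synthetic_sdr_panel <- function(seed = 1) {
  seeds <- seed_proteins()
  with_seed(seed, {
    targets <- c(15, 18, 20, 22, 24, 26, 28, 30, 32, 35, 38, 40,
                 42, 45, 48, 50, 52, 55, 58, 60, 62, 65, 68, 70,
                 72, 75, 78, 80, 82, 85, 88, 90, 92, 95, 30, 50)
    parents <- rep(1:3, length.out = length(targets))
    prots <- character(0)
    meta <- list()
    for (i in seq_along(targets)) {
      tpl <- gene_template(paste0("seed_", parents[i]), seeds[[parents[i]]], keep_motifs = TRUE)
      p <- as.character(mutate_protein(tpl, targets[i]))
      prots <- c(prots, p)
      meta[[i]] <- data.frame(parent = names(seeds)[parents[i]], target = targets[i])
    }
    # engineered near-duplicate: member 37 is the 98%-identity twin of member 36
    twin <- as.character(mutate_protein(gene_template("m36", prots[36], keep_motifs = FALSE), 98))
    prots <- c(prots, twin)
    meta[[37]] <- data.frame(parent = "sSDR-36", target = 98)
    out <- setNames(prots, sprintf("sSDR-%02d", seq_along(prots)))
    attr(out, "parents") <- do.call(rbind, meta)
    out
  })
}

#' Identity statistics for an SDR panel
#'
#' Computes the pairwise global-identity matrix and the summary statistics the
#' comparative stage reports: mean/min/max off-diagonal identity and, when
#' requested, identities of named pairs and the mean identity within a subset
#' (e.g. a selected screening panel).
#'
#' @param proteins Named character vector of proteins (>= 2).
#' @param pairs Optional 2-column character matrix of id pairs to report.
#' @param subset Optional character vector of ids whose within-subset mean
#'   identity is reported.
#' @return List with `matrix`, `mean`, `min`, `max`, and optionally
#'   `pair_identity` (named numeric) and `subset_mean`.
#' @export
si_panel_stats <- function(proteins, pairs = NULL, subset = NULL) {
  m <- identity_matrix(proteins)
  off <- m[upper.tri(m)]
  out <- list(matrix = m, mean = mean(off), min = min(off), max = max(off))
  if (!is.null(pairs)) {
    out$pair_identity <- setNames(
      vapply(seq_len(nrow(pairs)), function(i) m[pairs[i, 1], pairs[i, 2]], numeric(1)),
      paste(pairs[, 1], pairs[, 2], sep = "/"))
  }
  if (!is.null(subset)) {
    sm <- m[subset, subset, drop = FALSE]
    out$subset_mean <- mean(sm[upper.tri(sm)])
  }
  out
}
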