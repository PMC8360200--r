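#' Six-frame ORF discovery
#'
#' Candidate coding regions are mined from both strands of each contig under
#' the selection rule used for the metagenome screen: an ORF must begin at an
#' initiator methionine (ATG only), end at a stop codon that lies within the
#' contig, and encode a protein of at least `min_len_aa` residues. Within
#' each stop-to-stop segment of a reading frame at most one ORF is reported,
#' anchored at the segment's first ATG (an `all_starts` flag exposes every
#' nested start instead). Coordinates are 0-based, half-open, on the forward
#' strand, and include the stop codon.
#'
#' @name orf_mining
NULL

.code_cache <- new.env(parent = emptyenv())

genetic_code <- function(code = "11") {
  if (is.null(.code_cache[[code]])) .code_cache[[code]] <- getGeneticCode(code)
  .code_cache[[code]]
}

#' Translate a DNA sequence
#'
#' @param dna DNA sequence; length must be divisible by 3. `N` is allowed;
#'   any codon containing an ambiguous base translates to `X`.
#' @param code Genetic code id (default `"11"`, bacterial/plastid).
#' @return Protein string; stops rendered as `*`. Empty input gives `""`.
#' @export
translate_dna <- function(dna, code = "11") {
  assert_that(nchar(dna) %% 3 == 0, "invalid_argument",
              "DNA length (%d) is not divisible by 3", nchar(dna))
  if (nchar(dna) == 0) return("")
  as.character(translate(DNAString(dna), genetic.code = genetic_code(code),
                         if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# translate a vector of codons via direct table lookup (fast path for ORF
# scanning); codons with ambiguity become X
translate_codons <- function(codons, code = "11") {
  gc <- genetic_code(code)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

scan_frames_one_strand <- function(s, contig_id, strand, L, min_len_aa, starts,
                                   code, all_starts, max_x_frac) {
  out <- list()
  for (frame in 0:2) {
    ncod <- (nchar(s) - frame) %/% 3
    if (ncod < 2) next
    from <- frame + 1 + 3 * (seq_len(ncod) - 1)
    codons <- substring(s, from, from + 2)
    aa <- translate_codons(codons, code)
    stops <- which(aa == "*")
    is_start <- codons %in% starts
    seg_begin <- 1L
    for (t in stops) {
      if (t > seg_begin) {
        cand <- which(is_start[seg_begin:(t - 1)]) + seg_begin - 1L
        if (length(cand) > 0) {
          picks <- if (all_starts) cand else cand[1]
          for (a in picks) {
            plen <- t - a
            if (plen < min_len_aa) next
            prot <- paste(aa[a:(t - 1)], collapse = "")
            nx <- sum(aa[a:(t - 1)] == "X")
            if (nx / plen > max_x_frac) next
            s_start <- frame + (a - 1) * 3      # 0-based on this strand
            s_end <- frame + t * 3              # includes the stop codon
            if (strand == "+") { f_start <- s_start; f_end <- s_end }
            else { f_start <- L - s_end; f_end <- L - s_start }
            out[[length(out) + 1]] <- data.frame(
              orf_id = sprintf("%s|%s%d|%d", contig_id, strand, frame, f_start),
              contig_id = contig_id, start = f_start, end = f_end,
              strand = strand, frame = frame, protein = prot,
              stringsAsFactors = FALSE)
          }
        }
      }
      seg_begin <- t + 1L
    }
  }
  out
}

#' Find ORFs in a single contig (six frames)
#'
#' @param contig DNA sequence (character scalar, length >= 3).
#' @param contig_id Identifier used in the output records.
#' @param min_len_aa Minimum protein length in residues (default 230, the
#'   permissive reading of the screen's 230-250 aa filter).
#' @param starts Allowed start codons (default `"ATG"` only).
#' @param code Genetic code id (default `"11"`).
#' @param all_starts Report every nested ATG variant instead of one ORF per
#'   stop-bounded segment.
#' @param max_x_frac Drop ORFs whose protein exceeds this fraction of `X`
#'   residues (default 0.05).
#' @return data.frame of ORF records: `orf_id`, `contig_id`, `start`, `end`
#'   (0-based half-open, forward strand, stop codon included), `strand`,
#'   `frame` (on its own strand), `protein` (no stop symbol). Empty on no
#'   hits.
#' @export
find_orfs <- function(contig, contig_id = "contig", min_len_aa = 230,
                      starts = "ATG", code = "11", all_starts = FALSE,
                      max_x_frac = 0.05) {
  assert_that(nchar(contig) >= 3, "invalid_argument", "contig must be >= 3 bp")
  L <- nchar(contig)
  res <- c(scan_frames_one_strand(contig, contig_id, "+", L, min_len_aa,
                                  starts, code, all_starts, max_x_frac),
           scan_frames_one_strand(revcomp(contig), contig_id, "-", L, min_len_aa,
                                  starts, code, all_starts, max_x_frac))
  if (length(res) == 0) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

#' Find ORFs across a contig set
#'
#' @param contigs Named character vector of contigs.
#' @inheritParams find_orfs
#' @return Row-bound ORF table across all contigs.
#' @export
find_orfs_all <- function(contigs, min_len_aa = 230, starts = "ATG", code = "11",
                          all_starts = FALSE, max_x_frac = 0.05) {
  res <- lapply(seq_along(contigs), function(i) {
    find_orfs(contigs[[i]], names(contigs)[i] %||% paste0("contig_", i),
              min_len_aa, starts, code, all_starts, max_x_frac)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Re-filter an ORF table by protein length
#'
#' @param orfs ORF data.frame from [find_orfs()].
#' @param min_len_aa,max_len_aa Inclusive protein-length bounds
#'   (`max_len_aa = NULL` for no upper bound).
#' @return Stable-ordered subset of `orfs`.
#' @export
filter_orfs <- function(orfs, min_len_aa = 230, max_len_aa = NULL) {
  if (!is.null(max_len_aa)) {
    assert_that(min_len_aa <= max_len_aa, "invalid_argument",
                "min_len_aa (%d) exceeds max_len_aa (%d)", min_len_aa, max_len_aa)
  }
  if (nrow(orfs) == 0) return(orfs)
  len <- nchar(orfs$protein)
  keep <- len >= min_len_aa & (is.null(max_len_aa) | len <= (max_len_aa %||% Inf))
  orfs[keep, , drop = FALSE]
}

#' Write ORF records as protein FASTA and TSV table
#'
#' FASTA headers are `orf_id|contig|start|end|strand`.
#'
#' @param orfs ORF data.frame.
#' @param faa_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_orfs <- function(orfs, faa_path = NULL, tsv_path = NULL) {
  if (!is.null(faa_path)) {
    hdr <- sprintf("%s|%s|%d|%d|%s", orfs$orf_id, orfs$contig_id,
                   orfs$start, orfs$end, orfs$strand)
    write_fasta(setNames(orfs$protein, hdr), faa_path, type = "AA")
  }
  if (!is.null(tsv_path)) write_tsv(orfs, tsv_path)
  invisible(list(faa = faa_path, tsv = tsv_path))
}
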