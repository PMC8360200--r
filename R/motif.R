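#' SDR sequence hallmarks: motif scanning and QC
#'
#' Short-chain dehydrogenases/reductases carry two sequence hallmarks that the
#' screen uses as quality control: the N-terminal glycine-rich cofactor-binding
#' motif (TGxxxGxG, part of the Rossmann fold that binds NAD(P)H) and the
#' catalytic Ser-Tyr-Lys constellation in which the Tyr and Lys sit exactly
#' four residues apart (Y-x-x-x-K), with the Ser a short distance upstream and
#' a supporting Asn further upstream (the "tetrad"). All reported positions
#' are 0-based indices into the unmodified input protein.
#'
#' @name motif_qc
NULL

#' Scan for the glycine-rich cofactor-binding motif
#'
#' Finds the leftmost TGxxxGxG match whose first residue (the T) lies within
#' the configured N-terminal window.
#'
#' @param protein Protein sequence (character scalar).
#' @param window Integer pair `c(start, end)`: 0-based window for the motif's
#'   T position (default `c(0, 60)`).
#' @return 0-based position of the T, or `NA_integer_` when absent.
#' @export
scan_gly_motif <- function(protein, window = c(0, 60)) {
  assert_that(nzchar(protein), "invalid_argument", "protein must be non-empty")
  m <- gregexpr("TG...G.G", protein)[[1]]
  if (m[1] == -1L) return(NA_integer_)
  pos0 <- m - 1L  # 0-based
  hit <- pos0[pos0 >= window[1] & pos0 <= window[2]]
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

#' Scan for the catalytic Ser-Tyr-Lys (+Asn) constellation
#'
#' Every Tyr with a Lys at +4 is considered in order; the first pair that also
#' has a Ser in the configured upstream window anchors the triad. An Asn in
#' its own window upstream of the Ser completes the tetrad; its absence does
#' not fail the triad.
#'
#' @param protein Protein sequence.
#' @param ser_gap Allowed `tyr_pos - ser_pos` range (default `c(10, 25)`).
#' @param asn_gap Allowed `ser_pos - asn_pos` range (default `c(20, 60)`).
#' @return List with 0-based `tyr_pos`, `lys_pos`, `ser_pos`, `asn_pos`
#'   (`NA` when absent), and flags `triad_pass`, `tetrad_pass`.
#' @export
scan_catalytic <- function(protein, ser_gap = c(10, 25), asn_gap = c(20, 60)) {
  assert_that(nzchar(protein), "invalid_argument", "protein must be non-empty")
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  out <- list(tyr_pos = NA_integer_, lys_pos = NA_integer_,
              ser_pos = NA_integer_, asn_pos = NA_integer_,
              triad_pass = FALSE, tetrad_pass = FALSE)
  ys <- which(res == "Y")
  ys <- ys[ys + 4 <= n & res[ys + 4] == "K"]  # Y-x-x-x-K anchor
  for (y in ys) {
    s_lo <- y - ser_gap[2]; s_hi <- y - ser_gap[1]
    if (s_hi < 1) next
    s_cand <- which(res == "S")
    s_cand <- s_cand[s_cand >= max(1, s_lo) & s_cand <= s_hi]
    if (length(s_cand) == 0) next
    s <- max(s_cand)  # closest Ser upstream of the Tyr
    out$tyr_pos <- y - 1L
    out$lys_pos <- y + 3L
    out$ser_pos <- s - 1L
    out$triad_pass <- TRUE
    n_lo <- s - asn_gap[2]; n_hi <- s - asn_gap[1]
    if (n_hi >= 1) {
      n_cand <- which(res == "N")
      n_cand <- n_cand[n_cand >= max(1, n_lo) & n_cand <= n_hi]
      if (length(n_cand) > 0) {
        out$asn_pos <- max(n_cand) - 1L
        out$tetrad_pass <- TRUE
      }
    }
    break
  }
  out
}

#' Motif QC table for a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @param window,ser_gap,asn_gap Passed to [scan_gly_motif()] and
#'   [scan_catalytic()].
#' @return A data.frame (input order) with columns `orf_id`, `gly_pos`,
#'   `ser_pos`, `tyr_pos`, `lys_pos`, `asn_pos`, `gly_pass`, `triad_pass`,
#'   `tetrad_pass`, and `family_pass` (= gly_pass & triad_pass), the flag the
#'   screen uses to call a candidate motif-positive.
#' @export
qc_table <- function(proteins, window = c(0, 60), ser_gap = c(10, 25), asn_gap = c(20, 60)) {
  ids <- names(proteins) %||% as.character(seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    g <- scan_gly_motif(proteins[[i]], window)
    cat_ <- scan_catalytic(proteins[[i]], ser_gap, asn_gap)
    data.frame(orf_id = ids[i], gly_pos = g,
               ser_pos = cat_$ser_pos, tyr_pos = cat_$tyr_pos,
               lys_pos = cat_$lys_pos, asn_pos = cat_$asn_pos,
               gly_pass = !is.na(g), triad_pass = cat_$triad_pass,
               tetrad_pass = cat_$tetrad_pass,
               family_pass = !is.na(g) && cat_$triad_pass,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(orf_id = character(), gly_pos = integer(), ser_pos = integer(),
                      tyr_pos = integer(), lys_pos = integer(), asn_pos = integer(),
                      gly_pass = logical(), triad_pass = logical(),
                      tetrad_pass = logical(), family_pass = logical()))
  }
  do.call(rbind, rows)
}
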