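#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom Biostrings reverseComplement translate getGeneticCode
#' @importFrom Biostrings pairwiseAlignment pid score writeXStringSet readDNAStringSet readAAStringSet
#' @importFrom stats rnorm runif setNames sd coef lm
#' @importFrom utils read.delim write.table data
NULL

# the 20 canonical residues, fixed ordering used by the scoring profile
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Structured conditions: every user-facing failure carries a machine-readable
# class under "sdrmine_error" so pipeline stages and tests can dispatch on it.
stop_sdr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sdrmine_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) stop_sdr(class, msg, ...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param dna Character scalar over A/C/G/T/N.
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(dna) {
  as.character(reverseComplement(DNAString(dna)))
}

# run expr with a private RNG stream; global .Random.seed is restored on exit
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write named sequences as wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param type "DNA" or "AA".
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA"), width = 60) {
  type <- match.arg(type)
  x <- if (type == "DNA") DNAStringSet(seqs) else AAStringSet(seqs)
  writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @param type "DNA" or "AA".
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") readDNAStringSet(path) else readAAStringSet(path)
  setNames(as.character(x), names(x))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
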