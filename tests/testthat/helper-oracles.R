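# Independent oracles used to cross-check the package's sequence machinery.
# Everything here is deliberately written from first principles (no Biostrings,
# no calls into the code paths under test).

AA20_ORACLE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# --- independent codon table (bacterial code; translation identical to the
# --- standard table) written as the classic 64-character string in T/C/A/G order
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # outer() above runs third base fastest in the wrong slot; rebuild explicitly
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  from <- 3 * (seq_len(n) - 1) + 1
  cod <- substring(dna, from, from + 2)
  aa <- unname(oracle_codon_table[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(dna, "")[[1]]])), collapse = "")
}

# --- affine-gap global aligner (Gotoh three-state DP), gap cost = open + ext*L.
# Returns the optimal score; with traceback = TRUE also the set of percent
# identities (full alignment length denominator) over all optimal alignments.
oracle_global <- function(a, b, sub, go, ge, traceback = FALSE, max_paths = 500) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- sub[A[i], B[j]] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge, Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge, X[i + 1, j] - go - ge)
    }
  }
  sc <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  if (!traceback) return(list(score = sc))
  # enumerate all optimal paths, collecting (matches, alignment length)
  idents <- numeric(0)
  paths <- 0
  walk <- function(i, j, state, matches, len) {
    if (paths >= max_paths) return()
    if (i == 0 && j == 0 && state == "M") {
      idents <<- c(idents, 100 * matches / len)
      paths <<- paths + 1
      return()
    }
    eps <- 1e-9
    if (state == "M") {
      if (i > 0 && j > 0) {
        tgt <- M[i + 1, j + 1] - sub[A[i], B[j]]
        add <- (A[i] == B[j])
        if (abs(M[i, j] - tgt) < eps) walk(i - 1, j - 1, "M", matches + add, len + 1)
        if (abs(X[i, j] - tgt) < eps) walk(i - 1, j - 1, "X", matches + add, len + 1)
        if (abs(Y[i, j] - tgt) < eps) walk(i - 1, j - 1, "Y", matches + add, len + 1)
      }
    } else if (state == "X") {  # gap in b (consumes a)
      if (i > 0) {
        v <- X[i + 1, j + 1]
        if (j == 0 && abs(v + go + ge * i) < eps && i >= 1) {
          # leading run of gaps straight to the origin
          idents <<- c(idents, 100 * matches / (len + i))
          paths <<- paths + 1
          return()
        }
        if (abs(M[i, j + 1] - go - ge - v) < eps) walk(i - 1, j, "M", matches, len + 1)
        if (abs(X[i, j + 1] - ge - v) < eps) walk(i - 1, j, "X", matches, len + 1)
        if (abs(Y[i, j + 1] - go - ge - v) < eps) walk(i - 1, j, "Y", matches, len + 1)
      }
    } else {
      if (j > 0) {
        v <- Y[i + 1, j + 1]
        if (i == 0 && abs(v + go + ge * j) < eps && j >= 1) {
          idents <<- c(idents, 100 * matches / (len + j))
          paths <<- paths + 1
          return()
        }
        if (abs(M[i + 1, j] - go - ge - v) < eps) walk(i, j - 1, "M", matches, len + 1)
        if (abs(Y[i + 1, j] - ge - v) < eps) walk(i, j - 1, "Y", matches, len + 1)
        if (abs(X[i + 1, j] - go - ge - v) < eps) walk(i, j - 1, "X", matches, len + 1)
      }
    }
  }
  eps <- 1e-9
  if (abs(M[n + 1, m + 1] - sc) < eps) walk(n, m, "M", 0, 0)
  if (abs(X[n + 1, m + 1] - sc) < eps) walk(n, m, "X", 0, 0)
  if (abs(Y[n + 1, m + 1] - sc) < eps) walk(n, m, "Y", 0, 0)
  list(score = sc, identities = unique(round(idents, 6)))
}

# --- pure enumeration of every global alignment (tiny inputs only): the
# --- exhaustive anchor that validates oracle_global itself
oracle_global_enum <- function(a, b, sub, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return()
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, score + sub[A[i], B[j]], "M")
    }
    if (i <= length(A)) {
      rec(i + 1, j, score - ge - if (last == "X") 0 else go, "X")
    }
    if (j <= length(B)) {
      rec(i, j + 1, score - ge - if (last == "Y") 0 else go, "Y")
    }
  }
  rec(1, 1, 0, "M")
  best
}

# --- brute-force local alignment: best global score over all substring pairs
# --- (an alignment with terminal gaps is never optimal, so the max equals the
# --- Smith-Waterman optimum, floored at 0 for the empty alignment)
oracle_local <- function(a, b, sub, go, ge) {
  A <- nchar(a); B <- nchar(b)
  best <- 0
  for (i1 in seq_len(A)) for (i2 in i1:A) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(B)) for (j2 in j1:B) {
      sc <- oracle_global(sa, substr(b, j1, j2), sub, go, ge)$score
      if (sc > best) best <- sc
    }
  }
  best
}

# --- brute-force six-frame ORF enumerator: tests every in-frame (ATG, stop)
# --- codon pair, keeps pairs with no intervening stop, then the first ATG per
# --- stop; reports forward-strand half-open coordinates including the stop
oracle_orfs <- function(contig, min_len_aa) {
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else oracle_revcomp(contig)
    for (frame in 0:2) {
      ncod <- (nchar(s) - frame) %/% 3
      if (ncod < 2) next
      from <- frame + 1 + 3 * (seq_len(ncod) - 1)
      cod <- substring(s, from, from + 2)
      aa <- strsplit(oracle_translate(substr(s, frame + 1, frame + 3 * ncod)), "")[[1]]
      stops <- which(aa == "*")
      starts <- which(cod == "ATG")
      for (t in stops) {
        cand <- starts[starts < t]
        # no intervening stop between candidate start and this stop
        cand <- cand[vapply(cand, function(a0) !any(stops > a0 & stops < t), logical(1))]
        if (length(cand) == 0) next
        a0 <- min(cand)
        if (t - a0 < min_len_aa) next
        s_start <- frame + (a0 - 1) * 3
        s_end <- frame + t * 3
        if (strand == "+") { fs <- s_start; fe <- s_end } else { fs <- L - s_end; fe <- L - s_start }
        out[[length(out) + 1]] <- data.frame(
          start = fs, end = fe, strand = strand, frame = frame,
          protein = paste(aa[a0:(t - 1)], collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

random_protein <- function(len) paste(sample(AA20_ORACLE, len, replace = TRUE), collapse = "")

# BLOSUM62 with zeroed X, as the implementation documents
oracle_submatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- get("BLOSUM62", envir = e)
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}
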