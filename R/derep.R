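#' Dereplication: identity matrix and greedy clustering
#'
#' Family hits are collapsed into a non-redundant panel: all pairwise global
#' identities are computed once (full-alignment-length denominator, gap
#' columns included), then sequences are clustered greedily in
#' longest-sequence-first order (ties broken lexicographically by id), each
#' joining the first existing cluster whose representative it matches at or
#' above the threshold, CD-HIT style. The default threshold is 99%: the
#' original panel retained a 98%-identical pair as distinct entries, so the
#' implied dereplication level exceeds 98%.
#'
#' @name dereplication
NULL

#' Pairwise global-identity matrix
#'
#' @param proteins Named character vector (>= 2, unique ids).
#' @param ... Passed to [global_identity()] (matrix, gap penalties,
#'   denominator).
#' @return Symmetric numeric matrix (percent), diagonal 100, dimnames = input
#'   ids in input order.
#' @export
identity_matrix <- function(proteins, ...) {
  n <- length(proteins)
  assert_that(n >= 2, "invalid_argument", "need at least 2 sequences")
  ids <- names(proteins) %||% as.character(seq_len(n))
  assert_that(!anyDuplicated(ids), "invalid_argument", "duplicate sequence ids")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- global_identity(proteins[[i]], proteins[[j]], ...)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Greedy dereplication clustering
#'
#' @param matrix Identity matrix from [identity_matrix()].
#' @param threshold Percent identity threshold in (0, 100\] (default 99).
#' @param seq_lengths Optional named numeric vector of sequence lengths used
#'   for longest-first processing; without it, ids are processed in
#'   lexicographic order.
#' @return List of clusters, each a list with `members`, `representative`
#'   (the founding, i.e. longest, member) and `threshold_used`. Clusters
#'   partition the input ids.
#' @export
cluster_greedy <- function(matrix, threshold = 99, seq_lengths = NULL) {
  assert_that(threshold > 0 && threshold <= 100, "invalid_argument",
              "threshold must be in (0, 100]")
  ids <- rownames(matrix)
  if (!is.null(seq_lengths)) {
    ord <- ids[order(-seq_lengths[ids], ids)]
  } else {
    ord <- sort(ids)
  }
  clusters <- list()
  for (id in ord) {
    joined <- FALSE
    for (k in seq_along(clusters)) {
      if (matrix[id, clusters[[k]]$representative] >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1]] <-
        list(members = id, representative = id, threshold_used = threshold)
    }
  }
  clusters
}

#' Pick a cluster representative
#'
#' @param cluster One cluster from [cluster_greedy()].
#' @param policy `"longest"` (default; ties broken by lexicographic id) or
#'   `"first"`.
#' @param seq_lengths Named numeric vector of sequence lengths (required for
#'   `policy = "longest"`).
#' @return The representative id.
#' @export
pick_representative <- function(cluster, policy = c("longest", "first"),
                                seq_lengths = NULL) {
  policy <- match.arg(policy)
  m <- cluster$members
  assert_that(length(m) >= 1, "invalid_argument", "cluster must be non-empty")
  if (policy == "first" || is.null(seq_lengths)) return(m[1])
  m[order(-seq_lengths[m], m)][1]
}

#' Write an identity matrix as square TSV (1 decimal place)
#' @param matrix Identity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix),
                   format(round(matrix, 1), nsmall = 1, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(matrix))
  write_tsv(df, path)
}

#' Write clusters as long TSV (cluster_id, representative, member)
#' @param clusters Cluster list from [cluster_greedy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(k) {
    data.frame(cluster_id = sprintf("cluster_%03d", k),
               representative = clusters[[k]]$representative,
               member = clusters[[k]]$members, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
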