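#' Comparative view: distances, neighbor joining, clades, heat-map order
#'
#' The dereplicated panel is compared the way the study's figure presents it:
#' the identity matrix is converted to a distance (1 - fractional identity; a
#' similarity display, not an evolutionary-rate estimate), a neighbor-joining
#' tree is built, clades are assigned by cutting the longest internal
#' branches, and a deterministic leaf ordering is exported for heat-map
#' rendering. Trees are `ape` "phylo" objects throughout.
#'
#' @name comparative
NULL

#' Distance matrix from an identity matrix
#'
#' `d(i,j) = 1 - identity(i,j)/100`.
#'
#' @param m Identity matrix (percent).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_from_identity <- function(m) {
  d <- 1 - m / 100
  diag(d) <- 0
  d
}

# quote leaf labels that contain Newick-reserved characters
nwk_label <- function(x) {
  ifelse(grepl("[][ ():;,']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: the pair minimizing the Q criterion is joined at
#' each step (ties broken by the lexicographically smallest index pair) and
#' branch lengths come from the standard two-point formulas. A negative
#' branch length is clamped to 0 and its deficit moved to the sister branch,
#' so path lengths through the join are preserved; additive matrices are
#' reproduced exactly. The result is the standard unrooted NJ topology with a
#' trifurcating root.
#'
#' @param d Symmetric distance matrix with zero diagonal, n >= 3, with
#'   dimnames.
#' @return An [ape::read.tree()] "phylo" object.
#' @export
neighbor_joining <- function(d) {
  n <- nrow(d)
  assert_that(!is.null(n) && n >= 3, "invalid_argument", "need at least 3 taxa")
  assert_that(isTRUE(all.equal(d, t(d))) && all(abs(diag(d)) < 1e-12),
              "invalid_argument", "distance matrix must be symmetric with zero diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active node carries its Newick subtree string; leaves get placeholder
  # labels so arbitrary ids survive the Newick round trip unmangled
  sub <- paste0("L", seq_len(n))
  D <- d
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- max(0, lj + li); li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # lexicographically smallest (i, j), i < j, among ties
    best <- NULL
    for (i in 1:(m - 1)) {
      j <- which(Q[i, (i + 1):m] <= qmin + 1e-12)
      if (length(j) > 0) { best <- c(i, i + j[1]); break }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)
    newsub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], ll[1], sub[j], ll[2])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    D <- D2
  }
  # final trifurcation: closed-form three-point lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(0, l1); l2 <- max(0, l2); l3 <- max(0, l3)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], l1, sub[2], l2, sub[3], l3)
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labels[as.integer(sub("^L", "", tr$tip.label))]
  tr
}

#' Serialize a tree to Newick text
#'
#' @param t A "phylo" tree.
#' @param precision Decimal places for branch lengths (default 5).
#' @return Newick string terminated by `;`. Labels containing spaces or other
#'   Newick-reserved characters are single-quoted.
#' @export
to_newick <- function(t, precision = 5) {
  assert_that(inherits(t, "phylo"), "invalid_argument", "t must be a phylo tree")
  nl <- length(t$tip.label)
  kids <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  fmt <- function(x) {
    s <- formatC(x, format = "f", digits = precision)
    s
  }
  ser <- function(node) {
    if (node <= nl) return(nwk_label(t$tip.label[node]))
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(ei) {
      paste0(ser(t$edge[ei, 2]), ":", fmt(t$edge.length[ei]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(ser(nl + 1L), ";")
}

#' Assign leaves to clades by cutting long branches
#'
#' Branches are cut longest-first (internal branches before terminal ones;
#' ties by edge traversal order) until the leaves fall into `k` connected
#' groups.
#'
#' @param t A "phylo" tree.
#' @param k Number of clades (1 <= k <= number of leaves; default 3, the
#'   number of coloured clades in the study's comparative figure).
#' @return Named character vector mapping leaf label to clade label
#'   (`"clade_1"`, ... in leaf-order of first appearance).
#' @export
assign_clades <- function(t, k = 3) {
  assert_that(inherits(t, "phylo"), "invalid_argument", "t must be a phylo tree")
  nl <- length(t$tip.label)
  assert_that(k >= 1, "invalid_argument", "k must be >= 1")
  assert_that(k <= nl, "invalid_argument", "k (%d) exceeds number of leaves (%d)", k, nl)
  ne <- nrow(t$edge)
  internal <- t$edge[, 2] > nl
  # cut order: internal edges longest-first, then terminal edges longest-first
  ord <- order(!internal, -t$edge.length, seq_len(ne))
  nnode <- nl + t$Nnode
  uf <- seq_len(nnode)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  comp_count <- function(cut) {
    uf <<- seq_len(nnode)
    for (e in seq_len(ne)) {
      if (!cut[e]) {
        a <- find(t$edge[e, 1]); b <- find(t$edge[e, 2])
        if (a != b) uf[a] <<- b
      }
    }
    length(unique(vapply(seq_len(nl), find, integer(1))))
  }
  cut <- rep(FALSE, ne)
  for (e in ord) {
    if (comp_count(cut) >= k) break
    cut[e] <- TRUE
  }
  comp_count(cut)  # refresh union-find with final cut set
  comp <- vapply(seq_len(nl), find, integer(1))
  lab <- setNames(paste0("clade_", match(comp, unique(comp))), t$tip.label)
  lab
}

#' Deterministic leaf ordering for heat-map rendering
#'
#' Depth-first traversal from the root with children ordered by subtree leaf
#' count (ties by lexicographically smallest leaf label).
#'
#' @param t A "phylo" tree.
#' @return Character vector: a permutation of the leaf labels.
#' @export
heatmap_order <- function(t) {
  assert_that(inherits(t, "phylo"), "invalid_argument", "t must be a phylo tree")
  nl <- length(t$tip.label)
  kids <- split(t$edge[, 2], t$edge[, 1])
  info <- function(node) {
    if (node <= nl) {
      return(list(leaves = t$tip.label[node], size = 1L, minlab = t$tip.label[node]))
    }
    ch <- lapply(kids[[as.character(node)]], info)
    sizes <- vapply(ch, `[[`, integer(1), "size")
    mins <- vapply(ch, `[[`, character(1), "minlab")
    ord <- order(sizes, mins)
    list(leaves = unlist(lapply(ch[ord], `[[`, "leaves")),
         size = sum(sizes), minlab = min(mins))
  }
  info(nl + 1L)$leaves
}
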