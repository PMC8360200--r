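random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, d = D[ord, ord])
}

test_that("identity-to-distance conversion is the documented map", {
  m <- matrix(c(100, 11, 11, 100), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- distance_from_identity(m)
  expect_equal(d["a", "b"], 0.89)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_identical(d, t(d))
})

test_that("three-taxon branch lengths follow the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), class = "invalid_argument")
})

test_that("NJ reproduces additive matrices exactly (topology and path lengths)", {
  set.seed(7)
  for (i in 1:10) {
    inst <- random_additive_matrix(sample(5:10, 1))
    tr <- neighbor_joining(inst$d)
    paths <- ape::cophenetic.phylo(tr)[rownames(inst$d), colnames(inst$d)]
    expect_lt(max(abs(paths - inst$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(inst$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ topology agrees with the reference implementation on random matrices", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- stats::runif(n * (n - 1) / 2, 0.2, 1.5)
    d[upper.tri(d)] <- v
    d <- d + t(d)
    mine <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("clear ultrametric pairs come out as sisters", {
  d <- matrix(c(0, 0.1, 0.9, 0.9,
                0.1, 0, 0.9, 0.9,
                0.9, 0.9, 0, 0.1,
                0.9, 0.9, 0.1, 0), 4,
              dimnames = list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2")))
  tr <- neighbor_joining(d)
  cl <- assign_clades(tr, 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])
})

test_that("Newick round-trip preserves topology and branch lengths", {
  set.seed(19)
  for (i in 1:5) {
    inst <- random_additive_matrix(10)
    tr <- neighbor_joining(inst$d)
    back <- ape::read.tree(text = to_newick(tr, precision = 6))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-5)
  }
  two <- ape::read.tree(text = "(A:0.1,B:0.2);")
  expect_equal(to_newick(two), "(A:0.10000,B:0.20000);")
})

test_that("labels with spaces are quoted in Newick output", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("sp one", "sp two", "out"), c("sp one", "sp two", "out")))
  nwk <- to_newick(neighbor_joining(d))
  expect_match(nwk, "'sp one'", fixed = TRUE)
  back <- ape::read.tree(text = nwk)
  expect_setequal(gsub("^'|'$", "", back$tip.label), c("sp one", "sp two", "out"))
})

test_that("clade assignment spans k = 1 to k = n and separates planted families", {
  inst <- random_additive_matrix(8)
  tr <- neighbor_joining(inst$d)
  expect_equal(length(unique(assign_clades(tr, 1))), 1)
  expect_equal(length(unique(assign_clades(tr, 8))), 8)
  expect_error(assign_clades(tr, 0), class = "invalid_argument")
  expect_error(assign_clades(tr, 9), class = "invalid_argument")

  # two well-separated families from different seed templates
  t1 <- fx_templates()[[1]]; t2 <- fx_templates()[[2]]
  prots <- c(
    setNames(vapply(1:3, function(i) as.character(mutate_protein(t1, 85, seed = i)),
                    character(1)), paste0("famA_", 1:3)),
    setNames(vapply(1:3, function(i) as.character(mutate_protein(t2, 85, seed = i)),
                    character(1)), paste0("famB_", 1:3)))
  m <- identity_matrix(prots)
  tr2 <- neighbor_joining(distance_from_identity(m))
  cl <- assign_clades(tr2, 2)
  expect_equal(length(unique(cl[paste0("famA_", 1:3)])), 1)
  expect_equal(length(unique(cl[paste0("famB_", 1:3)])), 1)
  expect_false(cl[["famA_1"]] == cl[["famB_1"]])

  # clade assignment does not depend on the input row order
  perm <- sample(names(prots))
  tr3 <- neighbor_joining(distance_from_identity(m[perm, perm]))
  cl3 <- assign_clades(tr3, 2)
  grouping <- function(x) unname(x[sort(names(x))] == x[[sort(names(x))[1]]])
  expect_equal(grouping(cl3), grouping(cl))

  # heat-map order keeps each family contiguous
  ord <- heatmap_order(tr2)
  expect_setequal(ord, names(prots))
  fam <- substr(ord, 1, 4)
  expect_equal(length(rle(fam)$lengths), 2)
})
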