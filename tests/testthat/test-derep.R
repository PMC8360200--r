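# exhaustive best-partition oracle: all set partitions of ids, keep those where
# every member matches its block's longest member at >= threshold, return the
# minimum block count
best_partition_blocks <- function(m, lens, threshold) {
  ids <- rownames(m)
  n <- length(ids)
  parts <- list(list(1L))
  for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      c(lapply(seq_along(p), function(k) { p[[k]] <- c(p[[k]], i); p }),
        list(c(p, list(i))))
    }), recursive = FALSE)
  }
  valid <- vapply(parts, function(p) {
    all(vapply(p, function(blk) {
      b <- ids[blk]
      rep_ <- b[order(-lens[b], b)][1]
      all(m[b, rep_] >= threshold)
    }, logical(1)))
  }, logical(1))
  min(vapply(parts[valid], length, integer(1)))
}

test_that("identity matrix is symmetric with expected block structure", {
  p <- random_protein(120)
  prots <- c(a = p, b = p, c = shuffle_protein(p, seed = 1))
  m <- identity_matrix(prots)
  expect_identical(m, t(m))
  expect_equal(diag(m), c(a = 100, b = 100, c = 100))
  expect_equal(m["a", "b"], 100)
  expect_lt(m["a", "c"], 50)
  expect_error(identity_matrix(c(a = p, a = p)), class = "invalid_argument")
  expect_error(identity_matrix(c(a = p)), class = "invalid_argument")
})

test_that("a 98%-identity pair stays distinct at the 99% threshold", {
  tpl <- fx_templates()[[1]]
  twin <- as.character(mutate_protein(gene_template("t", tpl$protein, FALSE), 98, seed = 8))
  prots <- c(x = tpl$protein, y = twin)
  m <- identity_matrix(prots)
  expect_gte(m["x", "y"], 96)
  expect_lte(m["x", "y"], 100)
  cl <- cluster_greedy(m, threshold = 99, seq_lengths = nchar(prots))
  expect_length(cl, 2)
})

test_that("greedy clustering merges planted duplicates and matches the partition oracle", {
  tpl <- fx_templates()[[1]]
  base <- tpl$protein
  dup <- as.character(mutate_protein(gene_template("d", base, FALSE), 99.5, seed = 3))
  prots <- c(s1 = base, s2 = dup,
             s3 = as.character(mutate_protein(tpl, 60, seed = 4)),
             s4 = as.character(mutate_protein(tpl, 40, seed = 5)),
             s5 = shuffle_protein(base, seed = 6))
  m <- identity_matrix(prots)
  lens <- nchar(prots)
  cl <- cluster_greedy(m, threshold = 99, seq_lengths = lens)
  expect_length(cl, best_partition_blocks(m, lens, 99))
  merged <- cl[[which(vapply(cl, function(c) "s1" %in% c$members, logical(1)))]]
  expect_setequal(merged$members, c("s1", "s2"))
  # partition property
  expect_setequal(unlist(lapply(cl, `[[`, "members")), names(prots))
  expect_equal(sum(lengths(lapply(cl, `[[`, "members"))), length(prots))
})

test_that("all-distinct sequences give singletons at threshold 100", {
  prots <- setNames(vapply(c(40, 45, 50), random_protein, character(1)),
                    c("a", "b", "c"))
  m <- identity_matrix(prots)
  cl <- cluster_greedy(m, threshold = 100, seq_lengths = nchar(prots))
  expect_length(cl, 3)
  expect_error(cluster_greedy(m, threshold = 0), class = "invalid_argument")
  expect_error(cluster_greedy(m, threshold = 150), class = "invalid_argument")
})

test_that("raising the threshold never decreases the cluster count", {
  set.seed(71)
  tpl <- fx_templates()[[3]]
  prots <- setNames(vapply(seq(40, 95, length.out = 8), function(t) {
    as.character(mutate_protein(tpl, t))
  }, character(1)), paste0("p", 1:8))
  m <- identity_matrix(prots)
  counts <- vapply(c(40, 60, 80, 95, 100), function(th) {
    length(cluster_greedy(m, th, seq_lengths = nchar(prots)))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("representatives follow the longest-then-lexicographic rule", {
  lens <- c(sdrA = 250, sdrB = 250, sdrC = 260)
  cl <- list(members = c("sdrA", "sdrB", "sdrC"), representative = "sdrA",
             threshold_used = 99)
  expect_equal(pick_representative(cl, "longest", lens), "sdrC")
  expect_equal(pick_representative(list(members = "solo"), "longest", c(solo = 10)), "solo")
  cl2 <- list(members = c("sdrB", "sdrA"))
  expect_equal(pick_representative(cl2, "longest", c(sdrA = 250, sdrB = 250)), "sdrA")
})

test_that("no two greedy representatives match at or above the threshold", {
  set.seed(83)
  tpl <- fx_templates()[[1]]
  prots <- setNames(vapply(rep(c(50, 85, 97), each = 3), function(t) {
    as.character(mutate_protein(tpl, t))
  }, character(1)), paste0("q", 1:9))
  m <- identity_matrix(prots)
  for (th in c(80, 90, 99)) {
    cl <- cluster_greedy(m, th, seq_lengths = nchar(prots))
    reps <- vapply(cl, `[[`, character(1), "representative")
    if (length(reps) > 1) {
      sub <- m[reps, reps]
      expect_true(all(sub[upper.tri(sub)] < th))
    }
  }
})
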