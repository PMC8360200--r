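mk_trace <- function(a340, times = seq(0, by = 57, length.out = length(a340)),
                     path = 0.5, sub_mM = 5, cof_mM = 1, enzyme = "e1",
                     substrate = "s1", well = "w1", blank = NA_character_) {
  assay_trace(well, enzyme, substrate, "NADPH", times, a340, path, sub_mM, cof_mM, blank)
}

test_that("Beer-Lambert endpoint arithmetic is exact", {
  flat <- mk_trace(rep(0.9, 10))
  expect_equal(delta_to_nadph(flat), 0)
  dropping <- mk_trace(c(0.511, 0.40, 0.30, 0.20))
  expect_equal(delta_to_nadph(dropping), 0.311 / (6220 * 0.5) * 1000)  # 0.1 mM
  # a drop beyond the cofactor equivalent is clipped with a warning
  huge <- mk_trace(c(3.5, 0.1))
  expect_warning(got <- delta_to_nadph(huge), "clipping")
  expect_equal(got, 1)
})

test_that("conversion is reported against substrate and cofactor", {
  cv <- conversion_percent(1, substrate_mM = 5, cofactor_mM = 1)
  expect_equal(cv$substrate_pct, 20)   # the stoichiometric ceiling without recycling
  expect_equal(cv$cofactor_pct, 100)
  expect_equal(conversion_percent(0.55, 5)$substrate_pct, 11)
  expect_equal(conversion_percent(0, 5)$substrate_pct, 0)
  expect_error(conversion_percent(1, 0), class = "invalid_argument")
})

test_that("substrate-referenced conversion respects the cofactor-limited ceiling", {
  # even an over-range absorbance collapse cannot report more than
  # 100 * cofactor / substrate percent conversion
  collapse <- mk_trace(c(3.3, 0))
  expect_warning(cons <- delta_to_nadph(collapse))
  cv <- conversion_percent(cons, substrate_mM = 5, cofactor_mM = 1)
  expect_lte(cv$substrate_pct, 20)
})

test_that("initial rate recovers exact slopes and is unbiased on noise", {
  times <- seq(0, by = 60, length.out = 20)
  exact <- mk_trace(1 - 0.01 * times / 60, times = times)
  got <- initial_rate(exact, n_points = 10)
  expect_equal(got$dA_per_min, -0.01, tolerance = 1e-12)
  full <- initial_rate(exact, n_points = 20)
  expect_equal(full$dA_per_min, -0.01, tolerance = 1e-12)
  expect_error(initial_rate(exact, n_points = 1), class = "invalid_argument")

  slopes <- vapply(1:100, function(i) {
    set.seed(i)
    tr <- mk_trace(rnorm(20, 1, 0.01), times = times)
    initial_rate(tr, n_points = 20)$dA_per_min
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) * 1.96 * sd(slopes) / sqrt(length(slopes))
  expect_gte(0, ci[1])
  expect_lte(0, ci[2])
})

test_that("screen matrix calls planted actives with perfect recall and precision", {
  active <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), nrow = 2,
                   dimnames = list(c("sdrA", "sdrB"), c("sub1", "sub2", "sub3")))
  plate <- simulate_assay_plate(active, seed = 21)
  out <- screen_matrix(plate$traces)
  expect_equal(nrow(out), 6)
  key_truth <- paste(plate$truth$enzyme, plate$truth$substrate)
  key_out <- paste(out$enzyme, out$substrate)
  called <- out$hit[match(key_truth, key_out)]
  expect_equal(called, plate$truth$active)
  # triplicates aggregated with a populated sd column
  expect_true(all(out$n == 3))
  expect_true(all(is.finite(out$substrate_pct_sd)))
  expect_equal(nrow(screen_matrix(list())), 0)
})

test_that("a constant absorbance offset cancels through blank correction", {
  times <- seq(0, by = 57, length.out = 50)
  decay <- 0.4 * (1 - exp(-0.001 * times))
  base <- mk_trace(1.5 - decay, times = times, blank = "blk")
  blank0 <- mk_trace(rep(1.5, 50), times = times, enzyme = "blank", well = "blk")
  off <- 0.25
  shifted <- mk_trace(1.5 + off - decay, times = times, blank = "blk")
  blank_off <- mk_trace(rep(1.5 + off, 50), times = times, enzyme = "blank", well = "blk")
  a <- delta_to_nadph(base, blank = blank0)
  b <- delta_to_nadph(shifted, blank = blank_off)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("conflicting replicate metadata is rejected", {
  t1 <- mk_trace(c(1, 0.9), well = "w1", sub_mM = 5)
  t2 <- mk_trace(c(1, 0.9), well = "w2", sub_mM = 10)
  expect_error(screen_matrix(list(t1, t2)), class = "invalid_argument")
})

test_that("traces round-trip through the TSV interchange format", {
  active <- matrix(TRUE, 1, 1, dimnames = list("e1", "s1"))
  plate <- simulate_assay_plate(active, replicates = 2, cycles = 10, seed = 3)
  rows <- do.call(rbind, lapply(plate$traces, function(tr) {
    data.frame(well = tr$well_id, enzyme = tr$enzyme_id, substrate = tr$substrate_id,
               cofactor = tr$cofactor, time_s = tr$times, a340 = tr$a340,
               path_cm = tr$path_cm, substrate_mM = tr$substrate_mM,
               cofactor_mM = tr$cofactor_mM)
  }))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_traces_tsv(f)
  expect_length(back, 2)
  expect_equal(back[["W001"]]$a340, plate$traces[[1]]$a340)
})
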