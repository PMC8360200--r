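#' NAD(P)H depletion plate-assay quantification
#'
#' Carbonyl reductase activity is read from 340 nm absorbance traces: NAD(P)H
#' absorbs at 340 nm (epsilon = 6220 per M per cm) and its oxidation during
#' ketone reduction appears as an absorbance drop. Endpoint consumption is
#' converted through Beer-Lambert, referenced both to substrate (1:1
#' stoichiometry) and to cofactor. Without cofactor recycling the
#' substrate-referenced conversion is capped at
#' `100 * cofactor_mM / substrate_mM` (e.g. 20% at 1 mM cofactor / 5 mM
#' substrate); both percentages are always reported side by side because
#' endpoint screens are sometimes quoted on either scale. The optical path
#' length is a required input: vertical paths in plate readers depend on fill
#' volume, so no default is assumed.
#'
#' @name assay_quant
NULL

EPSILON_NADPH <- 6220  # M^-1 cm^-1 at 340 nm, used for both NADH and NADPH

#' Construct a single-well assay trace
#'
#' @param well_id,enzyme_id,substrate_id Identifiers.
#' @param cofactor `"NADH"` or `"NADPH"`.
#' @param times Time points in seconds (strictly increasing).
#' @param a340 Absorbances (same length as `times`).
#' @param path_cm Optical path length in cm (> 0; required, no default).
#' @param substrate_mM,cofactor_mM Concentrations in mM (> 0).
#' @param blank_well Optional id of a no-enzyme reference well.
#' @return An `assay_trace` object.
#' @export
assay_trace <- function(well_id, enzyme_id, substrate_id, cofactor, times, a340,
                        path_cm, substrate_mM, cofactor_mM, blank_well = NA_character_) {
  assert_that(length(times) == length(a340), "invalid_argument",
              "times and a340 must have equal length")
  assert_that(all(diff(times) > 0), "invalid_argument", "times must be strictly increasing")
  assert_that(path_cm > 0, "invalid_argument", "path_cm must be positive")
  assert_that(substrate_mM > 0 && cofactor_mM > 0, "invalid_argument",
              "concentrations must be positive")
  cofactor <- match.arg(cofactor, c("NADH", "NADPH"))
  structure(list(well_id = well_id, enzyme_id = enzyme_id,
                 substrate_id = substrate_id, cofactor = cofactor,
                 times = times, a340 = a340, path_cm = path_cm,
                 substrate_mM = substrate_mM, cofactor_mM = cofactor_mM,
                 blank_well = blank_well),
            class = "assay_trace")
}

#' NAD(P)H consumed over a trace (Beer-Lambert)
#'
#' `consumed = (A_0 - A_end) / (epsilon * path)`, blank-corrected when a
#' blank trace is supplied, clipped into `[0, cofactor_mM]` (with a warning
#' when the raw drop exceeds the cofactor ceiling).
#'
#' @param trace An [assay_trace()].
#' @param blank Optional blank [assay_trace()] whose drop is subtracted.
#' @param epsilon Molar extinction coefficient (default 6220 / M / cm).
#' @param endpoint `"final"` (last cycle, the default endpoint of a
#'   fixed-duration incubation) or `"min"` (minimum absorbance, for noisy
#'   traces).
#' @return Consumed NAD(P)H in mM.
#' @export
delta_to_nadph <- function(trace, blank = NULL, epsilon = EPSILON_NADPH,
                           endpoint = c("final", "min")) {
  endpoint <- match.arg(endpoint)
  assert_that(length(trace$a340) >= 2, "invalid_argument", "need at least 2 time points")
  a_end <- if (endpoint == "final") trace$a340[length(trace$a340)] else min(trace$a340)
  da <- trace$a340[1] - a_end
  if (!is.null(blank)) {
    b_end <- if (endpoint == "final") blank$a340[length(blank$a340)] else min(blank$a340)
    da <- da - (blank$a340[1] - b_end)
  }
  consumed <- da / (epsilon * trace$path_cm) * 1000  # M -> mM
  if (consumed > trace$cofactor_mM) {
    warning(sprintf("absorbance drop exceeds the Beer-Lambert equivalent of %g mM cofactor; clipping",
                    trace$cofactor_mM))
    consumed <- trace$cofactor_mM
  }
  max(0, consumed)
}

#' Substrate- and cofactor-referenced conversion
#'
#' @param consumed_mM NAD(P)H consumed (mM).
#' @param substrate_mM Substrate concentration (mM, > 0).
#' @param cofactor_mM Optional cofactor concentration (mM) for the
#'   cofactor-referenced percentage.
#' @return List with `substrate_pct` (100 x consumed / substrate, 1:1
#'   stoichiometry) and `cofactor_pct` (`NA` when `cofactor_mM` missing).
#' @export
conversion_percent <- function(consumed_mM, substrate_mM, cofactor_mM = NULL) {
  assert_that(substrate_mM > 0, "invalid_argument", "substrate_mM must be positive")
  list(substrate_pct = 100 * consumed_mM / substrate_mM,
       cofactor_pct = if (is.null(cofactor_mM)) NA_real_ else 100 * consumed_mM / cofactor_mM)
}

#' Initial rate from the first cycles of a trace
#'
#' Least-squares slope over the first `n_points` readings.
#'
#' @param trace An [assay_trace()].
#' @param n_points Number of leading points to fit (2 <= n <= trace length;
#'   default 10).
#' @param well_volume_uL Reaction volume for the molar rate (default 200).
#' @param epsilon Molar extinction coefficient.
#' @return List with `dA_per_min` (signed slope) and `nadph_umol_per_min`
#'   (rate of NAD(P)H oxidation; positive for a falling trace).
#' @export
initial_rate <- function(trace, n_points = 10, well_volume_uL = 200,
                         epsilon = EPSILON_NADPH) {
  n <- length(trace$times)
  assert_that(n_points >= 2 && n_points <= n, "invalid_argument",
              "n_points must be in [2, trace length]")
  i <- seq_len(n_points)
  slope_s <- unname(coef(lm(trace$a340[i] ~ trace$times[i]))[2])
  da_min <- slope_s * 60
  rate_M_min <- -da_min / (epsilon * trace$path_cm)
  list(dA_per_min = da_min,
       nadph_umol_per_min = rate_M_min * well_volume_uL * 1e-6 * 1e6)
}

#' Screen table: enzyme x substrate x cofactor conversions and hit calls
#'
#' Replicate wells (same enzyme, substrate and cofactor) are aggregated as
#' mean and SD; a hit is a mean substrate-referenced conversion at or above
#' the threshold. Conflicting metadata within a replicate group is an error.
#'
#' @param traces List of [assay_trace()] objects. Traces whose `enzyme_id`
#'   is `"blank"` are used as blanks for wells that name them via
#'   `blank_well`.
#' @param hit_threshold Percent substrate-referenced conversion calling a hit
#'   (default 10).
#' @param epsilon,endpoint Passed to [delta_to_nadph()].
#' @return data.frame: `enzyme`, `substrate`, `cofactor`, `n`,
#'   `consumed_mM_mean`, `substrate_pct_mean`, `substrate_pct_sd`,
#'   `cofactor_pct_mean`, `hit`.
#' @export
screen_matrix <- function(traces, hit_threshold = 10, epsilon = EPSILON_NADPH,
                          endpoint = "final") {
  if (length(traces) == 0) {
    return(data.frame(enzyme = character(), substrate = character(),
                      cofactor = character(), n = integer(),
                      consumed_mM_mean = numeric(), substrate_pct_mean = numeric(),
                      substrate_pct_sd = numeric(), cofactor_pct_mean = numeric(),
                      hit = logical(), stringsAsFactors = FALSE))
  }
  by_well <- setNames(traces, vapply(traces, `[[`, character(1), "well_id"))
  per <- lapply(traces, function(tr) {
    blank <- if (!is.na(tr$blank_well) && tr$blank_well %in% names(by_well)) {
      by_well[[tr$blank_well]]
    } else NULL
    cons <- delta_to_nadph(tr, blank = blank, epsilon = epsilon, endpoint = endpoint)
    cv <- conversion_percent(cons, tr$substrate_mM, tr$cofactor_mM)
    data.frame(enzyme = tr$enzyme_id, substrate = tr$substrate_id,
               cofactor = tr$cofactor, substrate_mM = tr$substrate_mM,
               cofactor_mM = tr$cofactor_mM, consumed = cons,
               substrate_pct = cv$substrate_pct, cofactor_pct = cv$cofactor_pct,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per)
  df <- df[df$enzyme != "blank", , drop = FALSE]
  key <- interaction(df$enzyme, df$substrate, df$cofactor, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    assert_that(length(unique(g$substrate_mM)) == 1 && length(unique(g$cofactor_mM)) == 1,
                "invalid_argument",
                "conflicting concentrations within replicate group %s/%s/%s",
                g$enzyme[1], g$substrate[1], g$cofactor[1])
    data.frame(enzyme = g$enzyme[1], substrate = g$substrate[1],
               cofactor = g$cofactor[1], n = nrow(g),
               consumed_mM_mean = mean(g$consumed),
               substrate_pct_mean = mean(g$substrate_pct),
               substrate_pct_sd = if (nrow(g) > 1) sd(g$substrate_pct) else NA_real_,
               cofactor_pct_mean = mean(g$cofactor_pct),
               hit = mean(g$substrate_pct) >= hit_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$enzyme, out$substrate, out$cofactor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a screening plate
#'
#' Active wells follow an exponential NAD(P)H decay towards a planted
#' consumed amount; inactive wells are flat. Gaussian reader noise is added
#' to every cycle. Defaults mirror a 100-cycle, 57-second kinetic read of
#' 200 uL wells with 1 mM cofactor and 5 mM substrate.
#'
#' @param active Logical matrix (enzymes x substrates): which combinations
#'   are truly active.
#' @param cofactor `"NADH"` or `"NADPH"`.
#' @param consumed_mM NAD(P)H consumed by an active well at the endpoint
#'   (default 0.8).
#' @param cycles,cycle_s Number of cycles and cycle time (default 100 x 57 s).
#' @param path_cm Optical path (default 0.5 cm).
#' @param cofactor_mM,substrate_mM Concentrations (default 1 and 5 mM).
#' @param noise_sd Absorbance noise SD per cycle (default 0.005).
#' @param replicates Wells per enzyme x substrate combination (default 3).
#' @param seed Integer seed.
#' @return List with `traces` (list of [assay_trace()], replicates included)
#'   and `truth` (data.frame enzyme/substrate/active).
#' @export
simulate_assay_plate <- function(active, cofactor = "NADPH", consumed_mM = 0.8,
                                 cycles = 100, cycle_s = 57, path_cm = 0.5,
                                 cofactor_mM = 1, substrate_mM = 5,
                                 noise_sd = 0.005, replicates = 3, seed = 1) {
  with_seed(seed, {
    times <- seq(0, by = cycle_s, length.out = cycles)
    a0 <- EPSILON_NADPH * cofactor_mM / 1000 * path_cm
    traces <- list()
    truth <- list()
    wi <- 0
    for (e in rownames(active)) {
      for (s in colnames(active)) {
        for (r in seq_len(replicates)) {
          wi <- wi + 1
          if (active[e, s]) {
            k <- runif(1, 5e-4, 2e-3)
            drop <- consumed_mM / 1000 * EPSILON_NADPH * path_cm
            a <- a0 - drop * (1 - exp(-k * times)) / (1 - exp(-k * max(times)))
          } else {
            a <- rep(a0, cycles)
          }
          a <- a + rnorm(cycles, 0, noise_sd)
          traces[[wi]] <- assay_trace(sprintf("W%03d", wi), e, s, cofactor,
                                      times, a, path_cm, substrate_mM, cofactor_mM)
        }
        truth[[length(truth) + 1]] <- data.frame(enzyme = e, substrate = s,
                                                 active = active[e, s],
                                                 stringsAsFactors = FALSE)
      }
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Read assay traces from long-format TSV
#'
#' Expected columns: `well`, `enzyme`, `substrate`, `cofactor`, `time_s`,
#' `a340`, `path_cm`, `substrate_mM`, `cofactor_mM` and optionally
#' `blank_well`.
#'
#' @param path TSV file.
#' @return List of [assay_trace()] objects.
#' @export
read_traces_tsv <- function(path) {
  df <- read_tsv(path)
  lapply(split(df, df$well), function(g) {
    g <- g[order(g$time_s), ]
    assay_trace(g$well[1], g$enzyme[1], g$substrate[1], g$cofactor[1],
                g$time_s, g$a340, g$path_cm[1], g$substrate_mM[1],
                g$cofactor_mM[1],
                if ("blank_well" %in% names(g)) g$blank_well[1] else NA_character_)
  })
}
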