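#' Pipeline orchestration
#'
#' One configuration drives the full mine -> search -> dereplicate ->
#' compare -> QC -> primer-design flow, writing stage artifacts in order and
#' a machine-readable JSON run report. Every stage is also callable on its
#' own (via the exported stage functions), because re-screening with new
#' thresholds must not require re-mining.
#'
#' @name pipeline_run
NULL

#' Default pipeline configuration
#'
#' @param contigs Path to the contig FASTA (DNA).
#' @param seeds Path to the seed protein FASTA.
#' @param out_dir Output directory (created if absent).
#' @param seed_msa Optional aligned seed FASTA for the profile route; when
#'   `NULL` and the seeds are equal-length, the seeds themselves are used as
#'   an (ungapped) alignment, otherwise the profile route is skipped.
#' @return Named list of configuration values with documented defaults:
#'   `min_len_aa` (230), `max_len_aa` (NULL), `norm_threshold` (0.18),
#'   `profile_frac` (0.3), `derep_threshold` (99), `clades_k` (3),
#'   `adapter_len` (20), `tm_target` (60), `rng_seed` (1).
#' @export
default_config <- function(contigs, seeds, out_dir, seed_msa = NULL) {
  list(contigs = contigs, seeds = seeds, out_dir = out_dir, seed_msa = seed_msa,
       min_len_aa = 230, max_len_aa = NULL, norm_threshold = 0.18,
       profile_frac = 0.3, derep_threshold = 99, clades_k = 3,
       adapter_len = 20, tm_target = 60, rng_seed = 1)
}

KNOWN_KEYS <- c("contigs", "seeds", "out_dir", "seed_msa", "min_len_aa",
                "max_len_aa", "norm_threshold", "profile_frac",
                "derep_threshold", "clades_k", "adapter_len", "tm_target",
                "rng_seed")

#' Validate a pipeline configuration
#'
#' All problems are collected and reported together, not first-failure.
#' Unknown keys produce a warning (forward compatibility), never an error.
#'
#' @param config A config list, or the path of a YAML file holding one.
#' @return The validated config (defaults filled in). On any validation
#'   failure an error of class `config_error` is thrown whose message lists
#'   every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), "io_error", "config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  unknown <- setdiff(names(config), KNOWN_KEYS)
  if (length(unknown) > 0) {
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
    config <- config[intersect(names(config), KNOWN_KEYS)]
  }
  for (req in c("contigs", "seeds", "out_dir")) {
    if (is.null(config[[req]])) errs <- c(errs, sprintf("missing required key '%s'", req))
  }
  full <- default_config(config$contigs %||% "", config$seeds %||% "",
                         config$out_dir %||% "", config$seed_msa)
  for (k in names(config)) full[[k]] <- config[[k]]
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(full$min_len_aa >= 1, "min_len_aa must be >= 1")
  if (!is.null(full$max_len_aa)) chk(full$max_len_aa >= full$min_len_aa,
                                     "max_len_aa must be >= min_len_aa")
  chk(full$norm_threshold >= 0 && full$norm_threshold <= 1,
      "norm_threshold must be in [0, 1]")
  chk(full$profile_frac >= 0 && full$profile_frac <= 1,
      "profile_frac must be in [0, 1]")
  chk(full$derep_threshold > 0 && full$derep_threshold <= 100,
      "derep_threshold must be in (0, 100]")
  chk(full$clades_k >= 1, "clades_k must be >= 1")
  chk(full$adapter_len >= 10, "adapter_len must be >= 10")
  if (length(errs) > 0) {
    stop_sdr("config_error", "invalid configuration:\n- %s", paste(errs, collapse = "\n- "))
  }
  full
}

stage <- function(name, report, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop_sdr("stage_failure", "stage '%s' failed: %s", name, conditionMessage(e))
  })
  report$stages[[name]] <- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
  res
}

#' Run the full mining pipeline
#'
#' Stage artifacts written under `out_dir`, in order: `orfs.faa` / `orfs.tsv`,
#' `hits.tsv`, `identity_matrix.tsv`, `clusters.tsv`, `representatives.faa`,
#' `tree.nwk`, `clades.tsv`, `matrix_ordered.tsv`, `motif_qc.tsv`,
#' `primers.tsv`, `report.json`. The report records counts at every stage,
#' the thresholds used, the RNG seed and per-stage wall time. Reruns with
#' identical config and inputs are byte-identical except the report's
#' timestamps and timings.
#'
#' @param config Config list or YAML path (validated with
#'   [validate_config()]).
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- new.env()
  report$stages <- list()
  counts <- list()

  contigs <- stage("load", report, {
    assert_that(file.exists(cfg$contigs), "io_error", "contig file '%s' not found", cfg$contigs)
    x <- read_fasta(cfg$contigs, "DNA")
    assert_that(length(x) > 0, "invalid_argument", "contig file is empty")
    x
  })
  seeds <- read_fasta(cfg$seeds, "AA")

  orfs <- stage("mine", report, {
    o <- find_orfs_all(contigs, min_len_aa = cfg$min_len_aa)
    o <- filter_orfs(o, cfg$min_len_aa, cfg$max_len_aa)
    write_orfs(o, file.path(cfg$out_dir, "orfs.faa"), file.path(cfg$out_dir, "orfs.tsv"))
    o
  })
  counts$orfs <- nrow(orfs)

  hits <- stage("search", report, {
    msa <- if (!is.null(cfg$seed_msa)) read_fasta(cfg$seed_msa, "AA")
           else if (length(unique(nchar(seeds))) == 1) seeds else NULL
    prof <- if (!is.null(msa)) build_profile(msa) else NULL
    h <- score_orfs(orfs, seeds, prof, cfg$norm_threshold, cfg$profile_frac)
    write_tsv(h, file.path(cfg$out_dir, "hits.tsv"))
    h
  })
  counts$passed_hits <- sum(hits$passed)

  passed <- orfs[orfs$orf_id %in% hits$orf_id[hits$passed], , drop = FALSE]
  reps <- stage("derep", report, {
    prots <- setNames(passed$protein, passed$orf_id)
    if (length(prots) >= 2) {
      m <- identity_matrix(prots)
      cl <- cluster_greedy(m, cfg$derep_threshold, seq_lengths = nchar(prots))
      write_identity_matrix(m, file.path(cfg$out_dir, "identity_matrix.tsv"))
      write_clusters(cl, file.path(cfg$out_dir, "clusters.tsv"))
      rep_ids <- vapply(cl, `[[`, character(1), "representative")
    } else {
      m <- NULL
      rep_ids <- names(prots)
    }
    write_fasta(prots[rep_ids], file.path(cfg$out_dir, "representatives.faa"), "AA")
    list(ids = rep_ids, proteins = prots[rep_ids], matrix = m)
  })
  counts$representatives <- length(reps$ids)

  clades <- stage("compare", report, {
    if (length(reps$ids) >= 3) {
      m <- reps$matrix[reps$ids, reps$ids]
      tr <- neighbor_joining(distance_from_identity(m))
      writeLines(to_newick(tr), file.path(cfg$out_dir, "tree.nwk"))
      k <- min(cfg$clades_k, length(reps$ids))
      cl <- assign_clades(tr, k)
      write_tsv(data.frame(id = names(cl), clade = unname(cl)),
                file.path(cfg$out_dir, "clades.tsv"))
      ord <- heatmap_order(tr)
      write_identity_matrix(m[ord, ord], file.path(cfg$out_dir, "matrix_ordered.tsv"))
      cl
    } else {
      setNames(rep("clade_1", length(reps$ids)), reps$ids)
    }
  })
  counts$clades <- length(unique(clades))

  qc <- stage("qc", report, {
    q <- qc_table(reps$proteins)
    write_tsv(q, file.path(cfg$out_dir, "motif_qc.tsv"))
    q
  })
  counts$motif_pass <- sum(qc$family_pass)

  stage("primers", report, {
    vec <- mock_vector()
    genes <- setNames(
      vapply(reps$proteins, function(p) {
        paste0("ATG", reverse_translate(substr(p, 2, nchar(p))), "TAA")
      }, character(1)),
      reps$ids)
    pt <- primer_table(genes, vec, adapter_len = cfg$adapter_len, tm_target = cfg$tm_target)
    write_tsv(pt, file.path(cfg$out_dir, "primers.tsv"))
    pt
  })

  rep_out <- list(counts = counts,
                  thresholds = cfg[c("min_len_aa", "norm_threshold", "profile_frac",
                                     "derep_threshold", "clades_k")],
                  rng_seed = cfg$rng_seed,
                  stage_seconds = lapply(report$stages, `[[`, "seconds"),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rep_out, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(rep_out)
}
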