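# End-to-end orchestration: simulate (optional) -> segment -> call ->
# integrate -> candidates -> report, with stage caching and full
# provenance (the resolved configuration is written next to the outputs).

#' Build a pipeline configuration
#'
#' Either point the path arguments at existing TSV inputs, or supply
#' `sim` (a [sim_config()]) to generate a synthetic study in
#' `<out_dir>/inputs/` first.
#'
#' @param out_dir Output directory (created if needed).
#' @param acgh,map,expr,expr_map,clinical,de,normals Input TSV paths
#'   (ignored when `sim` is given).
#' @param sim Optional [sim_config()] for a self-contained synthetic run.
#' @param alpha,n_perm_cbs,merge_tol,k,z Segmentation parameters.
#' @param thresholds A [cna_thresholds()]; when `normals` is available
#'   the gain/loss cut is derived from it instead.
#' @param n_perm_cor,window_bp,min_n,r_cut,q_cut Integration parameters.
#' @param bin_bp Bin size for the diagonal analysis.
#' @param min_imbalance Candidate filter imbalance cut.
#' @param stratify_by Clinical features for stratified frequencies.
#' @param seed Master seed for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            acgh = NULL, map = NULL, expr = NULL,
                            expr_map = NULL, clinical = NULL, de = NULL,
                            normals = NULL, sim = NULL,
                            alpha = 0.01, n_perm_cbs = 1000,
                            merge_tol = 0.05, k = 2, z = 4,
                            thresholds = cna_thresholds(),
                            n_perm_cor = 1000, window_bp = 1e6, min_n = 10,
                            r_cut = 0.29, q_cut = 0.01,
                            bin_bp = 2e7, min_imbalance = 5,
                            stratify_by = "stage", seed = 7) {
  if (is.null(sim) && (is.null(acgh) || is.null(map))) {
    abort("either `sim` or the `acgh` and `map` paths must be given")
  }
  structure(
    list(out_dir = out_dir, acgh = acgh, map = map, expr = expr,
         expr_map = expr_map, clinical = clinical, de = de,
         normals = normals, sim = sim,
         alpha = alpha, n_perm_cbs = n_perm_cbs, merge_tol = merge_tol,
         k = k, z = z, thresholds = thresholds,
         n_perm_cor = n_perm_cor, window_bp = window_bp, min_n = min_n,
         r_cut = r_cut, q_cut = q_cut, bin_bp = bin_bp,
         min_imbalance = min_imbalance, stratify_by = stratify_by,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_hash <- function(params, paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  digest::digest(list(params, unname(tools::md5sum(unlist(paths)))))
}

stage_cached <- function(out_dir, stage, hash, outputs) {
  hf <- file.path(out_dir, paste0(".", stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

stage_done <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(".", stage, ".hash")))
}

#' Run the full integrative pipeline
#'
#' Executes segmentation, aberration calling, expression integration,
#' candidate-gene nomination and report tables, writing every stage's
#' output as TSV under `config$out_dir`. Stages are cached by a content
#' hash of their parameters and input files, so re-running with an
#' unchanged configuration is cheap, and a re-run with the same seeds
#' reproduces byte-identical TSVs. If the DE list is missing the
#' candidates stage is skipped with a notice; earlier stages still run.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory stage results and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "pipeline_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("pipeline run %s\n", format(Sys.time())), file = logf)

  # ---- stage: simulate (optional) -----------------------------------
  if (!is.null(config$sim)) {
    idir <- file.path(out, "inputs")
    dir.create(idir, showWarnings = FALSE)
    sim_hash <- digest::digest(unclass(config$sim))
    sim_paths <- file.path(idir, c("acgh.tsv", "map.tsv", "expr.tsv",
                                   "expr_map.tsv", "clinical.tsv",
                                   "de.tsv", "normals.tsv", "truth.tsv"))
    if (!stage_cached(out, "simulate", sim_hash, sim_paths)) {
      study <- simulate_study(config$sim)
      write_ratio_matrix(study$acgh$ratios, sim_paths[1])
      write_clone_map(study$map, sim_paths[2])
      write_ratio_matrix(study$expr$ratios, sim_paths[3])
      write_clone_map(study$expr_map, sim_paths[4])
      write_clinical(study$clinical, sim_paths[5])
      write_de_list(study$de_list, sim_paths[6])
      write_ratio_matrix(study$normals, sim_paths[7])
      readr::write_tsv(truth_file(study), sim_paths[8], na = "NA")
      stage_done(out, "simulate", sim_hash)
      logline("simulate: wrote synthetic study (%d samples, %d BACs, %d expression clones)",
              config$sim$n_samples,
              config$sim$n_chromosomes * config$sim$clones_per_chrom,
              config$sim$n_expr_clones)
    } else {
      logline("simulate: cache hit")
    }
    config$acgh <- sim_paths[1]; config$map <- sim_paths[2]
    config$expr <- sim_paths[3]; config$expr_map <- sim_paths[4]
    config$clinical <- sim_paths[5]; config$de <- sim_paths[6]
    config$normals <- sim_paths[7]
  }

  resolved <- config
  resolved$thresholds <- unclass(resolved$thresholds)
  resolved$sim <- if (!is.null(resolved$sim)) unclass(resolved$sim)
  yaml::write_yaml(purrr::map(unclass(resolved), function(v) {
    if (is.data.frame(v)) as.list(v) else v
  }), file.path(out, "config_resolved.yaml"))

  map <- read_clone_map(config$map)
  acgh <- read_ratio_matrix(config$acgh, map)

  # ---- stage: segment ------------------------------------------------
  seg_params <- config[c("alpha", "n_perm_cbs", "merge_tol", "k", "z", "seed")]
  seg_hash <- stage_hash(seg_params, config[c("acgh", "map")])
  seg_paths <- file.path(out, c("segments.tsv", "smoothed.tsv"))
  if (stage_cached(out, "segment", seg_hash, seg_paths)) {
    logline("segment: cache hit")
    segments <- readr::read_tsv(seg_paths[1], show_col_types = FALSE)
    smoothed <- read_ratio_matrix(seg_paths[2], map)
    seg <- NULL
  } else {
    seg <- segment_cna(acgh, map, alpha = config$alpha,
                       n_perm = config$n_perm_cbs, seed = config$seed,
                       merge_tol = config$merge_tol, k = config$k,
                       z = config$z)
    segments <- seg$segments
    smoothed <- seg$smoothed
    readr::write_tsv(segments, seg_paths[1], na = "NA")
    write_ratio_matrix(smoothed, seg_paths[2])
    stage_done(out, "segment", seg_hash)
    logline("segment: %d segments over %d samples", nrow(segments),
            length(unique(segments$sample_id)))
  }

  # ---- stage: call ---------------------------------------------------
  th <- config$thresholds
  if (!is.null(config$normals)) {
    th <- derive_thresholds(read_ratio_matrix(config$normals),
                            sd_multiplier = th$sd_multiplier, base = th)
    logline("call: thresholds derived from normals (gain = %.4f)", th$gain)
  }
  calls <- call_clones(acgh, th)
  arm_calls <- call_arms(acgh, map, th)
  freq <- cna_frequency(calls, map)
  events <- catalogue_events(calls, map)
  readr::write_tsv(tibble::as_tibble(unclass(th)[1:4]),
                   file.path(out, "thresholds.tsv"))
  readr::write_tsv(calls, file.path(out, "calls.tsv"), na = "NA")
  readr::write_tsv(arm_calls, file.path(out, "arm_calls.tsv"), na = "NA")
  readr::write_tsv(freq, file.path(out, "frequency.tsv"), na = "NA")
  readr::write_tsv(events$events, file.path(out, "events.tsv"), na = "NA")
  write_regions_bed(events$recurrent, file.path(out, "recurrent.bed"))
  logline("call: %d events, %d recurrent regions",
          nrow(events$events), nrow(events$recurrent))

  clinical <- NULL
  if (!is.null(config$clinical)) {
    clinical <- read_clinical(config$clinical)
    for (f in intersect(config$stratify_by,
                        setdiff(names(clinical), "sample_id"))) {
      readr::write_tsv(stratified_frequency(arm_calls, clinical, f),
                       file.path(out, paste0("stratified_", f, ".tsv")),
                       na = "NA")
    }
  }

  # ---- stage: integrate ---------------------------------------------
  records <- selected <- binned <- NULL
  if (!is.null(config$expr) && !is.null(config$expr_map)) {
    expr_map <- read_clone_map(config$expr_map)
    expr <- read_ratio_matrix(config$expr, expr_map)
    records <- map_expression_to_bac(expr, expr_map, smoothed, map,
                                     window_bp = config$window_bp,
                                     min_n = config$min_n)
    records <- permutation_pvalues(records, expr, smoothed,
                                   n_perm = config$n_perm_cor,
                                   seed = config$seed, min_n = config$min_n)
    records$q <- bh_adjust(records$p_perm)
    selected <- select_correlated(records, config$r_cut, config$q_cut)
    binned <- binned_diagonal_analysis(expr, expr_map, smoothed, map,
                                       bin_bp = config$bin_bp)
    readr::write_tsv(records, file.path(out, "records.tsv"), na = "NA")
    readr::write_tsv(selected, file.path(out, "selected.tsv"), na = "NA")
    readr::write_tsv(binned$grid, file.path(out, "binned_grid.tsv"), na = "NA")
    readr::write_tsv(glance(binned), file.path(out, "binned_summary.tsv"),
                     na = "NA")
    logline("integrate: %d/%d records selected (r > %g, q < %g), achieved FDR %.4g",
            nrow(selected), sum(!records$unmapped), config$r_cut,
            config$q_cut, attr(selected, "achieved_fdr") %||% NA)
  } else {
    logline("integrate: skipped (no expression inputs)")
  }

  # ---- stage: candidates --------------------------------------------
  cands <- NULL
  if (!is.null(selected) && !is.null(config$de)) {
    de <- read_de_list(config$de)
    cands <- nominate_candidates(selected, calls, de,
                                 min_imbalance = config$min_imbalance)
    readr::write_tsv(cands$candidates, file.path(out, "candidates.tsv"),
                     na = "NA")
    readr::write_tsv(cands$discordant, file.path(out, "discordant.tsv"),
                     na = "NA")
    readr::write_tsv(cands$genes, file.path(out, "candidate_genes.tsv"),
                     na = "NA")
    if (nrow(cands$candidates) >= 2) {
      cl <- cluster_candidates(read_ratio_matrix(config$expr),
                               unique(cands$candidates$expr_clone_id))
      write_clustering(cl, file.path(out, "clustering"))
    }
    logline("candidates: %d clones (%d oncogene, %d tsg), %d genes",
            nrow(cands$candidates),
            sum(cands$candidates$class == "oncogene"),
            sum(cands$candidates$class == "tsg"), nrow(cands$genes))
  } else if (is.null(config$de)) {
    message("candidates stage skipped: no DE list configured")
    logline("candidates: skipped (no DE list)")
  }

  invisible(list(
    segmentation = seg, segments = segments, smoothed = smoothed,
    thresholds = th, calls = calls, arm_calls = arm_calls,
    frequency = freq, events = events, records = records,
    selected = selected, binned = binned, candidates = cands,
    clinical = clinical, out_dir = out
  ))
}

# Planted-event truth in the TSV form written next to synthetic inputs:
# one row per (sample, event) with the clone span, shift and implied call.
truth_file <- function(study) {
  ab <- study$config$aberrations
  carriers <- study$acgh$truth$carriers
  ids <- sim_sample_ids(study$config)
  purrr::map_dfr(seq_len(nrow(ab)), function(e) {
    shift <- ab$shift[e] * study$config$admixture_shrink
    tibble::tibble(
      sample_id = ids[carriers[[e]]],
      chromosome = paste0("chr", ab$chrom[e]),
      start_clone = ab$start_index[e],
      end_clone = ab$end_index[e],
      shift = shift,
      call = call_value(shift, cna_thresholds())
    )
  })
}
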