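# Candidate oncogene / tumour-suppressor nomination: the conjunction of
# dosage correlation, recurrent copy-number imbalance, and concordant
# differential expression.

#' Gain/loss imbalance at each record's mapped BAC
#'
#' Counts, across samples, calls in \{gain, amp\} and \{loss, homdel\} at
#' the BAC clone each expression record maps to; missing calls are
#' excluded. The imbalance is `n_gain - n_loss`.
#'
#' @param records Correlation records with a `mapped_bac_id` column.
#' @param calls Call table from [call_clones()] covering the mapped BACs.
#' @return `records` with columns `n_gain`, `n_loss`, `imbalance`.
#' @export
gain_loss_imbalance <- function(records, calls) {
  cm <- as.matrix(calls[, -1, drop = FALSE])
  rownames(cm) <- calls$probe_id
  idx <- match(records$mapped_bac_id, rownames(cm))
  if (any(is.na(idx) & !is.na(records$mapped_bac_id))) {
    abort("some mapped BACs are absent from the call matrix")
  }
  n_gain <- n_loss <- rep(NA_integer_, nrow(records))
  ok <- which(!is.na(idx))
  sub <- cm[idx[ok], , drop = FALSE]
  n_gain[ok] <- as.integer(rowSums(sub == "gain" | sub == "amp", na.rm = TRUE))
  n_loss[ok] <- as.integer(rowSums(sub == "loss" | sub == "homdel", na.rm = TRUE))
  records$n_gain <- n_gain
  records$n_loss <- n_loss
  records$imbalance <- n_gain - n_loss
  records
}

#' Nominate candidate oncogenes and tumour suppressor genes
#'
#' Applies the three-criterion filter to dosage-correlated records:
#' the record passed [select_correlated()]; its mapped BAC shows at
#' least `min_imbalance` more gains than losses (oncogene direction) or
#' more losses than gains (suppressor direction); and the clone is in
#' the differential-expression list with the concordant direction (up
#' for gained, down for lost). Discordant records - imbalance passing in
#' one direction with differential expression in the other - are
#' excluded and reported, not silently dropped. A gene-level roll-up
#' counts each gene once, represented by its highest-correlation clone;
#' genes whose clones disagree on the class are reported as conflicts.
#'
#' @param records_selected Output of [select_correlated()].
#' @param calls Call table (raw-ratio calls by convention).
#' @param de DE list tibble: `expr_clone_id`, `direction` in
#'   \{up, down\} (a `gene_symbol` column is allowed).
#' @param min_imbalance Minimum |gains - losses| (default 5).
#' @return List of class `cna_candidates`: `candidates` (clone-level
#'   tibble with `class` in \{oncogene, tsg\}), `discordant`,
#'   `genes` (one row per gene, representative clone), `conflicts`
#'   (genes with clones of both classes).
#' @export
nominate_candidates <- function(records_selected, calls, de,
                                min_imbalance = 5) {
  if (!all(c("expr_clone_id", "direction") %in% names(de))) {
    abort("DE list must have columns `expr_clone_id` and `direction`")
  }
  if (!all(de$direction %in% c("up", "down"))) {
    abort("DE `direction` must be 'up' or 'down'")
  }
  rec <- gain_loss_imbalance(records_selected, calls)
  rec <- dplyr::inner_join(
    rec, de[, c("expr_clone_id", "direction")], by = "expr_clone_id")
  names(rec)[names(rec) == "direction"] <- "de_direction"

  pass_gain <- rec$imbalance >= min_imbalance
  pass_loss <- -rec$imbalance >= min_imbalance
  concord <- (pass_gain & rec$de_direction == "up") |
    (pass_loss & rec$de_direction == "down")
  discord <- (pass_gain & rec$de_direction == "down") |
    (pass_loss & rec$de_direction == "up")

  cand <- rec[concord, ]
  cand$class <- ifelse(cand$imbalance >= min_imbalance, "oncogene", "tsg")
  discordant <- rec[discord, ]
  if (nrow(discordant)) {
    message(sprintf("%d records discordant between imbalance and DE direction; excluded",
                    nrow(discordant)))
  }

  genes <- cand |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::arrange(dplyr::desc(.data$r), .by_group = TRUE) |>
    dplyr::mutate(n_classes = dplyr::n_distinct(.data$class)) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  conflicts <- genes$gene_symbol[genes$n_classes > 1]
  genes <- genes[genes$n_classes == 1, setdiff(names(genes), "n_classes")]

  structure(
    list(candidates = cand, discordant = discordant, genes = genes,
         conflicts = cand[cand$gene_symbol %in% conflicts, ],
         min_imbalance = min_imbalance),
    class = "cna_candidates"
  )
}

#' @export
print.cna_candidates <- function(x, ...) {
  cat(sprintf(
    "cna_candidates: %d clones (%d oncogene, %d tsg), %d unique genes, %d discordant records\n",
    nrow(x$candidates), sum(x$candidates$class == "oncogene"),
    sum(x$candidates$class == "tsg"), nrow(x$genes), nrow(x$discordant)))
  invisible(x)
}

#' @export
tidy.cna_candidates <- function(x, ...) x$candidates

#' @export
glance.cna_candidates <- function(x, ...) {
  tibble::tibble(
    n_clones = nrow(x$candidates),
    n_oncogene = sum(x$candidates$class == "oncogene"),
    n_tsg = sum(x$candidates$class == "tsg"),
    n_genes = nrow(x$genes),
    n_discordant = nrow(x$discordant),
    n_conflict_genes = length(unique(x$conflicts$gene_symbol))
  )
}

#' Hierarchically cluster samples and candidate clones
#'
#' Agglomerative clustering with distance 1 minus the Pearson
#' correlation and average linkage, the Cluster/TreeView-style view of
#' candidate-gene expression. Constant rows are dropped with a warning.
#'
#' @param expr Expression ratio table.
#' @param clone_ids Clones to cluster (default: all rows of `expr`).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List of class `cna_clustering`: `matrix` (ordered clones x
#'   ordered samples), `sample_hclust`, `clone_hclust` (NULL when fewer
#'   than 2 clones), `sample_order`, `clone_order`.
#' @export
cluster_candidates <- function(expr, clone_ids = NULL, linkage = "average") {
  m <- ratio_matrix(expr)
  if (!is.null(clone_ids)) {
    missing_ids <- setdiff(clone_ids, rownames(m))
    if (length(missing_ids)) {
      abort(sprintf("%d requested clones absent from the expression table",
                    length(missing_ids)))
    }
    m <- m[clone_ids, , drop = FALSE]
  }
  if (ncol(m) < 2 || nrow(m) < 1) abort("need at least 1 clone and 2 samples")
  const <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || sd(v) == 0
  })
  if (any(const)) {
    warn(sprintf("%d constant clones dropped before clustering", sum(const)))
    m <- m[!const, , drop = FALSE]
  }
  cor_dist <- function(x) as.dist(1 - cor(t(x), use = "pairwise.complete.obs"))
  # with a single clone the sample correlation is undefined; fall back to
  # Euclidean distance on the one profile
  sample_h <- if (nrow(m) >= 2) {
    hclust(cor_dist(t(m)), method = linkage)
  } else {
    hclust(dist(t(m)), method = linkage)
  }
  clone_h <- if (nrow(m) >= 2) hclust(cor_dist(m), method = linkage) else NULL
  s_ord <- sample_h$order
  c_ord <- if (is.null(clone_h)) seq_len(nrow(m)) else clone_h$order
  structure(
    list(matrix = m[c_ord, s_ord, drop = FALSE],
         sample_hclust = sample_h, clone_hclust = clone_h,
         sample_order = colnames(m)[s_ord],
         clone_order = rownames(m)[c_ord]),
    class = "cna_clustering"
  )
}

#' Write a clustering as a plain-text ordered heatmap export
#'
#' Writes the reordered matrix as TSV plus the sample and clone orders,
#' a tab-delimited export suitable for external heatmap rendering.
#'
#' @param clustering A `cna_clustering`.
#' @param prefix Output path prefix; writes `<prefix>_matrix.tsv`,
#'   `<prefix>_samples.txt`, `<prefix>_clones.txt`.
#' @return The file paths, invisibly.
#' @export
write_clustering <- function(clustering, prefix) {
  stopifnot(inherits(clustering, "cna_clustering"))
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             samples = paste0(prefix, "_samples.txt"),
             clones = paste0(prefix, "_clones.txt"))
  readr::write_tsv(ratio_table(clustering$matrix), paths["matrix"])
  writeLines(clustering$sample_order, paths["samples"])
  writeLines(clustering$clone_order, paths["clones"])
  invisible(paths)
}
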