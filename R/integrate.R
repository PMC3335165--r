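# Copy-number / expression dosage correlation with a permutation null.

# Vectorized per-row Pearson correlation between paired rows of E and C,
# pairwise-complete over samples.
row_pearson <- function(E, C) {
  M <- !is.na(E) & !is.na(C)
  E0 <- E; E0[!M] <- 0
  C0 <- C; C0[!M] <- 0
  n <- rowSums(M)
  sx <- rowSums(E0); sy <- rowSums(C0)
  sxx <- rowSums(E0 * E0); syy <- rowSums(C0 * C0)
  sxy <- rowSums(E0 * C0)
  num <- n * sxy - sx * sy
  den2 <- pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0)
  r <- ifelse(n >= 2 & den2 > 0, num / sqrt(den2), NA_real_)
  list(r = r, n = n)
}

#' Map expression clones to their best-correlated nearby BAC clone
#'
#' For each expression clone, candidate BACs are those on the same
#' chromosome whose midpoint lies within `window_bp` of the expression
#' clone midpoint. The Pearson correlation between the clone's
#' expression and each candidate's smoothed copy-number values is
#' computed over pairwise-complete shared samples, and the candidate
#' with the highest correlation is selected (ties broken by smaller
#' distance, then lexicographic BAC id). Clones with no candidate are
#' returned flagged `unmapped` and are excluded downstream.
#'
#' @param expr Expression ratio table.
#' @param expr_map Expression clone map (needs `clone_id`, `chromosome`,
#'   positions; a `gene_symbol` column is carried through when present).
#' @param smoothed_cn Smoothed copy-number ratio table (see
#'   [smoothed_values()]).
#' @param map BAC clone map.
#' @param window_bp Candidate window around the expression clone (bp).
#' @param min_n Minimum pairwise-complete samples for a usable
#'   correlation.
#' @return Tibble of correlation records: `expr_clone_id`,
#'   `gene_symbol`, `chromosome`, `position`, `mapped_bac_id`,
#'   `distance_bp`, `r`, `n_used`, `unmapped`. The candidate pair table
#'   is attached as attribute `candidates` for permutation re-selection.
#' @export
map_expression_to_bac <- function(expr, expr_map, smoothed_cn, map,
                                  window_bp = 1e6, min_n = 10) {
  assert_ratio_table(expr, "expr")
  assert_ratio_table(smoothed_cn, "smoothed_cn")
  expr_map <- with_position(expr_map)
  map <- with_position(assert_clone_map(map))

  shared <- intersect(sample_ids(expr), sample_ids(smoothed_cn))
  if (length(shared) < min_n) {
    abort(sprintf("only %d shared samples; need at least %d",
                  length(shared), min_n))
  }
  E <- ratio_matrix(expr)[, shared, drop = FALSE]
  C <- ratio_matrix(smoothed_cn)[, shared, drop = FALSE]
  emap <- expr_map[match(rownames(E), expr_map$clone_id), ]
  bmap <- map[match(rownames(C), map$clone_id), ]

  pairs <- dplyr::inner_join(
    tibble::tibble(ei = seq_len(nrow(E)), chromosome = emap$chromosome,
                   epos = emap$position),
    tibble::tibble(bi = seq_len(nrow(C)), chromosome = bmap$chromosome,
                   bpos = bmap$position),
    by = "chromosome", relationship = "many-to-many")
  pairs$distance_bp <- abs(pairs$epos - pairs$bpos)
  pairs <- pairs[pairs$distance_bp <= window_bp, ]

  if (!nrow(pairs)) {
    abort("no expression clone has a candidate BAC within the window; check that both maps use the same assembly")
  }
  rp <- row_pearson(E[pairs$ei, , drop = FALSE], C[pairs$bi, , drop = FALSE])
  pairs$r <- rp$r
  pairs$n_used <- rp$n
  pairs$bac_id <- rownames(C)[pairs$bi]

  usable <- pairs[!is.na(pairs$r) & pairs$n_used >= min_n, ]
  best <- usable |>
    dplyr::group_by(.data$ei) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$distance_bp, .data$bac_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  records <- tibble::tibble(
    expr_clone_id = rownames(E),
    gene_symbol = if ("gene_symbol" %in% names(emap)) emap$gene_symbol
                  else NA_character_,
    chromosome = emap$chromosome,
    position = emap$position
  )
  records$mapped_bac_id <- NA_character_
  records$distance_bp <- NA_real_
  records$r <- NA_real_
  records$n_used <- NA_integer_
  records$mapped_bac_id[best$ei] <- best$bac_id
  records$distance_bp[best$ei] <- best$distance_bp
  records$r[best$ei] <- best$r
  records$n_used[best$ei] <- as.integer(best$n_used)
  records$unmapped <- is.na(records$mapped_bac_id)

  n_drop <- sum(records$unmapped)
  if (n_drop) {
    message(sprintf("%d of %d expression clones unmapped (no usable BAC within %g bp)",
                    n_drop, nrow(records), window_bp))
  }
  attr(records, "candidates") <- pairs[, c("ei", "bi", "bac_id", "distance_bp")]
  attr(records, "samples") <- shared
  records
}

#' Permutation p-values for copy-number/expression correlations
#'
#' For each of `n_perm` permutations the expression sample labels are
#' shuffled once, globally, and every record's Pearson correlation with
#' its mapped BAC is recomputed; a record's p-value is the proportion of
#' permutations whose correlation is greater than or equal to the
#' observed one (one-sided, positive correlations). Sharing a single
#' shuffle across records preserves the between-clone dependence needed
#' for honest FDR control downstream.
#'
#' @param records Output of [map_expression_to_bac()].
#' @param expr,smoothed_cn The ratio tables used for mapping.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_n Records whose pairwise-complete count drops below this in
#'   any permutation are dropped with a warning.
#' @param pseudo_count If `TRUE`, report (k+1)/(B+1) instead of the plain
#'   proportion k/B.
#' @param reselect If `TRUE`, each permutation re-selects the
#'   best-correlated candidate BAC per clone (more conservative) instead
#'   of re-using the observed mapping.
#' @return `records` with a `p_perm` column (unmapped records keep NA).
#' @export
permutation_pvalues <- function(records, expr, smoothed_cn, n_perm = 1000,
                                seed = 1, min_n = 10, pseudo_count = FALSE,
                                reselect = FALSE) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  shared <- attr(records, "samples") %||%
    intersect(sample_ids(expr), sample_ids(smoothed_cn))
  E <- ratio_matrix(expr)[, shared, drop = FALSE]
  C <- ratio_matrix(smoothed_cn)[, shared, drop = FALSE]

  mapped <- which(!records$unmapped)
  Em <- E[match(records$expr_clone_id[mapped], rownames(E)), , drop = FALSE]
  Cm <- C[match(records$mapped_bac_id[mapped], rownames(C)), , drop = FALSE]
  r_obs <- records$r[mapped]

  cand <- attr(records, "candidates")
  if (reselect && is.null(cand)) {
    abort("records lack the candidate table needed for reselect = TRUE")
  }

  count <- integer(length(mapped))
  n_min <- rep(ncol(E), length(mapped))
  withr::with_seed(derive_seed(seed, "perm"), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(ncol(E))
      if (!reselect) {
        rp <- row_pearson(Em[, perm, drop = FALSE], Cm)
        r_b <- rp$r
        n_min <- pmin(n_min, rp$n)
      } else {
        rp <- row_pearson(E[cand$ei, perm, drop = FALSE],
                          C[cand$bi, , drop = FALSE])
        best_b <- tapply(rp$r, cand$ei, max, na.rm = TRUE)
        r_b <- unname(best_b[as.character(mapped)])
        r_b[is.infinite(r_b)] <- NA_real_
      }
      count <- count + (!is.na(r_b) & r_b >= r_obs)
    }
  })
  p <- if (pseudo_count) (count + 1) / (n_perm + 1) else count / n_perm

  records$p_perm <- NA_real_
  records$p_perm[mapped] <- p
  low <- mapped[n_min < min_n]
  if (length(low)) {
    warn(sprintf("%d records dropped: fewer than %d pairwise-complete samples under permutation",
                 length(low), min_n))
    records <- records[-low, ]
  }
  records
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q for the i-th smallest p-value is the minimum over j >= i of
#' (m / j) p_(j), clipped at 1; the original order is restored and
#' missing p-values propagate as missing q.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  m <- length(ok)
  o <- order(p[ok])
  ps <- p[ok][o]
  qs <- pmin(rev(cummin(rev(ps * m / seq_len(m)))), 1)
  q[ok[o]] <- qs
  q
}

#' Select significantly dosage-correlated clones
#'
#' Adds BH q-values (when absent) and keeps records with `r > r_cut` and
#' `q < q_cut`. The achieved FDR bound of the selection (the largest q
#' among kept records) is attached as attribute `achieved_fdr`.
#'
#' @param records Records with `p_perm` (and optionally `q`).
#' @param r_cut Correlation cutoff (default 0.29).
#' @param q_cut BH-adjusted p cutoff (default 0.01).
#' @return The selected subset, with a `q` column.
#' @export
select_correlated <- function(records, r_cut = 0.29, q_cut = 0.01) {
  if (!"p_perm" %in% names(records)) {
    abort("run permutation_pvalues() before select_correlated()")
  }
  if (!"q" %in% names(records)) records$q <- bh_adjust(records$p_perm)
  keep <- !records$unmapped & !is.na(records$r) & !is.na(records$q) &
    records$r > r_cut & records$q < q_cut
  out <- records[keep, ]
  attr(out, "achieved_fdr") <- if (nrow(out)) max(out$q) else NA_real_
  attr(out, "candidates") <- NULL
  attr(out, "samples") <- attr(records, "samples")
  out
}

#' Binned diagonal correlation analysis
#'
#' Each chromosome arm is divided into bins of `bin_bp`; for every pair
#' of an expression bin and a copy-number bin, the average pairwise
#' Pearson correlation between all expression clones in the one and all
#' BAC clones in the other is computed. Diagonal entries pair a bin with
#' itself; a cis dosage effect shows up as the median diagonal
#' correlation exceeding the median off-diagonal correlation. Missing
#' entries are mean-imputed per probe before correlating.
#'
#' @param expr,expr_map Expression ratio table and clone map.
#' @param smoothed_cn,map Smoothed copy-number ratio table and BAC map.
#' @param bin_bp Bin size in bp (default 20 Mb).
#' @return Object of class `cna_binned_map`: `grid` (tibble:
#'   `expr_bin`, `cn_bin`, `chromosome_expr`, `arm_expr`, ..., `mean_r`,
#'   `n_pairs`, `diagonal`) and `summary` (medians).
#' @export
binned_diagonal_analysis <- function(expr, expr_map, smoothed_cn, map,
                                     bin_bp = 2e7) {
  expr_map <- with_position(expr_map)
  map <- with_position(map)
  shared <- intersect(sample_ids(expr), sample_ids(smoothed_cn))
  if (length(shared) < 3) abort("need at least 3 shared samples")
  E <- ratio_matrix(expr)[, shared, drop = FALSE]
  C <- ratio_matrix(smoothed_cn)[, shared, drop = FALSE]
  emap <- expr_map[match(rownames(E), expr_map$clone_id), ]
  bmap <- map[match(rownames(C), map$clone_id), ]

  bin_of <- function(m) {
    key <- paste(m$chromosome, m$arm)
    base <- stats::ave(m$position, key, FUN = min)
    paste0(key, ":", floor((m$position - base) / bin_bp))
  }
  ebin <- bin_of(emap)
  cbin <- bin_of(bmap)

  zscore <- function(M) {
    mu <- rowMeans(M, na.rm = TRUE)
    M[is.na(M)] <- mu[which(is.na(M), arr.ind = TRUE)[, 1]]
    M <- M - rowMeans(M)
    s <- sqrt(rowSums(M^2))
    keep <- s > 0
    list(z = M[keep, , drop = FALSE] / s[keep], keep = keep)
  }
  ze <- zscore(E)
  zc <- zscore(C)
  R <- ze$z %*% t(zc$z)   # exact Pearson of the imputed rows

  eb <- ebin[ze$keep]
  cb <- cbin[zc$keep]
  sums <- t(rowsum(t(rowsum(R, eb)), cb))  # expr-bin x cn-bin pair sums
  n_e <- table(eb)[rownames(sums)]
  n_c <- table(cb)[colnames(sums)]
  counts <- outer(as.vector(n_e), as.vector(n_c))
  meanr <- sums / counts

  grid <- tibble::tibble(
    expr_bin = rep(rownames(meanr), times = ncol(meanr)),
    cn_bin = rep(colnames(meanr), each = nrow(meanr)),
    mean_r = as.vector(meanr),
    n_pairs = as.vector(counts)
  )
  grid$diagonal <- grid$expr_bin == grid$cn_bin
  med_d <- median(grid$mean_r[grid$diagonal], na.rm = TRUE)
  med_o <- median(grid$mean_r[!grid$diagonal], na.rm = TRUE)
  structure(
    list(grid = grid,
         summary = list(median_diagonal = med_d, median_off_diagonal = med_o,
                        difference = med_d - med_o),
         bin_bp = bin_bp),
    class = "cna_binned_map"
  )
}

#' @export
print.cna_binned_map <- function(x, ...) {
  cat(sprintf(
    "cna_binned_map (%g Mb bins): median diagonal r = %.4f, off-diagonal r = %.4f\n",
    x$bin_bp / 1e6, x$summary$median_diagonal, x$summary$median_off_diagonal))
  invisible(x)
}

#' @export
tidy.cna_binned_map <- function(x, ...) x$grid

#' @export
glance.cna_binned_map <- function(x, ...) {
  tibble::tibble(
    median_diagonal = x$summary$median_diagonal,
    median_off_diagonal = x$summary$median_off_diagonal,
    difference = x$summary$difference,
    n_bins = length(unique(x$grid$cn_bin))
  )
}
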