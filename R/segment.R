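#' Flag and shrink outlier probes before segmentation
#'
#' A probe is flagged as an outlier when it deviates from the median of
#' its `k` neighbours on either side (excluding itself) by more than `z`
#' times the robust SD of the chromosome (median absolute deviation with
#' the usual 1.4826 consistency factor). Flagged values are shrunk to the
#' neighbour median plus/minus `z` times the robust SD; the shrunk vector
#' is meant for change-point testing only, the original values being
#' retained for reporting.
#'
#' @param values Ordered numeric log2 ratios of one chromosome (no NAs;
#'   drop missing probes before calling).
#' @param k Window half-width (neighbours on each side).
#' @param z Robust-SD multiplier.
#' @return List: `values` (shrunk copy), `flags` (logical).
#' @export
smooth_outliers <- function(values, k = 2, z = 4) {
  n <- length(values)
  if (anyNA(values)) abort("smooth_outliers expects no missing values")
  if (n < 3) return(list(values = values, flags = rep(FALSE, n)))
  rsd <- mad(values, constant = 1.4826)
  if (rsd == 0) return(list(values = values, flags = rep(FALSE, n)))
  flags <- logical(n)
  out <- values
  for (i in seq_len(n)) {
    nb <- setdiff(max(1, i - k):min(n, i + k), i)
    med <- median(values[nb])
    dev <- values[i] - med
    if (abs(dev) > z * rsd) {
      flags[i] <- TRUE
      out[i] <- med + sign(dev) * z * rsd
    }
  }
  list(values = out, flags = flags)
}

#' Segment one chromosome by circular binary segmentation
#'
#' Recursive change-point search: the probe sequence is treated as a
#' circle and the arc maximizing the absolute pooled-variance two-sample
#' t statistic between
#' in-arc and out-of-arc values is located; its significance is assessed
#' against `n_perm` random shuffles of the sequence (p = proportion of
#' shuffles whose maximal statistic is at least the observed one). If
#' p <= `alpha` the sequence is split at the arc boundary/boundaries and
#' the procedure recurses on each piece; otherwise one segment is
#' emitted. Adjacent segments whose means differ by less than
#' `merge_tol` are merged. The permutation reference of each test is
#' seeded deterministically from `seed` and the piece location, so a
#' fixed seed gives identical segmentations and the search never touches
#' R's global random-number state.
#'
#' @param values Numeric log2 ratios, already outlier-shrunk, no NAs.
#' @param alpha Significance level for a split.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param merge_tol Merge adjacent segments closer than this (log2 units).
#' @param pseudo_count If `TRUE`, use the (k+1)/(B+1) permutation
#'   p-value instead of the plain proportion.
#' @return Tibble of segments: `start`, `end` (1-based inclusive /
#'   exclusive probe indices into `values`), `mean`, `n_probes`.
#' @export
cbs_segment <- function(values, alpha = 0.01, n_perm = 1000, seed = 1,
                        merge_tol = 0.05, pseudo_count = FALSE) {
  if (anyNA(values)) abort("cbs_segment expects no missing values")
  if (n_perm < 100) abort("n_perm must be >= 100 (smaller values give unstable p-values)")
  n <- length(values)
  if (n == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          mean = double(), n_probes = integer()))
  }
  segs <- cbs_recurse(values, offset = 0L, alpha = alpha, n_perm = n_perm,
                      seed = seed, pseudo_count = pseudo_count)
  segs <- merge_close_segments(segs, values, merge_tol)
  tibble::tibble(
    start = segs$start, end = segs$end,
    mean = vapply(seq_along(segs$start),
                  function(i) mean(values[segs$start[i]:(segs$end[i] - 1L)]), 0),
    n_probes = segs$end - segs$start
  )
}

# Recursion on values[(offset+1):(offset+n)] of the original vector;
# returns list(start, end) of 1-based [start, end) indices.
cbs_recurse <- function(x, offset, alpha, n_perm, seed, pseudo_count) {
  n <- length(x)
  whole <- list(start = offset + 1L, end = offset + n + 1L)
  if (n < 4) return(whole)
  hit <- cbs_scan_cpp(x)
  if (!is.finite(hit$t) && hit$t < 0) return(whole)
  stop_count <- if (pseudo_count) {
    floor(alpha * (n_perm + 1))
  } else {
    floor(alpha * n_perm) + 1L
  }
  piece_seed <- derive_seed(seed, "cbs", offset, n)
  pc <- cbs_perm_count_cpp(x, hit$t, n_perm, piece_seed, stop_count)
  significant <- if (pc$done < n_perm) {
    FALSE  # early stop: exceedances already force p > alpha
  } else if (pseudo_count) {
    (pc$count + 1) / (n_perm + 1) <= alpha
  } else {
    pc$count / n_perm <= alpha
  }
  if (!significant) return(whole)
  cuts <- unique(c(hit$b1, hit$b2))           # 0-based boundaries
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(whole)
  bounds <- c(0L, sort(cuts), n)
  parts <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i]; b <- bounds[i + 1L]
    cbs_recurse(x[(a + 1L):b], offset + a, alpha, n_perm, seed, pseudo_count)
  })
  list(start = unlist(lapply(parts, `[[`, "start")),
       end = unlist(lapply(parts, `[[`, "end")))
}

merge_close_segments <- function(segs, values, merge_tol) {
  start <- segs$start; end <- segs$end
  seg_mean <- function(i) mean(values[start[i]:(end[i] - 1L)])
  repeat {
    if (length(start) < 2) break
    means <- vapply(seq_along(start), seg_mean, 0)
    d <- abs(diff(means))
    if (all(d >= merge_tol)) break
    i <- which.min(d)
    end[i] <- end[i + 1L]
    start <- start[-(i + 1L)]
    end <- end[-(i + 1L)]
  }
  list(start = start, end = end)
}

#' Segment a full study: CBS with outlier smoothing and imputation
#'
#' Per sample and chromosome: missing probes are set aside, outliers are
#' flagged and shrunk ([smooth_outliers()]), the shrunk sequence is
#' segmented ([cbs_segment()]), and segment boundaries are mapped back to
#' clone index space (segments are contiguous from the first to the last
#' non-missing clone of the chromosome). The smoothed matrix holds each
#' clone's segment mean, except that flagged outlier clones keep their
#' originally observed log2 ratio; missing clones inside a segment span
#' are imputed with the segment mean by [impute_missing()] (on by
#' default), while missing clones outside any segment stay missing.
#'
#' @param ratios Ratio table of raw log2 ratios.
#' @param map Clone map.
#' @param alpha,n_perm,seed,merge_tol,pseudo_count See [cbs_segment()].
#' @param k,z See [smooth_outliers()].
#' @param impute Impute missing clones inside segments (default TRUE).
#' @return Object of class `cna_segmentation`: list with `segments`
#'   (tibble: `sample_id`, `chromosome`, `start_index`, `end_index`
#'   clone indices within chromosome, 1-based half-open; `start`, `end`
#'   bp; `mean`; `n_probes`), `smoothed` (ratio table), `outliers`
#'   (logical matrix as tibble), `params`.
#' @export
segment_cna <- function(ratios, map, alpha = 0.01, n_perm = 1000, seed = 1,
                        merge_tol = 0.05, k = 2, z = 4,
                        pseudo_count = FALSE, impute = TRUE) {
  assert_ratio_table(ratios, "ratios")
  assert_clone_map(map)
  m <- ratio_matrix(ratios)
  map <- map[match(rownames(m), map$clone_id), ]
  if (anyNA(map$clone_id)) abort("ratio table contains probes absent from the map")

  smoothed <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  outliers <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  chroms <- unique(map$chromosome)
  all_segs <- vector("list", length(chroms) * ncol(m))
  ix <- 0L

  for (ch in chroms) {
    rows <- which(map$chromosome == ch)
    for (s in colnames(m)) {
      v <- unname(m[rows, s])
      ok <- which(!is.na(v))
      ix <- ix + 1L
      if (length(ok) == 0) {
        warn(sprintf("sample %s: chromosome %s is entirely missing", s, ch))
        next
      }
      sm <- smooth_outliers(v[ok], k = k, z = z)
      outliers[rows[ok], s] <- sm$flags
      segs <- cbs_segment(sm$values, alpha = alpha, n_perm = n_perm,
                          seed = derive_seed(seed, s, ch),
                          merge_tol = merge_tol, pseudo_count = pseudo_count)
      # map [start, end) in non-missing space to clone-index space:
      # contiguous coverage from first to last non-missing clone
      ci_start <- ok[segs$start]
      ci_end <- c(ok[segs$start][-1], ok[length(ok)] + 1L)
      for (g in seq_len(nrow(segs))) {
        members <- rows[ok[segs$start[g]:(segs$end[g] - 1L)]]
        smoothed[members, s] <- segs$mean[g]
      }
      all_segs[[ix]] <- tibble::tibble(
        sample_id = s, chromosome = ch,
        start_index = ci_start, end_index = ci_end,
        start = map$start[rows[ci_start]],
        end = map$end[rows[ci_end - 1L]],
        mean = segs$mean, n_probes = segs$n_probes
      )
    }
  }
  # outlier clones keep the observed value in the smoothed matrix
  smoothed[outliers] <- m[outliers]

  res <- structure(
    list(
      segments = dplyr::bind_rows(all_segs),
      smoothed = ratio_table(smoothed),
      outliers = tibble::as_tibble(as.data.frame(outliers),
                                   rownames = "probe_id"),
      map = map,
      params = list(alpha = alpha, n_perm = n_perm, seed = seed,
                    merge_tol = merge_tol, k = k, z = z,
                    pseudo_count = pseudo_count)
    ),
    class = "cna_segmentation"
  )
  if (impute) res <- impute_missing(res) else res
}

#' Impute missing clones with their segment mean
#'
#' Every clone whose within-chromosome index falls inside a segment's
#' index span and whose smoothed value is missing receives that
#' segment's mean. Clones outside any segment (chromosome ends beyond
#' the outermost non-missing clones, or entirely missing chromosomes)
#' remain missing and are listed in `unsegmented`. Idempotent.
#'
#' @param result A `cna_segmentation`.
#' @return The result with `smoothed` filled in and an `unsegmented`
#'   tibble (`probe_id`, `sample_id`) of still-missing cells.
#' @export
impute_missing <- function(result) {
  stopifnot(inherits(result, "cna_segmentation"))
  sm <- ratio_matrix(result$smoothed)
  map <- result$map
  segs <- result$segments
  for (ch in unique(segs$chromosome)) {
    rows <- which(map$chromosome == ch)
    sub <- segs[segs$chromosome == ch, ]
    for (g in seq_len(nrow(sub))) {
      cells <- rows[sub$start_index[g]:(sub$end_index[g] - 1L)]
      s <- sub$sample_id[g]
      fill <- cells[is.na(sm[cells, s])]
      if (length(fill)) sm[fill, s] <- sub$mean[g]
    }
  }
  still <- which(is.na(sm), arr.ind = TRUE)
  result$smoothed <- ratio_table(sm)
  result$unsegmented <- tibble::tibble(
    probe_id = rownames(sm)[still[, 1]],
    sample_id = colnames(sm)[still[, 2]]
  )
  result
}

#' @export
print.cna_segmentation <- function(x, ...) {
  cat(sprintf(
    "cna_segmentation: %d samples, %d segments (alpha = %g, %d permutations)\n",
    length(unique(x$segments$sample_id)), nrow(x$segments),
    x$params$alpha, x$params$n_perm))
  invisible(x)
}

#' @export
tidy.cna_segmentation <- function(x, ...) x$segments

#' @export
glance.cna_segmentation <- function(x, ...) {
  out_m <- as.matrix(x$outliers[, -1])
  sm <- ratio_matrix(x$smoothed)
  tibble::tibble(
    n_samples = length(unique(x$segments$sample_id)),
    n_segments = nrow(x$segments),
    segments_per_sample = nrow(x$segments) /
      max(1L, length(unique(x$segments$sample_id))),
    frac_outliers = mean(out_m),
    frac_missing_after = mean(is.na(sm))
  )
}

#' Extract the smoothed copy-number matrix
#'
#' @param result A `cna_segmentation`.
#' @return Ratio table of smoothed values (segment means, original values
#'   at outlier clones, imputed values at missing clones).
#' @export
smoothed_values <- function(result) {
  stopifnot(inherits(result, "cna_segmentation"))
  result$smoothed
}
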