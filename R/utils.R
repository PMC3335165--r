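# Internal helpers shared across modules.

# A "ratio table" is the package-wide tabular form of a probes x samples
# log2-ratio matrix: a tibble whose first column is `probe_id` and whose
# remaining columns are one numeric column per sample. NA marks missing.

#' Convert a ratio table to a numeric matrix
#'
#' @param x A ratio table (tibble with a `probe_id` column followed by one
#'   numeric column per sample).
#' @return Numeric matrix with probe ids as row names and sample ids as
#'   column names.
#' @keywords internal
#' @noRd
ratio_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "probe_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$probe_id
  m
}

#' Convert a numeric matrix back to a ratio table
#' @keywords internal
#' @noRd
ratio_table <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "probe_id")
}

sample_ids <- function(x) names(x)[-1]

assert_ratio_table <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2 || names(x)[1] != "probe_id") {
    abort(sprintf(
      "`%s` must be a ratio table: a data frame with a `probe_id` first column and one column per sample.",
      arg
    ))
  }
  if (ncol(x) < 3) abort("at least 2 samples required")
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (any(is.infinite(vals))) {
    abort(sprintf("`%s` contains non-finite log2 ratios.", arg))
  }
  invisible(x)
}

assert_clone_map <- function(map, arg = "map") {
  needed <- c("clone_id", "chromosome", "arm", "start", "end")
  miss <- setdiff(needed, names(map))
  if (length(miss)) {
    abort(sprintf("`%s` is missing clone-map columns: %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(map$clone_id)) abort("duplicate clone ids in clone map")
  if (any(map$start >= map$end)) abort("clone map has start >= end")
  invisible(map)
}

# Midpoint used as the single per-probe anchor for all distance work.
with_position <- function(map) {
  if (!"position" %in% names(map)) {
    map$position <- (map$start + map$end) / 2
  }
  map
}

# Deterministic sub-seed below 2^31 for a significance test or stage,
# derived from a base seed plus a context string. Independent of R's RNG.
derive_seed <- function(seed, ...) {
  ctx <- paste(c(seed, ...), collapse = "|")
  h <- digest::digest(ctx, algo = "xxhash32", serialize = FALSE)
  strtoi(substr(h, 1, 7), base = 16L)
}

# Natural chromosome ordering: chr1..chr22, chrX, chrY (or bare 1..22,X,Y).
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  key <- sub("^chr", "", u)
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(key == "X", 23L, ifelse(key == "Y", 24L, 25L)))
  u[order(rank, key)]
}

chrom_factor <- function(chroms) {
  factor(as.character(chroms), levels = chrom_order(chroms))
}

# Ordinal aberration classes, lowest to highest copy number.
CALL_LEVELS <- c("homdel", "loss", "neutral", "gain", "amp")
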