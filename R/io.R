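# On-disk dialects. Everything is TSV with a header line and "NA" as the
# missing-value token; all coordinates are 0-based half-open. The only
# other format is the BED export of region catalogues (already 0-based).

CLONE_MAP_COLS <- c("clone_id", "chromosome", "arm", "start", "end")

#' Read a clone map
#'
#' Expects TSV columns `clone_id`, `chromosome`, `arm`, `start`, `end`
#' (0-based half-open bp; optional extra columns such as `gene_symbol`
#' are kept). Rows are sorted by (chromosome, start) in natural
#' chromosome order and a midpoint `position` column is added.
#'
#' @param path File path.
#' @return Clone-map tibble.
#' @export
read_clone_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                       col_types = readr::cols(
                         clone_id = "c", chromosome = "c", arm = "c",
                         start = "d", end = "d",
                         .default = readr::col_guess()))
  miss <- setdiff(CLONE_MAP_COLS, names(x))
  if (length(miss)) {
    abort(sprintf("clone map %s lacks columns: %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$clone_id)) abort("duplicate clone ids in clone map")
  if (any(x$start >= x$end)) abort("clone map has start >= end")
  if (!all(x$arm %in% c("p", "q"))) abort("arm must be 'p' or 'q'")
  x <- x[order(chrom_factor(x$chromosome), x$start), ]
  with_position(x)
}

#' Write a clone map
#' @param map Clone-map tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_clone_map <- function(map, path) {
  assert_clone_map(map)
  readr::write_tsv(map[, setdiff(names(map), "position")], path, na = "NA")
  invisible(path)
}

#' Read a log2-ratio matrix
#'
#' TSV dialect: a `probe_id` column followed by one numeric column per
#' sample. Probes absent from `map` are dropped with a message; rows are
#' re-sorted to map order; probes with more than 50% missing values are
#' kept but flagged with a warning.
#'
#' @param path File path.
#' @param map Clone map the probes must belong to (optional).
#' @return Ratio table.
#' @export
read_ratio_matrix <- function(path, map = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                       col_types = readr::cols(probe_id = "c",
                                               .default = "d"))
  if (names(x)[1] != "probe_id") abort("first column must be `probe_id`")
  if (ncol(x) < 3) abort("at least 2 samples required")
  if (anyDuplicated(x$probe_id)) abort("duplicate probe ids in ratio matrix")
  if (!is.null(map)) {
    assert_clone_map(map)
    known <- x$probe_id %in% map$clone_id
    if (!all(known)) {
      message(sprintf("%d probes absent from the map dropped", sum(!known)))
      x <- x[known, ]
    }
    x <- x[order(match(x$probe_id, map$clone_id)), ]
  }
  frac_na <- rowMeans(is.na(as.matrix(x[, -1])))
  if (any(frac_na > 0.5)) {
    warn(sprintf("%d probes have more than 50%% missing values (retained)",
                 sum(frac_na > 0.5)))
  }
  x
}

#' Write a log2-ratio matrix
#' @param ratios Ratio table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(ratios, path) {
  assert_ratio_table(ratios, "ratios")
  readr::write_tsv(ratios, path, na = "NA")
  invisible(path)
}

#' Read a clinical annotation table
#'
#' TSV with `sample_id` plus clinical factors (`stage`, `lauren_type`,
#' `site`, `differentiation`, `hpylori`, `ebv`); any field may be
#' missing.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                       col_types = readr::cols(sample_id = "c",
                                               stage = "i",
                                               .default = "c"))
  if (!"sample_id" %in% names(x)) abort("clinical table needs `sample_id`")
  if (anyDuplicated(x$sample_id)) abort("duplicate sample ids in clinical table")
  x
}

#' Write a clinical annotation table
#' @param clinical Tibble with `sample_id`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, na = "NA")
  invisible(path)
}

#' Read a differential-expression clone list
#'
#' TSV columns `expr_clone_id`, `gene_symbol`, `direction`
#' (up/down in tumour).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_de_list <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                       col_types = readr::cols(.default = "c"))
  if (!all(c("expr_clone_id", "direction") %in% names(x))) {
    abort("DE list needs columns `expr_clone_id` and `direction`")
  }
  if (anyDuplicated(x$expr_clone_id)) abort("duplicate clone ids in DE list")
  if (!all(x$direction %in% c("up", "down"))) {
    abort("DE direction must be 'up' or 'down'")
  }
  x
}

#' Write a differential-expression clone list
#' @param de Tibble with `expr_clone_id`, `direction`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_de_list <- function(de, path) {
  readr::write_tsv(de, path, na = "NA")
  invisible(path)
}

#' Write a region catalogue as BED
#'
#' BED dialect with 0-based half-open coordinates and columns
#' chrom/start/end/name/score, where name is the event class and score
#' the number of samples carrying the event. An empty catalogue yields a
#' file holding only the header comment.
#'
#' @param regions Tibble with `chromosome`, `start`, `end`, `class`,
#'   `n_samples` (the `recurrent` element of [catalogue_events()] fits).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  needed <- c("chromosome", "start", "end", "class", "n_samples")
  miss <- setdiff(needed, names(regions))
  if (length(miss)) {
    abort(sprintf("regions lack columns: %s", paste(miss, collapse = ", ")))
  }
  if (any(regions$start >= regions$end)) {
    abort("regions must have start < end (0-based half-open)")
  }
  lines <- "#chrom\tstart\tend\tname\tscore"
  if (nrow(regions)) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d",
                              regions$chromosome,
                              as.integer(regions$start),
                              as.integer(regions$end),
                              regions$class,
                              as.integer(regions$n_samples)))
  }
  writeLines(lines, path)
  invisible(path)
}
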