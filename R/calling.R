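#' Aberration-calling thresholds
#'
#' Ordinal thresholds on the normalized log2 ratio. The gain/loss cut of
#' 0.225 is the conventional "3 times the average SD of normal-vs-normal
#' hybridizations" rule for BAC arrays; amplification (> 0.8) and
#' homozygous deletion (< -0.7) are fixed high-level cuts.
#'
#' @param gain,loss,amp,homdel Log2-ratio thresholds. Must satisfy
#'   `homdel < loss < 0 < gain < amp`.
#' @param sd_multiplier Multiplier used by [derive_thresholds()].
#' @return Object of class `cna_thresholds`.
#' @export
cna_thresholds <- function(gain = 0.225, loss = -0.225, amp = 0.8,
                           homdel = -0.7, sd_multiplier = 3) {
  if (!(homdel < loss && loss < 0 && 0 < gain && gain < amp)) {
    abort("thresholds must satisfy homdel < loss < 0 < gain < amp")
  }
  structure(
    list(gain = gain, loss = loss, amp = amp, homdel = homdel,
         sd_multiplier = sd_multiplier),
    class = "cna_thresholds"
  )
}

#' @export
print.cna_thresholds <- function(x, ...) {
  cat(sprintf(
    "cna_thresholds: gain > %.4g, loss < %.4g, amp > %.4g, homdel < %.4g (sd multiplier %.3g)\n",
    x$gain, x$loss, x$amp, x$homdel, x$sd_multiplier))
  invisible(x)
}

#' Derive gain/loss thresholds from normal-vs-normal hybridizations
#'
#' The gain threshold is `sd_multiplier` times the average per-profile SD
#' of the reference log2 ratios; the loss threshold is its negative.
#' Amplification and homozygous-deletion cuts are taken from `base`
#' unchanged, as they are set independently of array noise.
#'
#' @param normals Ratio table of normal-vs-normal profiles (>= 1 column).
#' @param sd_multiplier SD multiplier (default 3).
#' @param base `cna_thresholds` supplying the amp/homdel cuts.
#' @return A `cna_thresholds` object.
#' @export
derive_thresholds <- function(normals, sd_multiplier = 3,
                              base = cna_thresholds()) {
  if (!is.data.frame(normals) || ncol(normals) < 2) {
    abort("`normals` must contain at least one reference profile")
  }
  m <- ratio_matrix(normals)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    abort("degenerate reference: a normal-vs-normal profile has zero or undefined SD")
  }
  g <- sd_multiplier * mean(sds)
  cna_thresholds(gain = g, loss = -g, amp = base$amp, homdel = base$homdel,
                 sd_multiplier = sd_multiplier)
}

call_value <- function(v, th) {
  ifelse(is.na(v), NA_character_,
    ifelse(v > th$amp, "amp",
      ifelse(v > th$gain, "gain",
        ifelse(v < th$homdel, "homdel",
          ifelse(v < th$loss, "loss", "neutral")))))
}

#' Call per-clone aberrations from log2 ratios
#'
#' Strict-inequality thresholding: value > amp cut is `amp`; else > gain
#' cut is `gain`; < homdel cut is `homdel`; else < loss cut is `loss`;
#' otherwise `neutral`. Values exactly at a cut are neutral; missing
#' values give missing calls.
#'
#' @param ratios Ratio table of raw per-clone log2 ratios.
#' @param thresholds A [cna_thresholds()].
#' @return Call table: `probe_id` plus one character column per sample
#'   with values in `homdel < loss < neutral < gain < amp`.
#' @export
call_clones <- function(ratios, thresholds = cna_thresholds()) {
  stopifnot(inherits(thresholds, "cna_thresholds"))
  m <- ratio_matrix(ratios)
  calls <- matrix(call_value(m, thresholds), nrow(m), ncol(m),
                  dimnames = dimnames(m))
  tibble::as_tibble(as.data.frame(calls), rownames = "probe_id")
}

#' Call whole-arm gains and losses
#'
#' An arm is called gained (lost) when the median log2 ratio over its
#' non-missing clones strictly exceeds the gain threshold (falls below
#' the loss threshold); otherwise neutral. Arms with no non-missing
#' clones get a missing call.
#'
#' @param ratios Ratio table.
#' @param map Clone map assigning every probe to a chromosome arm.
#' @param thresholds A [cna_thresholds()].
#' @return Tibble: `chromosome`, `arm`, `sample_id`, `median_log2`, `call`.
#' @export
call_arms <- function(ratios, map, thresholds = cna_thresholds()) {
  assert_clone_map(map)
  m <- ratio_matrix(ratios)
  map <- map[match(rownames(m), map$clone_id), ]
  if (anyNA(map$clone_id)) abort("ratio table contains probes absent from the map")
  key <- paste(map$chromosome, map$arm)
  out <- purrr::map_dfr(unique(key), function(k) {
    rows <- which(key == k)
    med <- apply(m[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    tibble::tibble(
      chromosome = map$chromosome[rows[1]],
      arm = map$arm[rows[1]],
      sample_id = colnames(m),
      median_log2 = unname(med),
      call = unname(ifelse(is.na(med), NA_character_,
               ifelse(med > thresholds$gain, "gain",
                 ifelse(med < thresholds$loss, "loss", "neutral"))))
    )
  })
  out
}

# Maximal runs of TRUE in a logical vector (NA counts as FALSE and breaks
# runs). Returns tibble(start, end) of 1-based inclusive indices.
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Catalogue copy-number events per sample and recurrent regions
#'
#' Per sample and chromosome, events are maximal runs of clones in the
#' same aberration class; multiple runs of the same class are counted as
#' separate events. Gain events include amplified clones (amp implies
#' gain) and amplicons are additionally reported as their own events;
#' symmetrically homozygous deletions are contained in loss events.
#' Recurrent regions are the maximal genomic intervals over which the set
#' of carrier samples of a class is constant, with carrier counts.
#'
#' @param calls Call table from [call_clones()].
#' @param map Clone map.
#' @return List of class `cna_events`: `events` (tibble `sample_id`,
#'   `chromosome`, `start`, `end`, `start_index`, `end_index`, `class`,
#'   `n_probes`) and `recurrent` (tibble `chromosome`, `start`, `end`,
#'   `class`, `n_samples`, `samples`).
#' @export
catalogue_events <- function(calls, map) {
  assert_clone_map(map)
  cm <- as.matrix(calls[, -1, drop = FALSE])
  rownames(cm) <- calls$probe_id
  map <- map[match(rownames(cm), map$clone_id), ]
  class_sets <- list(
    gain = c("gain", "amp"), loss = c("loss", "homdel"),
    amp = "amp", homdel = "homdel"
  )
  events <- purrr::map_dfr(unique(map$chromosome), function(ch) {
    rows <- which(map$chromosome == ch)
    purrr::map_dfr(colnames(cm), function(s) {
      v <- unname(cm[rows, s])
      purrr::map_dfr(names(class_sets), function(cl) {
        rr <- runs_of(v %in% class_sets[[cl]] & !is.na(v))
        if (!nrow(rr)) return(NULL)
        tibble::tibble(
          sample_id = s, chromosome = ch,
          start = map$start[rows[rr$start]],
          end = map$end[rows[rr$end]],
          start_index = rr$start, end_index = rr$end,
          class = cl, n_probes = rr$end - rr$start + 1L
        )
      })
    })
  })
  if (!nrow(events)) {
    events <- tibble::tibble(
      sample_id = character(), chromosome = character(), start = double(),
      end = double(), start_index = integer(), end_index = integer(),
      class = character(), n_probes = integer())
  }
  recurrent <- recurrent_regions(cm, map, class_sets)
  structure(list(events = events, recurrent = recurrent),
            class = "cna_events")
}

recurrent_regions <- function(cm, map, class_sets) {
  out <- purrr::map_dfr(names(class_sets), function(cl) {
    member <- !is.na(cm) & matrix(cm %in% class_sets[[cl]], nrow(cm))
    purrr::map_dfr(unique(map$chromosome), function(ch) {
      rows <- which(map$chromosome == ch)
      sub <- member[rows, , drop = FALSE]
      key <- unname(apply(sub, 1, function(z) paste(which(z), collapse = ",")))
      r <- rle(key)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != ""
      if (!any(keep)) return(NULL)
      tibble::tibble(
        chromosome = ch,
        start = map$start[rows[starts[keep]]],
        end = map$end[rows[ends[keep]]],
        class = cl,
        n_samples = vapply(strsplit(r$values[keep], ","), length, 1L),
        samples = vapply(
          strsplit(r$values[keep], ","),
          function(i) paste(colnames(cm)[as.integer(i)], collapse = ";"), "")
      )
    })
  })
  if (!nrow(out)) {
    out <- tibble::tibble(chromosome = character(), start = double(),
                          end = double(), class = character(),
                          n_samples = integer(), samples = character())
  }
  out
}

#' Per-clone gain/loss frequencies
#'
#' Fraction of non-missing samples called gained (gain or amp) and lost
#' (loss or homdel) at each clone, the two-way summary used in
#' genome-wide frequency plots.
#'
#' @param calls Call table.
#' @param map Optional clone map; when given, genome coordinates are
#'   attached and rows ordered by position.
#' @return Tibble: `probe_id`, `n_informative`, `frac_gain`, `frac_loss`
#'   (plus `chromosome`, `position` when `map` is supplied).
#' @export
cna_frequency <- function(calls, map = NULL) {
  cm <- as.matrix(calls[, -1, drop = FALSE])
  n_ok <- rowSums(!is.na(cm))
  out <- tibble::tibble(
    probe_id = calls$probe_id,
    n_informative = n_ok,
    frac_gain = rowSums(cm == "gain" | cm == "amp", na.rm = TRUE) / pmax(n_ok, 1),
    frac_loss = rowSums(cm == "loss" | cm == "homdel", na.rm = TRUE) / pmax(n_ok, 1)
  )
  out$frac_gain[n_ok == 0] <- NA_real_
  out$frac_loss[n_ok == 0] <- NA_real_
  if (!is.null(map)) {
    map <- with_position(map)
    out <- dplyr::left_join(
      out, map[, c("clone_id", "chromosome", "position")],
      by = c(probe_id = "clone_id"))
    out <- out[order(chrom_factor(out$chromosome), out$position), ]
  }
  out
}

#' Arm-level aberration frequencies stratified by a clinical feature
#'
#' For each level of a clinical feature, the percentage of samples in
#' that group whose arm-level call is gain or loss, per chromosome arm.
#' Samples with a missing feature value are excluded from denominators.
#'
#' @param arm_calls Output of [call_arms()].
#' @param clinical Clinical table with a `sample_id` column.
#' @param feature Name of the clinical column to stratify by.
#' @return Tibble: `chromosome`, `arm`, `group`, `n_group`, `class`,
#'   `n_aberrant`, `percent`.
#' @export
stratified_frequency <- function(arm_calls, clinical, feature) {
  if (!feature %in% setdiff(names(clinical), "sample_id")) {
    abort(sprintf("unknown clinical feature '%s'; available: %s", feature,
                  paste(setdiff(names(clinical), "sample_id"), collapse = ", ")))
  }
  grp <- clinical[, c("sample_id", feature)]
  names(grp)[2] <- "group"
  grp <- grp[!is.na(grp$group), ]
  joined <- dplyr::inner_join(arm_calls, grp, by = "sample_id")
  joined |>
    dplyr::group_by(.data$chromosome, .data$arm, .data$group) |>
    dplyr::reframe(
      n_group = sum(!is.na(.data$call)),
      class = c("gain", "loss"),
      n_aberrant = c(sum(.data$call == "gain", na.rm = TRUE),
                     sum(.data$call == "loss", na.rm = TRUE))
    ) |>
    dplyr::mutate(percent = 100 * .data$n_aberrant / pmax(.data$n_group, 1)) |>
    tibble::as_tibble()
}

#' @export
print.cna_events <- function(x, ...) {
  cat(sprintf("cna_events: %d per-sample events, %d recurrent regions\n",
              nrow(x$events), nrow(x$recurrent)))
  invisible(x)
}

#' @export
tidy.cna_events <- function(x, ...) x$events
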