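#' Configure a synthetic aCGH + expression study
#'
#' Builds the configuration object consumed by [make_clone_map()],
#' [simulate_acgh()], [simulate_expression()] and [simulate_clinical()].
#' Defaults emulate a BAC-array gastric-cancer cohort: ~2300 clones at
#' 1.5 Mb spacing across 23 chromosomes, 62 tumour samples shared between
#' the copy-number and expression matrices, per-clone Gaussian noise whose
#' standard deviation (0.075 log2 units) makes three times the average
#' normal-vs-normal SD equal the conventional 0.225 gain/loss threshold,
#' and a catalogue of planted segmental events (broad arm gains/losses,
#' focal amplicons, a focal homozygous deletion) with realistic recurrence.
#'
#' @param n_samples Number of tumour samples (shared by both matrices).
#' @param n_chromosomes,clones_per_chrom Synthetic genome dimensions.
#' @param clone_spacing_bp Distance between adjacent BAC clone starts.
#' @param centromere_fraction Fraction of each chromosome assigned to the
#'   p arm (clone index strictly below `floor(fraction * clones)` is p).
#' @param acgh_noise_sd,expr_noise_sd I.i.d. Gaussian noise SD (log2 units)
#'   for the copy-number and expression matrices.
#' @param missing_rate Fraction of entries set missing, uniformly at random.
#' @param aberrations Tibble of planted events with columns `chrom`
#'   (chromosome number), `start_index`, `end_index` (1-based inclusive
#'   clone indices within the chromosome), `shift` (log2 mean shift) and
#'   `carrier_frac` (fraction of samples carrying the event). Defaults to
#'   [default_aberrations()].
#' @param arm_event_prob Per-sample, per-arm probability of a background
#'   arm-level gain, and likewise of a loss (default 0.15 each). These
#'   background events give every genomic region sample-to-sample
#'   copy-number variance, the substrate of the genome-wide cis dosage
#'   signal.
#' @param arm_event_shift Log2 shift of a background arm event (default
#'   0.45, a single-copy change at realistic tumour-cell content).
#' @param admixture_shrink Multiplier in (0, 1] applied to all planted
#'   shifts, emulating ratio compression from admixed non-tumour cells.
#' @param n_expr_clones Number of expression (cDNA) clones.
#' @param dosage_gene_fraction Fraction of expression clones whose level is
#'   driven by local DNA copy number.
#' @param dosage_effect Slope of expression on the true local copy-number
#'   log2 ratio for dosage-driven clones.
#' @param de_independent_fraction Fraction of non-dosage clones labelled
#'   differentially expressed independently of copy number.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 62,
                       n_chromosomes = 23,
                       clones_per_chrom = 100,
                       clone_spacing_bp = 1.5e6,
                       centromere_fraction = 0.4,
                       acgh_noise_sd = 0.075,
                       expr_noise_sd = 0.3,
                       missing_rate = 0.03,
                       aberrations = NULL,
                       arm_event_prob = 0.15,
                       arm_event_shift = 0.45,
                       admixture_shrink = 1,
                       n_expr_clones = 3000,
                       dosage_gene_fraction = 0.25,
                       dosage_effect = 1,
                       de_independent_fraction = 0.1,
                       seed = 1L) {
  if (n_samples < 2 || n_chromosomes < 1 || clones_per_chrom < 1) {
    abort("counts must be positive (and n_samples >= 2)")
  }
  if (clone_spacing_bp <= 0) abort("clone_spacing_bp must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  if (dosage_gene_fraction < 0 || dosage_gene_fraction > 1) {
    abort("dosage_gene_fraction must lie in [0, 1]")
  }
  if (admixture_shrink <= 0 || admixture_shrink > 1) {
    abort("admixture_shrink must lie in (0, 1]")
  }
  if (arm_event_prob < 0 || arm_event_prob > 0.5) {
    abort("arm_event_prob must lie in [0, 0.5] (gain and loss each)")
  }
  if (is.null(aberrations)) {
    aberrations <- default_aberrations(n_chromosomes, clones_per_chrom)
  }
  ab <- tibble::as_tibble(aberrations)
  needed <- c("chrom", "start_index", "end_index", "shift", "carrier_frac")
  if (!all(needed %in% names(ab))) {
    abort(paste("aberrations needs columns:", paste(needed, collapse = ", ")))
  }
  bad <- ab$chrom < 1 | ab$chrom > n_chromosomes |
    ab$start_index < 1 | ab$end_index > clones_per_chrom |
    ab$start_index > ab$end_index
  if (any(bad)) {
    abort(sprintf("planted event out of bounds (rows %s)",
                  paste(which(bad), collapse = ", ")))
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_chromosomes = as.integer(n_chromosomes),
      clones_per_chrom = as.integer(clones_per_chrom),
      clone_spacing_bp = clone_spacing_bp,
      centromere_fraction = centromere_fraction,
      acgh_noise_sd = acgh_noise_sd,
      expr_noise_sd = expr_noise_sd,
      missing_rate = missing_rate,
      aberrations = ab,
      arm_event_prob = arm_event_prob,
      arm_event_shift = arm_event_shift,
      admixture_shrink = admixture_shrink,
      n_expr_clones = as.integer(n_expr_clones),
      dosage_gene_fraction = dosage_gene_fraction,
      dosage_effect = dosage_effect,
      de_independent_fraction = de_independent_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default catalogue of planted copy-number events
#'
#' Broad arm-level gains and losses at 30-50% recurrence, focal
#' high-level amplicons at 10-17%, and one focal homozygous deletion,
#' echoing the aberration spectrum commonly reported for gastric
#' adenocarcinoma (gains of 5p, 8q, 20q; losses of 4q, 18q, 21q; focal
#' 20q and 8q amplicons; a 9p deletion). Event indices are expressed as
#' fractions of the chromosome so the catalogue scales with genome size.
#'
#' @param n_chromosomes,clones_per_chrom Genome dimensions.
#' @return Tibble with columns `chrom`, `start_index`, `end_index`,
#'   `shift`, `carrier_frac`.
#' @export
default_aberrations <- function(n_chromosomes = 23, clones_per_chrom = 100) {
  frac <- function(f) pmax(1L, pmin(clones_per_chrom,
                                    as.integer(ceiling(f * clones_per_chrom))))
  spec <- tibble::tribble(
    ~chrom, ~f1,   ~f2,   ~shift, ~carrier_frac,
    5,      0.01,  0.38,  0.6,    0.40,   # 5p-style broad gain
    8,      0.55,  1.00,  0.6,    0.45,   # 8q-style broad gain
    8,      0.85,  0.92,  1.0,    0.10,   # focal 8q amplicon
    20,     0.45,  1.00,  0.6,    0.50,   # 20q-style broad gain
    20,     0.70,  0.78,  1.0,    0.17,   # focal 20q amplicon
    4,      0.45,  1.00, -0.6,    0.40,   # 4q-style broad loss
    18,     0.50,  1.00, -0.6,    0.35,   # 18q-style broad loss
    21,     0.50,  1.00, -0.6,    0.30,   # 21q-style broad loss
    9,      0.10,  0.16, -1.2,    0.11    # focal 9p homozygous deletion
  )
  spec <- spec[spec$chrom <= n_chromosomes, ]
  tibble::tibble(
    chrom = as.integer(spec$chrom),
    start_index = frac(spec$f1),
    end_index = frac(spec$f2),
    shift = spec$shift,
    carrier_frac = spec$carrier_frac
  )
}

#' Build the BAC clone map of a synthetic genome
#'
#' Clones are evenly spaced at `clone_spacing_bp` per chromosome, with
#' 0-based half-open coordinates, and split into p and q arms at a fixed
#' centromere fraction.
#'
#' @param config A [sim_config()].
#' @return Clone-map tibble: `clone_id`, `chromosome`, `arm`, `start`,
#'   `end`, `position` (midpoint), sorted by (chromosome, start).
#' @export
make_clone_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$clones_per_chrom
  sp <- config$clone_spacing_bp
  n_p <- floor(config$centromere_fraction * k)
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    idx <- seq_len(k) - 1L
    tibble::tibble(
      clone_id = sprintf("bac_%02d_%04d", ch, idx + 1L),
      chromosome = paste0("chr", ch),
      arm = ifelse(idx < n_p, "p", "q"),
      start = idx * sp,
      end = idx * sp + 2e5,   # nominal 200 kb BAC insert
      position = idx * sp + 1e5
    )
  })
}

# Per-clone per-sample matrix of true mean shifts, plus carrier bookkeeping.
planted_truth_means <- function(map, config) {
  n <- nrow(map)
  m <- matrix(0, n, config$n_samples,
              dimnames = list(map$clone_id, sim_sample_ids(config)))
  ab <- config$aberrations
  carriers <- vector("list", nrow(ab))
  withr::with_seed(derive_seed(config$seed, "carriers"), {
    for (e in seq_len(nrow(ab))) {
      n_car <- max(1L, round(ab$carrier_frac[e] * config$n_samples))
      car <- sort(sample.int(config$n_samples, n_car))
      carriers[[e]] <- car
      chrom <- paste0("chr", ab$chrom[e])
      rows <- which(map$chromosome == chrom)
      rows <- rows[seq(ab$start_index[e], ab$end_index[e])]
      m[rows, car] <- m[rows, car] + ab$shift[e] * config$admixture_shrink
    }
    # background arm-level gains/losses: every arm varies across samples
    if (config$arm_event_prob > 0) {
      arm_key <- paste(map$chromosome, map$arm)
      for (a in unique(arm_key)) {
        rows <- which(arm_key == a)
        u <- runif(config$n_samples)
        shift <- ifelse(u < config$arm_event_prob, config$arm_event_shift,
                 ifelse(u < 2 * config$arm_event_prob,
                        -config$arm_event_shift, 0))
        shift <- shift * config$admixture_shrink
        hit <- which(shift != 0)
        if (length(hit)) {
          m[rows, hit] <- m[rows, hit] +
            matrix(shift[hit], length(rows), length(hit), byrow = TRUE)
        }
      }
    }
  })
  list(means = m, carriers = carriers)
}

sim_sample_ids <- function(config) sprintf("s%02d", seq_len(config$n_samples))

# Breakpoints: per sample/chromosome, the 1-based within-chromosome index of
# the first clone of each new true segment (strictly increasing).
truth_breakpoints <- function(map, means) {
  out <- purrr::map_dfr(colnames(means), function(s) {
    purrr::map_dfr(unique(map$chromosome), function(ch) {
      rows <- which(map$chromosome == ch)
      v <- means[rows, s]
      bp <- which(diff(v) != 0) + 1L
      if (!length(bp)) return(NULL)
      tibble::tibble(sample_id = s, chromosome = ch, index = bp)
    })
  })
  if (!nrow(out)) {
    out <- tibble::tibble(sample_id = character(), chromosome = character(),
                          index = integer())
  }
  out
}

#' Simulate an aCGH log2-ratio matrix with known ground truth
#'
#' Each sample is baseline 0 plus the planted mean shifts of the events it
#' carries, plus i.i.d. Gaussian noise; entries are then set missing at
#' `missing_rate`. The ground-truth channel carries the noiseless mean
#' matrix, the aberration calls implied by thresholding it, and the true
#' breakpoints, enabling parameter-recovery tests downstream.
#'
#' @param map Clone map from [make_clone_map()].
#' @param config A [sim_config()].
#' @return List of class `acgh_sim` with elements `ratios` (ratio table),
#'   `truth` (list: `true_means` matrix, `true_calls` ratio-table of
#'   ordinal calls, `breakpoints` tibble, `carriers` list) and `map`.
#' @export
simulate_acgh <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_clone_map(map)
  pt <- planted_truth_means(map, config)
  means <- pt$means
  n <- length(means)
  vals <- withr::with_seed(derive_seed(config$seed, "acgh"), {
    x <- means + rnorm(n, sd = config$acgh_noise_sd)
    if (config$missing_rate > 0) {
      x[runif(n) < config$missing_rate] <- NA_real_
    }
    x
  })
  true_calls <- call_clones(ratio_table(means), cna_thresholds())
  structure(
    list(
      ratios = ratio_table(vals),
      truth = list(
        true_means = means,
        true_calls = true_calls,
        breakpoints = truth_breakpoints(map, means),
        carriers = pt$carriers
      ),
      map = map
    ),
    class = "acgh_sim"
  )
}

#' Place expression (cDNA) clones on the synthetic genome
#'
#' Clones are scattered uniformly over the genome covered by the BAC map;
#' runs of adjacent clones can share a gene symbol, mimicking genes
#' represented by several array clones.
#'
#' @param map BAC clone map (defines the genome extent).
#' @param config A [sim_config()].
#' @return Clone-map tibble for expression clones (`clone_id`,
#'   `chromosome`, `arm`, `start`, `end`, `position`, `gene_symbol`).
#' @export
make_expression_map <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_expr_clones
  chrom_len <- config$clones_per_chrom * config$clone_spacing_bp
  withr::with_seed(derive_seed(config$seed, "expr_map"), {
    ch <- sort(sample.int(config$n_chromosomes, n, replace = TRUE))
    pos <- floor(runif(n, 0, chrom_len - 1e3))
  })
  ord <- order(ch, pos)
  ch <- ch[ord]; pos <- pos[ord]
  n_p <- floor(config$centromere_fraction * config$clones_per_chrom)
  centro_bp <- n_p * config$clone_spacing_bp
  # ~8% of genes contributed by two adjacent clones
  gene_idx <- cumsum(c(1L, as.integer(seq_len(n - 1) %% 13 != 0)))
  tibble::tibble(
    clone_id = sprintf("cdna_%05d", seq_len(n)),
    chromosome = paste0("chr", ch),
    arm = ifelse(pos < centro_bp, "p", "q"),
    start = pos,
    end = pos + 1e3,
    position = pos + 500,
    gene_symbol = sprintf("G%05d", gene_idx)
  )
}

#' Simulate expression coupled to copy number through a dosage effect
#'
#' A seeded subset of expression clones is "dosage-driven": its level is
#' `dosage_effect` times the true local copy-number log2 ratio of the
#' nearest BAC clone (within 1 Mb), plus Gaussian noise. All other
#' clones are pure noise. Differential-expression labels are `up` for
#' dosage clones under recurrent gain, `down` under recurrent loss
#' (regions whose mean shift across samples exceeds 0.05 log2 in
#' magnitude), plus a configurable fraction of copy-number-independent
#' DE clones.
#'
#' @param expr_map Expression clone map from [make_expression_map()].
#' @param acgh An `acgh_sim` (or its `truth` element plus `map`).
#' @param config A [sim_config()].
#' @return List of class `expr_sim`: `ratios` (ratio table), `truth`
#'   (tibble: `clone_id`, `gene_symbol`, `source_bac`, `distance_bp`,
#'   `dosage`, `de_label`), `map`.
#' @export
simulate_expression <- function(expr_map, acgh, config) {
  stopifnot(inherits(config, "sim_config"), inherits(acgh, "acgh_sim"))
  map <- with_position(acgh$map)
  expr_map <- with_position(expr_map)
  means <- acgh$truth$true_means

  nearest <- nearest_bac(expr_map, map)
  eligible <- which(nearest$distance_bp <= 1e6)

  n <- nrow(expr_map)
  n_dosage <- round(config$dosage_gene_fraction * n)
  if (n_dosage > length(eligible)) {
    warn(sprintf(
      "only %d expression clones lie within 1 Mb of a BAC; using all of them as dosage clones (requested %d)",
      length(eligible), n_dosage))
    n_dosage <- length(eligible)
  }

  res <- withr::with_seed(derive_seed(config$seed, "expr"), {
    dosage_rows <- sort(sample(eligible, n_dosage))
    e <- matrix(rnorm(n * config$n_samples, sd = config$expr_noise_sd),
                n, config$n_samples,
                dimnames = list(expr_map$clone_id, colnames(means)))
    e[dosage_rows, ] <- e[dosage_rows, ] +
      config$dosage_effect * means[nearest$source_bac[dosage_rows], ,
                                   drop = FALSE]
    if (config$missing_rate > 0) {
      e[runif(length(e)) < config$missing_rate] <- NA_real_
    }
    # DE labels: only dosage clones under a *recurrently directional*
    # region (|mean shift across samples| > 0.05 log2) are copy-number DE
    de <- rep(NA_character_, n)
    net <- rowMeans(means)[nearest$source_bac]
    recur <- abs(net[dosage_rows]) > 0.05
    de[dosage_rows[recur]] <- ifelse(net[dosage_rows[recur]] > 0, "up", "down")
    free <- setdiff(seq_len(n), dosage_rows)
    n_free_de <- round(config$de_independent_fraction * n)
    free_de <- sort(sample(free, min(n_free_de, length(free))))
    de[free_de] <- sample(c("up", "down"), length(free_de), replace = TRUE)
    list(e = e, dosage_rows = dosage_rows, de = de)
  })

  truth <- tibble::tibble(
    clone_id = expr_map$clone_id,
    gene_symbol = expr_map$gene_symbol,
    source_bac = map$clone_id[nearest$source_bac],
    distance_bp = nearest$distance_bp,
    dosage = seq_len(n) %in% res$dosage_rows,
    de_label = res$de
  )
  structure(
    list(ratios = ratio_table(res$e), truth = truth, map = expr_map),
    class = "expr_sim"
  )
}

# For each expression clone, the row index in `map` of the nearest BAC
# (same chromosome, midpoint distance).
nearest_bac <- function(expr_map, map) {
  idx <- integer(nrow(expr_map))
  dist <- numeric(nrow(expr_map))
  for (ch in unique(expr_map$chromosome)) {
    e_rows <- which(expr_map$chromosome == ch)
    b_rows <- which(map$chromosome == ch)
    if (!length(b_rows)) {
      idx[e_rows] <- NA_integer_; dist[e_rows] <- NA_real_
      next
    }
    for (i in e_rows) {
      d <- abs(map$position[b_rows] - expr_map$position[i])
      j <- which.min(d)
      idx[i] <- b_rows[j]
      dist[i] <- d[j]
    }
  }
  list(source_bac = idx, distance_bp = dist)
}

#' Simulate a clinical annotation table
#'
#' Clinical labels are arbitrary grouping factors for stratified-frequency
#' analyses; they carry no biological coupling to the planted events.
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `stage`, `lauren_type`, `site`,
#'   `differentiation`, `hpylori`, `ebv`; a small fraction of entries is
#'   missing.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  withr::with_seed(derive_seed(config$seed, "clinical"), {
    tbl <- tibble::tibble(
      sample_id = sim_sample_ids(config),
      stage = sample(1:4, n, TRUE, prob = c(0.2, 0.25, 0.3, 0.25)),
      lauren_type = sample(c("intestinal", "diffuse", "mixed", "indeterminate"),
                           n, TRUE, prob = c(0.5, 0.3, 0.15, 0.05)),
      site = sample(c("antrum", "body", "cardia"), n, TRUE,
                    prob = c(0.5, 0.35, 0.15)),
      differentiation = sample(c("well_moderate", "poor"), n, TRUE,
                               prob = c(0.45, 0.55)),
      hpylori = sample(c("pos", "neg"), n, TRUE, prob = c(0.55, 0.45)),
      ebv = sample(c("pos", "neg"), n, TRUE, prob = c(0.08, 0.92))
    )
    for (col in setdiff(names(tbl), "sample_id")) {
      miss <- runif(n) < 0.02
      tbl[[col]][miss] <- NA
    }
    tbl
  })
}

#' Simulate normal-vs-normal reference hybridizations
#'
#' Pure-noise profiles used to derive gain/loss thresholds as a multiple
#' of the average per-profile SD.
#'
#' @param map Clone map.
#' @param config A [sim_config()]; `acgh_noise_sd` is the true noise SD.
#' @param n_profiles Number of reference hybridizations.
#' @return Ratio table of `n_profiles` normal-vs-normal profiles.
#' @export
simulate_normals <- function(map, config, n_profiles = 3) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "normals"), {
    m <- matrix(rnorm(nrow(map) * n_profiles, sd = config$acgh_noise_sd),
                nrow(map), n_profiles,
                dimnames = list(map$clone_id,
                                sprintf("normal%02d", seq_len(n_profiles))))
    ratio_table(m)
  })
}

#' Simulate a complete matched study
#'
#' Convenience wrapper running [make_clone_map()], [simulate_acgh()],
#' [make_expression_map()], [simulate_expression()], [simulate_clinical()]
#' and [simulate_normals()], plus the differential-expression list implied
#' by the truth channel.
#'
#' @param config A [sim_config()].
#' @return List of class `study_sim` with elements `map`, `acgh`,
#'   `expr_map`, `expr`, `clinical`, `normals`, `de_list`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  map <- make_clone_map(config)
  acgh <- simulate_acgh(map, config)
  expr_map <- make_expression_map(map, config)
  expr <- simulate_expression(expr_map, acgh, config)
  de <- expr$truth[!is.na(expr$truth$de_label),
                   c("clone_id", "gene_symbol", "de_label")]
  names(de) <- c("expr_clone_id", "gene_symbol", "direction")
  structure(
    list(
      map = map, acgh = acgh, expr_map = expr_map, expr = expr,
      clinical = simulate_clinical(config),
      normals = simulate_normals(map, config),
      de_list = de,
      config = config
    ),
    class = "study_sim"
  )
}
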