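test_that("threshold derivation is 3x the average normal-vs-normal SD", {
  # three profiles with per-profile SDs 0.07, 0.075, 0.08
  mk <- function(sd_target, n = 2001) {
    v <- scale(seq_len(n))[, 1]
    v * sd_target / sd(v)
  }
  normals <- tibble::tibble(probe_id = sprintf("p%04d", 1:2001),
                            n1 = mk(0.07), n2 = mk(0.075), n3 = mk(0.08))
  th <- derive_thresholds(normals)
  expect_equal(th$gain, 0.225, tolerance = 1e-12)
  expect_equal(th$loss, -0.225, tolerance = 1e-12)
  expect_equal(th$amp, 0.8)
  expect_equal(th$homdel, -0.7)

  const <- tibble::tibble(probe_id = c("a", "b", "c"), n1 = c(1, 1, 1))
  expect_error(derive_thresholds(const), "degenerate reference")
  expect_error(derive_thresholds(tibble::tibble(probe_id = character())),
               "at least one")
})

test_that("clone calls follow the strict-inequality threshold rules", {
  rt <- tibble::tibble(probe_id = sprintf("p%d", 1:6),
                       s1 = c(0.30, 0.85, -0.75, 0.225, 0, NA),
                       s2 = c(-0.30, -0.225, 0.8, -0.7, 2, -2))
  calls <- call_clones(rt)
  expect_equal(calls$s1, c("gain", "amp", "homdel", "neutral", "neutral", NA))
  expect_equal(calls$s2, c("loss", "neutral", "gain", "loss", "amp", "homdel"))
})

test_that("increasing a value never moves its call down the ordinal scale", {
  set.seed(31)
  v <- sort(runif(200, -1.5, 1.5))
  rt <- tibble::tibble(probe_id = sprintf("p%03d", seq_along(v)),
                       s1 = v, s2 = v)
  codes <- match(call_clones(rt)$s1,
                 c("homdel", "loss", "neutral", "gain", "amp"))
  expect_true(all(diff(codes) >= 0))
})

test_that("arm calls use the median with strict thresholds", {
  map <- tibble::tibble(
    clone_id = sprintf("c%d", 1:12), chromosome = "chr1",
    arm = rep(c("p", "q"), each = 6),
    start = (0:11) * 1e6, end = (0:11) * 1e6 + 1e5)
  vals <- cbind(s1 = c(0.3, 0.3, 0.3, 0.1, 0.3, 0.3,
                       0.3, 0.1, -0.1, -0.3, -0.1, 0.1),
                s2 = c(-0.3, -0.3, -0.25, -0.3, -0.25, -0.3,
                       rep(NA, 6)))
  rt <- tibble::as_tibble(as.data.frame(vals)) |>
    dplyr::mutate(probe_id = map$clone_id, .before = 1)
  ac <- call_arms(rt, map)
  get <- function(a, s) ac$call[ac$arm == a & ac$sample_id == s]
  expect_equal(get("p", "s1"), "gain")     # median 0.3
  expect_equal(get("q", "s1"), "neutral")  # median 0.0
  expect_equal(get("p", "s2"), "loss")     # median -0.3
  expect_true(is.na(get("q", "s2")))       # no informative clones
})

test_that("events are maximal runs; amp events sit inside gain events", {
  map <- tibble::tibble(
    clone_id = sprintf("c%d", 1:5), chromosome = "chr1", arm = "q",
    start = (0:4) * 1e6, end = (0:4) * 1e6 + 1e5)
  calls <- tibble::tibble(probe_id = map$clone_id,
                          s1 = c("neutral", "gain", "gain", "neutral", "gain"),
                          s2 = c("gain", "amp", "gain", "neutral", "neutral"))
  ev <- catalogue_events(calls, map)$events
  expect_equal(sum(ev$sample_id == "s1" & ev$class == "gain"), 2)
  # amp-in-gain: s2 has one 3-clone gain event and one 1-clone amp event
  s2gain <- ev[ev$sample_id == "s2" & ev$class == "gain", ]
  expect_equal(s2gain$n_probes, 3L)
  s2amp <- ev[ev$sample_id == "s2" & ev$class == "amp", ]
  expect_equal(s2amp$n_probes, 1L)
  expect_gte(s2amp$start, s2gain$start)
  expect_lte(s2amp$end, s2gain$end)

  all_neutral <- calls
  all_neutral$s1 <- all_neutral$s2 <- "neutral"
  expect_equal(nrow(catalogue_events(all_neutral, map)$events), 0)
})

test_that("per-sample event footprints equal per-sample call counts", {
  cfg <- tiny_config()
  st <- simulate_study(cfg)
  calls <- call_clones(st$acgh$ratios)
  ev <- catalogue_events(calls, st$map)$events
  cm <- as.matrix(calls[, -1])
  for (s in colnames(cm)) {
    for (cl in c("amp", "homdel")) {
      expect_equal(sum(ev$n_probes[ev$sample_id == s & ev$class == cl]),
                   sum(cm[, s] == cl, na.rm = TRUE))
    }
    expect_equal(sum(ev$n_probes[ev$sample_id == s & ev$class == "gain"]),
                 sum(cm[, s] %in% c("gain", "amp"), na.rm = TRUE))
    expect_equal(sum(ev$n_probes[ev$sample_id == s & ev$class == "loss"]),
                 sum(cm[, s] %in% c("loss", "homdel"), na.rm = TRUE))
  }
})

test_that("a planted recurrent amplicon is reported with its carrier count", {
  cfg <- sim_config(n_samples = 72, n_chromosomes = 4, clones_per_chrom = 50,
                    arm_event_prob = 0, missing_rate = 0, seed = 3,
                    aberrations = data.frame(
                      chrom = 3, start_index = 20, end_index = 26,
                      shift = 1.0, carrier_frac = 12 / 72))
  st <- simulate_study(cfg)
  calls <- call_clones(st$acgh$ratios)
  rec <- catalogue_events(calls, st$map)$recurrent
  top <- rec[rec$class == "amp", ]
  top <- top[which.max(top$n_samples), ]
  expect_equal(top$n_samples, 12L)   # 12/72-style recurrence
  expect_equal(top$chromosome, "chr3")
})

test_that("gain/loss frequencies count non-missing samples", {
  calls <- tibble::tibble(
    probe_id = "p1",
    !!!setNames(as.list(c(rep("gain", 4), rep("neutral", 5), NA)),
                sprintf("s%02d", 1:10)))
  f <- cna_frequency(calls)
  expect_equal(f$frac_gain, 4 / 9)
  expect_equal(f$n_informative, 9)
})

test_that("stratified arm frequencies recover group percentages", {
  # 19p-loss-style contrast: 4/20 vs 3/88
  samples <- sprintf("s%03d", 1:108)
  arm_calls <- tibble::tibble(
    chromosome = "chr19", arm = "p", sample_id = samples,
    median_log2 = 0,
    call = c(rep("loss", 4), rep("neutral", 16),   # early-stage group
             rep("loss", 3), rep("neutral", 85)))  # late-stage group
  clinical <- tibble::tibble(sample_id = samples,
                             stage_group = rep(c("early", "late"), c(20, 88)))
  sf <- stratified_frequency(arm_calls, clinical, "stage_group")
  loss <- sf[sf$class == "loss", ]
  expect_equal(loss$percent[loss$group == "early"], 20)
  expect_equal(loss$percent[loss$group == "late"], 3.41, tolerance = 0.005)
  expect_error(stratified_frequency(arm_calls, clinical, "nope"),
               "stage_group")
})

test_that("noiseless simulated ratios reproduce the planted calls exactly", {
  cfg <- tiny_config(acgh_noise_sd = 0, missing_rate = 0)
  st <- simulate_study(cfg)
  expect_identical(call_clones(st$acgh$ratios), st$acgh$truth$true_calls)
})
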