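imbalance_fixture <- function() {
  # one BAC, 14 samples with known call composition per case
  mk_calls <- function(calls) {
    tibble::tibble(probe_id = "bacA",
                   !!!setNames(as.list(calls), sprintf("s%02d", seq_along(calls))))
  }
  list(
    gain10_loss4 = mk_calls(c(rep("gain", 8), rep("amp", 2), rep("loss", 4))),
    gain5_loss1 = mk_calls(c(rep("gain", 5), "loss", rep("neutral", 8))),
    gain2_loss8 = mk_calls(c(rep("gain", 2), rep("loss", 6),
                             rep("homdel", 2), rep("neutral", 4)))
  )
}

test_that("gain/loss imbalance counts amp as gain and homdel as loss", {
  fx <- imbalance_fixture()
  rec <- tibble::tibble(expr_clone_id = "e1", mapped_bac_id = "bacA")
  r1 <- gain_loss_imbalance(rec, fx$gain10_loss4)
  expect_equal(c(r1$n_gain, r1$n_loss, r1$imbalance), c(10L, 4L, 6L))
  r2 <- gain_loss_imbalance(rec, fx$gain5_loss1)
  expect_equal(r2$imbalance, 4L)
  r3 <- gain_loss_imbalance(rec, fx$gain2_loss8)
  expect_equal(r3$imbalance, -6L)
  expect_error(
    gain_loss_imbalance(tibble::tibble(expr_clone_id = "e", mapped_bac_id = "zz"),
                        fx$gain10_loss4),
    "absent")
})

test_that("nomination requires imbalance concordant with DE direction", {
  fx <- imbalance_fixture()
  rec <- tibble::tibble(
    expr_clone_id = c("e1", "e2", "e3"),
    gene_symbol = c("GA", "GB", "GC"),
    mapped_bac_id = "bacA", r = c(0.6, 0.5, 0.4), q = 0.001,
    unmapped = FALSE)
  de <- tibble::tibble(expr_clone_id = c("e1", "e2"),
                       direction = c("up", "down"))
  nom <- suppressMessages(
    nominate_candidates(rec, fx$gain10_loss4, de))
  # e1: imbalance +6, up -> oncogene; e2: +6 but down -> discordant;
  # e3: not in the DE list -> out
  expect_equal(nom$candidates$expr_clone_id, "e1")
  expect_equal(nom$candidates$class, "oncogene")
  expect_equal(nom$discordant$expr_clone_id, "e2")

  nom2 <- nominate_candidates(rec[1, ], fx$gain5_loss1, de)
  expect_equal(nrow(nom2$candidates), 0)  # |imbalance| = 4 < 5

  down <- nominate_candidates(
    tibble::tibble(expr_clone_id = "e2", gene_symbol = "GB",
                   mapped_bac_id = "bacA", r = 0.5, q = 0.001,
                   unmapped = FALSE),
    fx$gain2_loss8, de)
  expect_equal(down$candidates$class, "tsg")

  expect_error(nominate_candidates(rec, fx$gain10_loss4,
                                   tibble::tibble(expr_clone_id = "e1")),
               "direction")
})

test_that("nomination equals an independent application of all criteria", {
  cfg <- tiny_config(n_samples = 20, dosage_gene_fraction = 0.3)
  st <- simulate_study(cfg)
  seg <- segment_cna(st$acgh$ratios, st$map, n_perm = 200, seed = 2)
  sm <- smoothed_values(seg)
  rec <- suppressMessages(map_expression_to_bac(
    st$expr$ratios, st$expr_map, sm, st$map))
  rec <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 200, seed = 3)
  rec$q <- bh_adjust(rec$p_perm)
  sel <- select_correlated(rec)
  calls <- call_clones(st$acgh$ratios)
  nom <- suppressMessages(nominate_candidates(sel, calls, st$de_list))

  # brute force over every record, sharing only the intermediates
  cm <- as.matrix(calls[, -1]); rownames(cm) <- calls$probe_id
  expected <- character()
  for (i in seq_len(nrow(rec))) {
    if (rec$unmapped[i]) next
    if (!(rec$r[i] > 0.29 && !is.na(rec$q[i]) && rec$q[i] < 0.01)) next
    v <- cm[rec$mapped_bac_id[i], ]
    imb <- sum(v %in% c("gain", "amp"), na.rm = TRUE) -
      sum(v %in% c("loss", "homdel"), na.rm = TRUE)
    j <- match(rec$expr_clone_id[i], st$de_list$expr_clone_id)
    if (is.na(j)) next
    dir <- st$de_list$direction[j]
    if ((imb >= 5 && dir == "up") || (imb <= -5 && dir == "down")) {
      expected <- c(expected, rec$expr_clone_id[i])
    }
  }
  expect_setequal(nom$candidates$expr_clone_id, expected)
  # soundness, record by record
  expect_true(all(nom$candidates$r > 0.29 & nom$candidates$q < 0.01 &
                    abs(nom$candidates$imbalance) >= 5))
  expect_false(any(nom$candidates$expr_clone_id %in%
                     nom$discordant$expr_clone_id))
})

test_that("clustering merges identical samples first and splits blocks", {
  set.seed(13)
  n_clone <- 20
  a <- matrix(rnorm(n_clone * 3, sd = 0.1), n_clone) + 1
  b <- matrix(rnorm(n_clone * 3, sd = 0.1), n_clone) - 1
  m <- cbind(a, b)
  m[, 2] <- m[, 1]  # two identical samples
  rownames(m) <- sprintf("e%02d", 1:n_clone)
  colnames(m) <- sprintf("s%d", 1:6)
  # block structure: clones up in group A, down in group B and vice versa
  m[11:20, ] <- -m[11:20, ]
  expr <- tibble::as_tibble(as.data.frame(m), rownames = "probe_id")
  cl <- cluster_candidates(expr)
  expect_equal(cl$sample_hclust$height[1], 0, tolerance = 1e-12)
  top <- cutree(cl$sample_hclust, 2)
  expect_equal(length(unique(top[c("s1", "s2", "s3")])), 1)
  expect_equal(length(unique(top[c("s4", "s5", "s6")])), 1)
  expect_false(top[["s1"]] == top[["s4"]])
})

test_that("single-candidate clustering still orders samples; constants dropped", {
  set.seed(14)
  m <- matrix(rnorm(8), 1, dimnames = list("e1", sprintf("s%d", 1:8)))
  expr <- tibble::as_tibble(as.data.frame(m), rownames = "probe_id")
  cl <- cluster_candidates(expr)
  expect_null(cl$clone_hclust)
  expect_equal(sort(cl$sample_order), sort(colnames(m)))

  m2 <- rbind(m, e2 = rep(1, 8))
  expr2 <- tibble::as_tibble(as.data.frame(m2), rownames = "probe_id")
  expect_warning(cl2 <- cluster_candidates(expr2), "constant")
  expect_equal(rownames(cl2$matrix), "e1")
})

test_that("clustering export writes the ordered matrix and orders", {
  dir <- withr::local_tempdir()
  set.seed(15)
  m <- matrix(rnorm(40), 5, dimnames = list(sprintf("e%d", 1:5),
                                            sprintf("s%d", 1:8)))
  expr <- tibble::as_tibble(as.data.frame(m), rownames = "probe_id")
  cl <- cluster_candidates(expr)
  paths <- write_clustering(cl, file.path(dir, "clust"))
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(paths["matrix"], show_col_types = FALSE)
  expect_equal(back$probe_id, cl$clone_order)
  expect_equal(readLines(paths["samples"]), cl$sample_order)
})
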