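test_that("each expression clone maps to the best-correlated BAC within 1 Mb", {
  n <- 20
  set.seed(8)
  e <- rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  map <- tibble::tibble(
    clone_id = c("bacA", "bacB", "bacC"),
    chromosome = "chr1", arm = "q",
    start = c(0.9e6, 1.5e6, 5.0e6), end = c(1.1e6, 1.7e6, 5.2e6))
  cn <- rbind(bacA = e + c(rep(0, 10), rep(1.5, 10)),  # correlated, weaker
              bacB = e,                                # perfectly correlated
              bacC = rnorm(n))
  colnames(cn) <- samples
  smoothed <- tibble::as_tibble(as.data.frame(cn), rownames = "probe_id")
  emap <- tibble::tibble(
    clone_id = c("expr1", "expr2"),
    chromosome = "chr1", arm = "q",
    start = c(1.2e6, 3.0e6), end = c(1.201e6, 3.001e6))
  expr <- tibble::as_tibble(as.data.frame(
    rbind(expr1 = e, expr2 = rnorm(n))), rownames = "probe_id")
  names(expr)[-1] <- samples

  rec <- suppressMessages(
    map_expression_to_bac(expr, emap, smoothed, map, min_n = 5))
  # expr1: bacB has r = 1 > bacA; both within 1 Mb of 1.2005 Mb
  expect_equal(rec$mapped_bac_id[1], "bacB")
  expect_equal(rec$r[1], 1, tolerance = 1e-12)
  # expr2: nearest BAC midpoint (bacB at 1.6 Mb) is 1.4 Mb away -> unmapped
  expect_true(rec$unmapped[2])
})

test_that("exact correlation ties are broken by distance then id", {
  n <- 12
  e <- seq_len(n) / n
  samples <- sprintf("s%02d", 1:n)
  map <- tibble::tibble(clone_id = c("bacN", "bacF"), chromosome = "chr1",
                        arm = "q", start = c(1.25e6, 1.85e6),
                        end = c(1.35e6, 1.95e6))
  cn <- rbind(bacN = e, bacF = e)  # identical values, identical r
  colnames(cn) <- samples
  smoothed <- tibble::as_tibble(as.data.frame(cn), rownames = "probe_id")
  emap <- tibble::tibble(clone_id = "expr1", chromosome = "chr1", arm = "q",
                         start = 1.0e6, end = 1.0e6 + 1)
  expr <- tibble::as_tibble(as.data.frame(rbind(expr1 = e)),
                            rownames = "probe_id")
  names(expr)[-1] <- samples
  rec <- map_expression_to_bac(expr, emap, smoothed, map, min_n = 5)
  expect_equal(rec$mapped_bac_id, "bacN")  # 0.3 Mb vs 0.9 Mb
})

test_that("BH adjustment matches hand examples and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.5, NA, 0.1)), c(0.5, NA, 0.2))
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")

  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("permutation p-values are deterministic and shared across records", {
  cfg <- tiny_config(dosage_gene_fraction = 0.3)
  st <- simulate_study(cfg)
  seg <- segment_cna(st$acgh$ratios, st$map, n_perm = 200, seed = 2)
  sm <- smoothed_values(seg)
  rec <- suppressMessages(map_expression_to_bac(
    st$expr$ratios, st$expr_map, sm, st$map))
  p1 <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 200, seed = 5)
  p2 <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 200, seed = 5)
  expect_identical(p1$p_perm, p2$p_perm)
  p3 <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 200, seed = 6)
  expect_false(identical(p1$p_perm, p3$p_perm))
  # a perfectly dosage-driven record should beat every shuffle
  best <- which.max(p1$r)
  expect_equal(p1$p_perm[best], 0)
  # pseudo-count variant is (k+1)/(B+1)
  p4 <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 200, seed = 5,
                            pseudo_count = TRUE)
  expect_equal(p4$p_perm[best], 1 / 201)
})

test_that("two identical expression clones get identical p-values (shared shuffles)", {
  n <- 30
  set.seed(9)
  e <- rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  map <- tibble::tibble(clone_id = "bacA", chromosome = "chr1", arm = "q",
                        start = 1e6, end = 1.2e6)
  smoothed <- tibble::as_tibble(as.data.frame(rbind(bacA = rnorm(n))),
                                rownames = "probe_id")
  names(smoothed)[-1] <- samples
  emap <- tibble::tibble(clone_id = c("e1", "e2"), chromosome = "chr1",
                         arm = "q", start = c(1.0e6, 1.05e6),
                         end = c(1.0e6, 1.05e6) + 1)
  expr <- tibble::as_tibble(as.data.frame(rbind(e1 = e, e2 = e)),
                            rownames = "probe_id")
  names(expr)[-1] <- samples
  rec <- map_expression_to_bac(expr, emap, smoothed, map, min_n = 5)
  rec <- permutation_pvalues(rec, expr, smoothed, n_perm = 300, seed = 1,
                             min_n = 5)
  expect_equal(rec$p_perm[1], rec$p_perm[2])
})

test_that("a constant expression clone is unmapped (undefined correlation)", {
  n <- 15
  samples <- sprintf("s%02d", 1:n)
  map <- tibble::tibble(clone_id = "bacA", chromosome = "chr1", arm = "q",
                        start = 1e6, end = 1.2e6)
  set.seed(2)
  smoothed <- tibble::as_tibble(as.data.frame(rbind(bacA = rnorm(n))),
                                rownames = "probe_id")
  names(smoothed)[-1] <- samples
  emap <- tibble::tibble(clone_id = "e1", chromosome = "chr1", arm = "q",
                         start = 1e6, end = 1e6 + 1)
  expr <- tibble::as_tibble(as.data.frame(rbind(e1 = rep(2, n))),
                            rownames = "probe_id")
  names(expr)[-1] <- samples
  rec <- suppressMessages(
    map_expression_to_bac(expr, emap, smoothed, map, min_n = 5))
  expect_true(rec$unmapped[1])
})

test_that("selection applies r > 0.29 and q < 0.01 and reports achieved FDR", {
  rec <- tibble::tibble(
    expr_clone_id = c("a", "b", "c", "d"),
    r = c(0.30, 0.28, 0.50, 0.35),
    p_perm = c(0.001, 0.0005, 0.002, 0.2),
    unmapped = FALSE)
  rec$q <- bh_adjust(rec$p_perm)
  sel <- select_correlated(rec)
  expect_setequal(sel$expr_clone_id, c("a", "c"))  # b fails r, d fails q
  expect_equal(attr(sel, "achieved_fdr"), max(sel$q))
  empty <- select_correlated(rec[rec$r > 2, ])
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "achieved_fdr")))
})

test_that("an arm shorter than one bin forms a single bin", {
  n <- 10
  samples <- sprintf("s%02d", 1:n)
  set.seed(4)
  map <- tibble::tibble(clone_id = c("b1", "b2"), chromosome = "chr1",
                        arm = "q", start = c(0, 5e6), end = c(2e5, 5.2e6))
  smoothed <- tibble::as_tibble(
    as.data.frame(matrix(rnorm(2 * n), 2, dimnames = list(map$clone_id, samples))),
    rownames = "probe_id")
  emap <- tibble::tibble(clone_id = c("e1", "e2"), chromosome = "chr1",
                         arm = "q", start = c(1e6, 6e6), end = c(1e6, 6e6) + 1)
  expr <- tibble::as_tibble(
    as.data.frame(matrix(rnorm(2 * n), 2, dimnames = list(emap$clone_id, samples))),
    rownames = "probe_id")
  b <- binned_diagonal_analysis(expr, emap, smoothed, map, bin_bp = 2e7)
  expect_equal(unique(b$grid$cn_bin), "chr1 q:0")
  expect_equal(unique(b$grid$expr_bin), "chr1 q:0")
  expect_true(all(b$grid$diagonal))
})

test_that("with no dosage effect almost nothing passes the selection", {
  frac <- numeric(5)
  for (r in 1:5) {
    cfg <- tiny_config(n_samples = 30, n_expr_clones = 200,
                       dosage_effect = 0, seed = 900 + r)
    st <- simulate_study(cfg)
    seg <- segment_cna(st$acgh$ratios, st$map, n_perm = 500, seed = r)
    sm <- smoothed_values(seg)
    rec <- suppressMessages(
      map_expression_to_bac(st$expr$ratios, st$expr_map, sm, st$map))
    rec <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 500,
                               seed = 20 + r)
    rec$q <- bh_adjust(rec$p_perm)
    sel <- select_correlated(rec)
    frac[r] <- nrow(sel) / sum(!rec$unmapped)
  }
  expect_lte(mean(frac), 0.02)
})

test_that("permutation re-selection of the best BAC is supported and conservative", {
  cfg <- tiny_config(dosage_gene_fraction = 0.3)
  st <- simulate_study(cfg)
  seg <- segment_cna(st$acgh$ratios, st$map, n_perm = 200, seed = 2)
  sm <- smoothed_values(seg)
  rec <- suppressMessages(map_expression_to_bac(
    st$expr$ratios, st$expr_map, sm, st$map))
  p_fix <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 300, seed = 5)
  p_res <- permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 300, seed = 5,
                               reselect = TRUE)
  expect_true(all(p_res$p_perm >= 0 & p_res$p_perm <= 1, na.rm = TRUE))
  # re-selecting under each shuffle can only raise the permuted maximum
  expect_gte(mean(p_res$p_perm, na.rm = TRUE),
             mean(p_fix$p_perm, na.rm = TRUE))
  expect_identical(
    p_res$p_perm,
    permutation_pvalues(rec, st$expr$ratios, sm, n_perm = 300, seed = 5,
                        reselect = TRUE)$p_perm)
})
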