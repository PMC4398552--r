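make_profile_fixture <- function() {
  # one parent, 4 windows, hand-set estimates
  manifest <- dplyr::bind_rows(
    make_parent(seq = strrep("ACGT", 10), parent_id = "p1", len = 40),
    purrr::map_dfr(seq(0, 30, by = 10), function(s) {
      purrr::map_dfr(1:2, function(r) {
        tibble::tibble(variant_id = sprintf("p1_scan10_w%03d_r%d", s, r),
                       parent_id = "p1", category = "scan10",
                       window_start = s, window_end = s + 10L,
                       replicate_index = r, barcode = NA_character_,
                       variable_region = strrep("TTTT", 10))
      })
    }))
  est <- tibble::tibble(
    variant_id = c("p1_wt", sprintf("p1_scan10_w%03d_r%d",
                                    rep(seq(0, 30, by = 10), each = 2), 1:2)),
    mean_au = c(4, 0.5, 0.5, 4, 4, 2.5, 2.5, 10, 10),
    status = "ml_fit")
  list(manifest = manifest, est = est)
}

test_that("fold-change profiles compute per-window log2 ratios against wild type", {
  fx <- make_profile_fixture()
  pr <- fold_change_profile(fx$manifest, fx$est, "p1")
  expect_equal(nrow(pr), 4)  # one entry per designed window
  expect_equal(pr$log2fc[pr$window_start == 0], -3)   # 0.5/4
  expect_equal(pr$log2fc[pr$window_start == 10], 0)
  expect_equal(pr$n_reps, rep(2L, 4))
  expect_error(fold_change_profile(fx$manifest, fx$est, "nope"), "no wild type")
})

test_that("effect fractions count two-fold changes on both sides", {
  fx <- make_profile_fixture()
  pr <- fold_change_profile(fx$manifest, fx$est, "p1")
  # ratios: 0.125, 1, 0.625, 2.5 -> one <= 1/2, one >= 2
  fr <- effect_fractions(pr)
  expect_equal(fr$fraction_decrease, 0.25)
  expect_equal(fr$fraction_increase, 0.25)
  expect_lte(fr$fraction_decrease + fr$fraction_increase, 1)

  flat <- pr; flat$ratio <- 1
  expect_equal(unlist(effect_fractions(flat)), c(fraction_decrease = 0,
                                                 fraction_increase = 0))
})

test_that("replicate consistency is 1 for identical replicates and ~0 under noise", {
  fx <- make_profile_fixture()
  pr <- fold_change_profile(fx$manifest, fx$est, "p1")
  rc <- replicate_consistency(pr)
  expect_equal(rc$n_pairs, 4)
  expect_equal(rc$r_squared, 1)

  set.seed(40)
  noise <- tibble::tibble(
    parent_id = "px", window_start = 1:1000, window_end = 2:1001,
    rep_means = purrr::map(1:1000, ~ rnorm(2)), n_reps = 2L,
    mean_mut_au = 1, wt_au = 1, ratio = 1, log2fc = 0)
  expect_lt(replicate_consistency(noise)$r_squared, 0.02)

  expect_error(replicate_consistency(pr[1:2, ]), "fewer than 3")
})

test_that("element calling merges adjacent affecting windows and reports single elements", {
  base <- tibble::tibble(
    parent_id = "p1",
    window_start = seq(0L, 90L, by = 10L), window_end = seq(10L, 100L, by = 10L),
    rep_means = purrr::map(1:10, ~ c(1, 1)), n_reps = 2L,
    mean_mut_au = c(5, 5, 5, 0.5, 0.4, 5, 5, 5, 5, 5),
    wt_au = 5, ratio = 1, log2fc = 0)
  call <- call_elements(base)
  expect_equal(call$element_start, 30L)
  expect_equal(call$element_end, 50L)
  expect_true(call$is_single_element)
  expect_equal(call$n_affecting_windows, 2L)

  none <- base; none$mean_mut_au <- rep(5, 10)
  expect_equal(nrow(call_elements(none)), 0)

  two <- base; two$mean_mut_au[8] <- 0.6
  c2 <- call_elements(two)
  expect_false(c2$is_single_element)
  expect_equal(c2$element_start, 30L)  # run containing the minimum

  # monotone in threshold: raising the threshold never shrinks the element set
  for (thr in c(0.45, 0.8, 2, 6)) {
    lo <- call_elements(base, abs_threshold = thr)
    hi <- call_elements(base, abs_threshold = thr + 1)
    if (nrow(lo) == 1 && nrow(hi) == 1) {
      expect_lte(hi$element_start, lo$element_start)
      expect_gte(hi$element_end, lo$element_end)
    } else {
      expect_gte(nrow(hi), nrow(lo))
    }
  }
})

test_that("polyA-relative statistics split windows and locate the max effect", {
  pr <- tibble::tibble(
    parent_id = "p1",
    window_start = seq(0L, 90L, by = 10L), window_end = seq(10L, 100L, by = 10L),
    rep_means = purrr::map(1:10, ~ c(1, 1)), n_reps = 2L,
    mean_mut_au = c(5, 5, 5, 5, 0.4, 5, 5, 5, 5, 5),
    wt_au = 5, ratio = c(1, 1, 1, 1, 0.08, 1, 1, 1, 1, 1), log2fc = 0)
  pr$log2fc <- log2(pr$ratio)
  polya <- tibble::tibble(parent_id = "p1", main_site = 85L)
  st <- polyA_relative_stats(pr, polya)
  expect_equal(st$n_upstream, 8)
  expect_equal(st$n_downstream, 2)
  expect_equal(st$distances$distance, 85 - 45)
  expect_lt(st$t_stat, 0)  # upstream mutations reduce expression more

  # identical upstream and downstream samples -> t ~ 0, p ~ 1
  flat <- pr; flat$log2fc <- rep(c(-1, 1), 5)
  st0 <- polyA_relative_stats(flat, polya)
  expect_equal(st0$t_stat, 0, tolerance = 1e-8)
  expect_gt(st0$p_value, 0.99)

  orphan <- pr; orphan$parent_id <- "p2"
  expect_warning(polyA_relative_stats(dplyr::bind_rows(pr, orphan), polya),
                 "excluded")
})

test_that("co-occurrence permutation p-values are bounded and calibrated", {
  set.seed(41)
  centers <- tibble::tibble(parent_id = paste0("p", 1:20),
                            center = runif(20, 0, 102), seq_length = 102)
  coincident <- tibble::tibble(parent_id = centers$parent_id,
                               position = centers$center)
  res <- motif_cooccurrence_test(centers, coincident, n_perm = 1000)
  expect_equal(res$p_value, 1 / 1001)
  expect_equal(res$observed, 0)

  # unrelated sites: p should not be systematically small
  set.seed(42)
  ps <- replicate(40, {
    sites <- tibble::tibble(parent_id = rep(centers$parent_id, 2),
                            position = runif(40, 0, 102))
    motif_cooccurrence_test(centers, sites, n_perm = 99)$p_value
  })
  expect_true(all(ps >= 1 / 100 & ps <= 1))
  expect_gt(mean(ps > 0.05), 0.75)
})

test_that("composition profiles report windowed coverage aligned at the polyA site", {
  polya <- tibble::tibble(parent_id = c("a", "b"), main_site = c(5L, 5L))
  seqs <- c(a = strrep("A", 30), b = strrep("A", 30))
  prof <- composition_profile(seqs, polya, kmers = c("A", "TA"), window = 10)
  expect_true(all(prof$frequency[prof$kmer == "A"] == 1))
  expect_true(all(prof$frequency[prof$kmer == "TA"] == 0))
  expect_equal(range(prof$offset), c(-5, 24))

  polyta <- c(a = strrep("TA", 15))
  p2 <- composition_profile(polyta, polya[1, ], kmers = "TA", window = 10)
  expect_true(all(p2$frequency == 1))  # overlapping occurrences cover everything
})
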