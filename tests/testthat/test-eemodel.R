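test_that("feature extraction matches hand enumeration on overlapping occurrences", {
  f <- extract_features("AAAA")
  expect_equal(f[["A_occ"]], 1)
  expect_equal(f[["A_cnt"]], 4)
  expect_equal(f[["A_pct"]], 100)
  expect_equal(f[["AA_occ"]], 1)
  expect_equal(f[["AA_cnt"]], 3)
  expect_equal(f[["AA_pct"]], 100)
  others <- setdiff(names(f), c("A_occ", "A_cnt", "A_pct",
                                "AA_occ", "AA_cnt", "AA_pct"))
  expect_true(all(f[others] == 0))

  g <- extract_features("TATATA")
  expect_equal(g[["TA_cnt"]], 3)
  expect_equal(g[["TA_pct"]], 100)
  expect_equal(g[["AT_cnt"]], 2)
  expect_equal(g[["AT_pct"]], 100 * 4 / 6)
  expect_equal(g[["T_cnt"]], 3)
  expect_equal(g[["T_pct"]], 50)

  expect_length(f, 60)
  expect_error(extract_features("ACGN"), "A,C,G,T")
})

test_that("feature invariants: occ/count coherence and mono percents sum to 100", {
  set.seed(50)
  for (i in 1:20) {
    s <- random_dna(sample(5:30, 1))
    f <- extract_features(s)
    occ <- f[grep("_occ$", names(f))]
    cnt <- f[grep("_cnt$", names(f))]
    expect_identical(unname(occ == 1), unname(cnt > 0))
    monos <- f[c("A_pct", "C_pct", "G_pct", "T_pct")]
    expect_equal(sum(monos), 100)
    pct <- f[grep("_pct$", names(f))]
    expect_true(all(pct >= 0 & pct <= 100))
  }
  # position invariance within a homopolymer; strand sensitivity
  expect_identical(extract_features("AAAA"), extract_features("AAAA"))
  expect_false(identical(extract_features("TATATA"),
                         extract_features("ATATAT")))
})

test_that("instance building uses wild-type windows and the 1 a.u. positive rule", {
  fx_manifest <- make_parent(seq = paste0(strrep("C", 10), strrep("TA", 5),
                                          strrep("G", 20)), parent_id = "p1",
                             len = 40)
  pr <- tibble::tibble(
    parent_id = "p1",
    window_start = seq(0L, 30L, by = 10L), window_end = seq(10L, 40L, by = 10L),
    rep_means = purrr::map(1:4, ~ c(1, 1)), n_reps = 2L,
    mean_mut_au = c(4, 0.4, 3, 2), wt_au = 4, ratio = 1, log2fc = 0)
  inst <- build_instances(pr, fx_manifest)
  expect_equal(nrow(inst), 4)
  expect_equal(sum(inst$label), 1)
  expect_identical(inst$wt_subsequence[2], strrep("TA", 5))

  bad <- pr; bad$window_end[4] <- 99L
  expect_error(build_instances(bad, fx_manifest), "outside")
})

test_that("grouped CV keeps parents intact and recovers the TA signal", {
  run <- small_pipeline_run()
  model <- run$model
  heldout <- run$heldout

  # no parent straddles outer folds
  per_parent <- tapply(model$fold_assignment[heldout$parent_id],
                       heldout$parent_id, function(x) length(unique(x)))
  expect_true(all(per_parent == 1))

  # TA dinucleotide family carries the largest positive coefficient
  fam <- sub("_(occ|cnt|pct)$", "", names(model$weights))
  fam_max <- tapply(model$weights, fam, max)
  expect_equal(names(which.max(fam_max)), "TA")

  # held-out scores are probabilities covering every instance
  expect_true(all(heldout$heldout_score >= 0 & heldout$heldout_score <= 1))
  expect_false(anyNA(heldout$heldout_score))
})

test_that("the L1 penalty controls sparsity along the fitted lambda grid", {
  run <- small_pipeline_run()
  inst <- run$heldout
  X <- scale(t(vapply(inst$wt_subsequence, extract_features, numeric(60))))
  X[is.na(X)] <- 0
  fit <- glmnet::glmnet(X, as.integer(inst$label), family = "binomial",
                        alpha = 1, lambda = run$model$lambda_grid,
                        standardize = FALSE)
  nz <- fit$df  # nonzero count along the decreasing-lambda path
  # the largest lambda zeroes every weight, and sparsity grows as the
  # penalty relaxes (the active set may fluctuate transiently, so exact
  # step-wise monotonicity of an L1 path is not guaranteed)
  expect_equal(nz[1], 0)
  expect_gt(nz[length(nz)], nz[1])
  expect_gt(cor(-log(fit$lambda), nz, method = "spearman"), 0.95)
  expect_true(all(cummax(nz) - nz <= 3))
})

test_that("shuffled labels give held-out accuracy near the base rate", {
  set.seed(51)
  run <- small_pipeline_run()
  inst <- run$heldout[, c("parent_id", "window_start", "window_end",
                          "wt_subsequence", "label", "mean_mut_au")]
  # permute labels across parents, breaking any feature association
  inst$label <- sample(inst$label)
  # signal-free labels leave the smallest lambdas unconverged in glmnet;
  # the larger-lambda solutions it returns are the ones used
  trained <- suppressWarnings(train_cv(inst))
  base <- max(mean(inst$label), 1 - mean(inst$label))
  acc <- mean((trained$heldout$heldout_score >= 0.5) == inst$label)
  expect_lt(abs(acc - base), 0.06)
})

test_that("native scoring profiles have sequence length and find planted elements", {
  run <- small_pipeline_run()
  lib <- run$library
  wt <- lib$manifest[lib$manifest$category == "native_wt", ]
  sc <- score_native(run$model, wt$variable_region[1])
  expect_length(sc, 102)
  expect_true(all(sc >= 0 & sc <= 1))
  # planted element at [40,50): profile argmax within [25, 55)
  expect_true(which.max(sc) - 1 >= 25 && which.max(sc) - 1 < 55)

  # a TA-free sequence scores uniformly low under the TA-dominated model
  flat <- score_native(run$model, strrep("GC", 51))
  expect_lt(max(flat), 0.5)

  expect_error(score_native(run$model, "ACGT"), "shorter")
})

test_that("max-effect classification and peak/correlation behave on the synthetic run", {
  run <- small_pipeline_run()
  cls <- max_effect_classification_rate(run$heldout)
  expect_equal(cls$n_parents, 25)
  expect_gt(cls$rate, 0.7)

  expect_equal(run$peak$peak_offset, -40, tolerance = 4)
  expect_gt(run$peak$r, 0.5)
  expect_error(peak_and_correlation(list(a = rep(0, 102)),
                                    tibble::tibble(parent_id = "a", main_site = 85L),
                                    tibble::tibble(parent_id = "a", mean_au = 1)),
               "at least 3")
})

test_that("model serialization round-trips through JSON", {
  run <- small_pipeline_run()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(run$model, path)
  back <- read_model(path)
  expect_equal(back$weights, run$model$weights)
  expect_equal(back$intercept, run$model$intercept)
  seqs <- c(strrep("TA", 5), strrep("GC", 5))
  expect_equal(predict_ee(back, seqs), predict_ee(run$model, seqs),
               tolerance = 1e-12)
})
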