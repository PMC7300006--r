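test_that("inclusion rule keeps callers with more units than parameters", {
  tab <- data.frame(
    caller_id = rep(c("A", "B", "C"), c(10, 6, 4)),
    bout_id = rep(sprintf("B%d", 1:10), 2))
  out <- check_inclusion(tab, n_params = 5)
  expect_setequal(attr(out, "eligible_callers"), c("A", "B"))
  expect_setequal(unique(out$caller_id), c("A", "B"))
  expect_error(check_inclusion(tab, n_params = 10), "infeasible")
})

test_that("two equal-variance 1-D classes split at the midpoint", {
  set.seed(1)
  tab <- data.frame(caller_id = rep(c("A", "B"), each = 50),
                    bout_id = rep(1:20, each = 5),
                    x = c(stats::rnorm(50, -1, 1e-3),
                          stats::rnorm(50, 1, 1e-3)))
  m <- fit_lda(tab, features = "x")
  near0 <- data.frame(x = c(-0.01, 0.01))
  expect_equal(predict(m, near0), c("A", "B"))
})

test_that("LDA predictions match the brute-force discriminant oracle", {
  for (s in 1:50) {
    tab <- random_feature_table(n_callers = 3, units_per_caller = 10,
                                sep = stats::runif(1, 0.5, 2), seed = s)
    m <- fit_lda(tab)
    expect_identical(predict(m, tab), brute_force_lda_predict(tab, tab),
                     label = sprintf("seed %d", s))
  }
})

test_that("LDA agrees with MASS::lda on a well-conditioned table", {
  skip_if_not_installed("MASS")
  tab <- random_feature_table(n_callers = 4, units_per_caller = 12,
                              sep = 1.5, seed = 99)
  feats <- c("DFB1", "DFA2", "PF", "FR", "duration")
  m <- fit_lda(tab)
  ref <- MASS::lda(tab[, feats], grouping = tab$caller_id)
  expect_equal(predict(m, tab),
               as.character(predict(ref, tab[, feats])$class))
})

test_that("well-separated callers reach near-perfect training accuracy", {
  tab <- gen_call_features(call_sim_spec(n_callers = 5,
                                         between_caller_sd = 10,
                                         within_caller_sd = 0.5, seed = 2))
  cl <- classify(fit_lda(tab), tab)
  expect_gte(cl$accuracy, 0.99)
  # zero-noise: exactly 1
  tab0 <- gen_call_features(call_sim_spec(n_callers = 3,
                                          within_caller_sd = 0, bout_sd = 0,
                                          seed = 3))
  expect_equal(classify(fit_lda(tab0), tab0)$accuracy, 1)
})

test_that("nested permutation preserves the bouts-per-caller multiset", {
  tab <- gen_call_features(call_sim_spec(n_callers = 4, bouts_per_caller = 3,
                                         seed = 6))
  before <- table(tapply(tab$caller_id, tab$bout_id, unique))
  set.seed(10)
  for (i in 1:200) {
    lab <- permute_nested(tab$caller_id, tab$bout_id)
    # units of each bout share one label
    expect_true(all(tapply(lab, tab$bout_id,
                           function(z) length(unique(z))) == 1))
    expect_equal(table(tapply(lab, tab$bout_id, unique)), before)
  }
  # a bout spanning two callers is a data-integrity error
  bad <- tab
  bad$caller_id[bad$bout_id == bad$bout_id[1]][1] <- "ZZ"
  expect_error(permute_nested(bad$caller_id, bad$bout_id), "integrity")
})

test_that("bout-label permutation is uniform over the 3! assignments", {
  labels <- rep(c("A", "B", "C"), each = 2)
  bouts <- rep(c("b1", "b2", "b3"), each = 2)
  set.seed(77)
  draws <- replicate(6000, paste(unique(
    data.frame(b = bouts, l = permute_nested(labels, bouts))$l),
    collapse = ""))
  tabn <- table(draws)
  expect_equal(length(tabn), 6)  # all 3! assignments occur
  gof <- stats::chisq.test(tabn)
  expect_gt(gof$p.value, 0.01)
  # identity assignment frequency consistent with 1/6
  expect_lt(abs(tabn[["ABC"]] / 6000 - 1 / 6), 0.02)
})

test_that("pdfa p-value follows the exceedance rank definition", {
  # caller means equal: observed accuracy typically below the null mean
  tab <- gen_call_features(call_sim_spec(n_callers = 4, bouts_per_caller = 4,
                                         between_caller_sd = 0, seed = 13))
  res <- pdfa_test(tab, n_perm = 199, seed = 14)
  expect_equal(res$p_value,
               (sum(res$permuted_accuracies >= res$observed_accuracy) + 1) /
                 (res$n_perm + 1))
  if (res$observed_accuracy < res$null_mean) expect_gt(res$p_value, 0.5)
  expect_true(res$null_ci[1] <= res$null_mean &&
                res$null_mean <= res$null_ci[2])
})

test_that("pdfa results are bit-for-bit reproducible given the seed", {
  tab <- gen_call_features(call_sim_spec(seed = 21))
  r1 <- pdfa_test(tab, n_perm = 199, seed = 5)
  r2 <- pdfa_test(tab, n_perm = 199, seed = 5)
  expect_identical(r1, r2)
  sub <- tab[tab$caller_id %in% c("C01", "C02", "C03"), ]
  r3 <- suppressWarnings(pdfa_crossvalidated(sub, n_perm = 49, seed = 5))
  r4 <- suppressWarnings(pdfa_crossvalidated(sub, n_perm = 49, seed = 5))
  expect_identical(r3, r4)
})

test_that("permutation power grows with the planted caller effect", {
  effects <- c(0, 1, 2, 3)
  med_p <- vapply(effects, function(eff) {
    p <- vapply(1:15, function(s) {
      tab <- gen_call_features(call_sim_spec(
        n_callers = 5, bouts_per_caller = 4, units_per_bout = c(3, 6),
        between_caller_sd = eff, within_caller_sd = 1, bout_sd = 0.3,
        seed = 1000 * eff + s))
      pdfa_test(tab, n_perm = 199, seed = s)$p_value
    }, numeric(1))
    stats::median(p)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
  expect_lt(med_p[4], 0.05)
})

test_that("leave-one-out accuracy does not exceed resubstitution accuracy", {
  worse_or_equal <- vapply(1:30, function(s) {
    tab <- gen_call_features(call_sim_spec(
      n_callers = 3, bouts_per_caller = 3, units_per_bout = c(3, 5),
      between_caller_sd = stats::runif(1, 0, 2), seed = 3000 + s))
    plain <- suppressWarnings(pdfa_test(tab, n_perm = 1, seed = 1))
    loo <- suppressWarnings(pdfa_crossvalidated(tab, n_perm = 1, seed = 1))
    loo$observed_accuracy <= plain$observed_accuracy
  }, logical(1))
  expect_gte(mean(worse_or_equal), 0.9)
})

test_that("bout holdout removes bout-leakage inflation", {
  # strong bout effects, no caller effect: unit-level LOO leaks bout
  # identity into training, inflating accuracy; bout-level holdout does not
  tab <- gen_call_features(call_sim_spec(
    n_callers = 4, bouts_per_caller = 5, units_per_bout = c(6, 10),
    between_caller_sd = 0, within_caller_sd = 0.2, bout_sd = 3, seed = 55))
  unit_cv <- suppressWarnings(
    pdfa_crossvalidated(tab, n_perm = 1, seed = 1, holdout = "unit"))
  bout_cv <- suppressWarnings(
    pdfa_crossvalidated(tab, n_perm = 1, seed = 1, holdout = "bout"))
  expect_gt(unit_cv$observed_accuracy, bout_cv$observed_accuracy + 0.1)
  expect_lt(bout_cv$observed_accuracy, 0.5)
})

test_that("single-bout-per-caller designs are rejected as unpermutable", {
  tab <- gen_call_features(call_sim_spec(n_callers = 3, bouts_per_caller = 1,
                                         units_per_bout = c(8, 8), seed = 1))
  expect_error(pdfa_test(tab, n_perm = 199, seed = 1), "infeasible")
  expect_warning(
    pdfa_test(gen_call_features(call_sim_spec(seed = 2)), n_perm = 50,
              seed = 1),
    "100 permutations")
})
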