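test_that("association matrix counts focal-neighbour co-occurrences", {
  scans <- data.frame(
    focal_id = c("A", "A", "B"), scan_index = 1:3,
    neighbour_ids = c("B", "B;C", "A"))
  a <- build_association_matrix(scans)
  expect_equal(a["A", "B"], 3)
  expect_equal(a["A", "C"], 1)
  expect_equal(a["B", "C"], 0)
  expect_true(isSymmetric(a))
  expect_true(all(diag(a) == 0))
  # order invariance
  a2 <- build_association_matrix(scans[c(3, 1, 2), ])
  expect_equal(a2, a)
  # empty neighbour sets give a zero matrix
  scans$neighbour_ids <- ""
  expect_true(all(build_association_matrix(scans,
                                           ids = c("A", "B", "C")) == 0))
  # unknown id rejected
  scans$neighbour_ids <- c("Z", "", "")
  expect_error(build_association_matrix(scans, ids = c("A", "B", "C")), "Z")
})

test_that("rate mode divides by combined dyadic scan effort", {
  scans <- data.frame(focal_id = c("A", "A", "B", "B"), scan_index = 1:4,
                      neighbour_ids = c("B", "B", "A", ""))
  r <- build_association_matrix(scans, mode = "rate")
  expect_equal(r["A", "B"], 3 / 4)
})

test_that("dyadic z-scoring standardises off-diagonal values", {
  m <- matrix(c(0, 0, 0, 2, 0, 0, 5, 7, 0), 3, 3)
  m <- m + t(m)
  z <- zscore_dyadic(m)
  vals <- z[upper.tri(z)]
  expect_lt(abs(mean(vals)), 1e-10)
  expect_lt(abs(stats::sd(vals) - 1), 1e-10)
  # affine invariance
  expect_equal(zscore_dyadic(3 * m + 7 - 7 * diag(3)), z, tolerance = 1e-10)
  # population-sd convention maps dyadic values {0, 2} to {-1, +1}
  expect_equal(zscore_dyadic(c(0, 2), sd_type = "population"), c(-1, 1))
  expect_error(zscore_dyadic(matrix(1, 3, 3)), "zero variance")
})

test_that("Elo follows the closed-form update and conserves the rating sum", {
  one <- data.frame(winner_id = "A", loser_id = "B", order = 1)
  e <- elo_ratings(one, k = 100, start = 1000)
  expect_equal(unname(e$ratings["A"]), 1050)
  expect_equal(unname(e$ratings["B"]), 950)
  # no events: everyone at start
  e0 <- elo_ratings(one[0, ], ids = c("A", "B", "C"))
  expect_true(all(e0$ratings == 1000))
  # conservation after every event of a longer random sequence
  set.seed(3)
  ids <- LETTERS[1:6]
  ev <- t(replicate(80, sample(ids, 2)))
  conf <- data.frame(winner_id = ev[, 1], loser_id = ev[, 2], order = 1:80)
  e2 <- elo_ratings(conf, ids = ids)
  expect_true(all(abs(rowSums(e2$history) - 6000) < 1e-9))
  expect_error(elo_ratings(data.frame(winner_id = "A", loser_id = "A",
                                      order = 1)), "differ")
})

test_that("Elo recovers a steep planted hierarchy", {
  spec <- troop_sim_spec(n_individuals = 10, n_females = 5,
                         n_scans_per_focal = 1, n_conflicts = 2000,
                         rank_steepness = 0.95, seed = 42)
  troop <- gen_troop_observations(spec)
  elo <- elo_ratings(troop$conflicts, ids = troop$ids)
  rho <- cor(-elo$ratings, troop$true_ranks, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("eigenvector centrality matches a dense eigensolver", {
  set.seed(7)
  for (i in 1:20) {
    n <- 10
    m <- matrix(stats::runif(n * n), n, n); m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(sprintf("I%02d", 1:n), sprintf("I%02d", 1:n))
    ce <- eigenvector_centrality(m)
    ev <- eigen(m)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_lt(max(abs(unname(ce$scores) - ev)), 1e-8)
    # scale invariance
    expect_equal(eigenvector_centrality(10 * m)$scores, ce$scores,
                 tolerance = 1e-8)
  }
})

test_that("centrality handles symmetric and star graphs as expected", {
  n <- 6
  full <- matrix(1, n, n); diag(full) <- 0
  dimnames(full) <- list(LETTERS[1:n], LETTERS[1:n])
  ce <- eigenvector_centrality(full)
  expect_true(all(abs(ce$scores - 1) < 1e-10))
  expect_equal(length(ce$central_set), 3)  # ceil(n/2), ties by id
  star <- matrix(0, n, n); star[1, 2:n] <- star[2:n, 1] <- 1
  dimnames(star) <- dimnames(full)
  cs <- eigenvector_centrality(star)
  expect_equal(names(which.max(cs$scores)), "A")
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "zero")
})

test_that("Mantel test is exact on identical matrices and matches vegan", {
  set.seed(11)
  n <- 12
  m1 <- matrix(stats::runif(n * n), n, n); m1 <- m1 + t(m1); diag(m1) <- 0
  res <- mantel_test(m1, m1, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 1000)
  skip_if_not_installed("vegan")
  m2 <- m1 + matrix(stats::rnorm(n * n, sd = 0.3), n, n)
  m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  res2 <- mantel_test(m1, m2, n_perm = 499, seed = 2)
  ref <- vegan::mantel(m1, m2, permutations = 499)
  expect_equal(res2$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Mantel detects the planted grooming-association dependence", {
  troop <- gen_troop_observations(troop_sim_spec(seed = 17))
  a <- build_association_matrix(troop$scans, ids = troop$ids)
  res <- mantel_test(a, troop$grooming, n_perm = 999, seed = 3)
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("split-half stability mirrors stationary vs re-wired networks", {
  spec <- troop_sim_spec(n_individuals = 12, n_females = 6,
                         n_scans_per_focal = 120, seed = 23)
  troop <- gen_troop_observations(spec)
  stable <- stability_split(troop$scans, 0.5, ids = troop$ids,
                            n_perm = 499, seed = 4)
  expect_gt(stable$r, 0)
  expect_lt(stable$p_value, 0.01)
  # regime change at the midpoint: permute ids in the second half
  set.seed(5)
  relab <- stats::setNames(sample(troop$ids), troop$ids)
  sc <- troop$scans[order(troop$scans$scan_index), ]
  second <- seq_len(nrow(sc)) > nrow(sc) / 2
  sc$focal_id[second] <- relab[sc$focal_id[second]]
  sc$neighbour_ids[second] <- vapply(sc$neighbour_ids[second], function(z) {
    if (z == "") return("")
    paste(relab[strsplit(z, ";")[[1]]], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  rewired <- stability_split(sc, 0.5, ids = troop$ids, n_perm = 499,
                             seed = 4)
  expect_lt(abs(rewired$r), abs(stable$r))
  expect_error(stability_split(troop$scans, 0), "split")
})

test_that("kinship matrix codes matriline membership", {
  k <- kinship_matrix(c(A = "m1", B = "m1", C = "m2"))
  expect_equal(k["A", "B"], 1)
  expect_equal(k["A", "C"], 0)
  expect_equal(k["B", "C"], 0)
  expect_true(all(diag(k) == 1))
  one <- kinship_matrix(c(A = "m", B = "m", C = "m"))
  expect_true(all(one == 1))
  singles <- kinship_matrix(c(A = "1", B = "2", C = "3"))
  expect_true(all(singles[upper.tri(singles)] == 0))
  expect_error(kinship_matrix(c(A = "m1", B = "")), "label")
})

test_that("condition dyad selection follows the friendship rules", {
  toy <- toy_troop_matrices()
  kin <- kinship_matrix(stats::setNames(c("m1", "m1", "m2", "m2", "m3", "m4"),
                                        toy$ids))
  cent <- eigenvector_centrality(toy$assoc)
  # condition 1: A = top friend F1; B = F1's best friend among
  # low-with-subject females = F2
  d1 <- select_condition_dyads("S", toy$assoc, kin, toy$sexes, cent, 1)
  expect_equal(d1, c("F1", "F2"))
  # condition 2: same A, B = lowest with F1 among low-with-subject = F3
  d2 <- select_condition_dyads("S", toy$assoc, kin, toy$sexes, cent, 2)
  expect_equal(d2, c("F1", "F3"))
  # callers are always female and never the subject
  for (cond in 1:6) {
    d <- select_condition_dyads("S", toy$assoc, kin, toy$sexes, cent, cond)
    if (!is.null(d)) {
      expect_false("S" %in% d)
      expect_true(all(toy$sexes[d] == "F"))
      expect_length(unique(d), 2)
    }
  }
  # determinism
  expect_identical(select_condition_dyads("S", toy$assoc, kin, toy$sexes,
                                          cent, 1), d1)
  expect_error(select_condition_dyads("ZZ", toy$assoc, kin, toy$sexes,
                                      cent, 1), "unknown subject")
})

test_that("conditions 3-4 are infeasible for central subjects", {
  troop <- gen_troop_observations(troop_sim_spec(seed = 29))
  a <- build_association_matrix(troop$scans, ids = troop$ids)
  kin <- kinship_matrix(troop$matrilines)
  cent <- eigenvector_centrality(a)
  central <- cent$central_set[1]
  peripheral <- cent$peripheral_set[1]
  expect_null(select_condition_dyads(central, a, kin, troop$sexes, cent, 3))
  expect_null(select_condition_dyads(central, a, kin, troop$sexes, cent, 4))
  expect_false(is.null(select_condition_dyads(peripheral, a, kin,
                                              troop$sexes, cent, 3)))
})

test_that("condition 5 pairs a matriarch with her matriline, 6 outside it", {
  troop <- gen_troop_observations(troop_sim_spec(seed = 37))
  a <- build_association_matrix(troop$scans, ids = troop$ids)
  kin <- kinship_matrix(troop$matrilines)
  cent <- eigenvector_centrality(a)
  d5 <- select_condition_dyads(troop$ids[12], a, kin, troop$sexes, cent, 5)
  d6 <- select_condition_dyads(troop$ids[12], a, kin, troop$sexes, cent, 6)
  expect_equal(troop$matrilines[d5[1]], troop$matrilines[d5[2]],
               ignore_attr = TRUE)
  expect_false(troop$matrilines[d6[1]] == troop$matrilines[d6[2]])
  # caller A is the most central female of her matriline
  matr <- troop$matrilines[d5[1]]
  fem_kin <- names(troop$matrilines)[troop$matrilines == matr &
                                       troop$sexes == "F"]
  expect_equal(d5[1], names(which.max(cent$scores[fem_kin])))
})
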