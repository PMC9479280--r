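test_that("a column unrelated to the term has delta near zero", {
  co <- toy_cohort(8L, seed = 51)
  Y <- toy_outcomes(co, q = 4, shift = list(changers = 1.5), seed = 52)
  # columns 2..4 are pure noise; average delta over replicates ~ 0
  deltas <- replicate(6, {
    Y2 <- Y
    Y2[, 3] <- rnorm(nrow(co))
    tab <- jackknife_effect_sizes(Y2, co, "group", K = 150,
                                  seed = sample.int(1e6, 1))
    tab$delta[3]
  })
  mc <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * mc + 1e-3)
})

test_that("a strongly planted column attains the maximal delta", {
  for (r in 1:3) {
    co <- toy_cohort(8L, seed = 60 + r)
    Y <- toy_outcomes(co, q = 6, shift = list(changers = 2), seed = 70 + r)
    tab <- jackknife_effect_sizes(Y, co, "group",
                                  groups = c("changers", "P-high"),
                                  K = 150, seed = 80 + r)
    expect_equal(rank_regions(tab, 1)$column_id, "roi_1")
  }
})

test_that("duplicating a signal column splits but does not destroy its delta", {
  co <- toy_cohort(10L, seed = 91)
  Y <- toy_outcomes(co, q = 5, shift = list(changers = 2), seed = 92)
  Ydup <- cbind(Y, roi_dup = Y[, 1])
  tab <- jackknife_effect_sizes(Ydup, co, "group", K = 150, seed = 93)
  null_max <- max(tab$delta[tab$column_id %in% paste0("roi_", 2:5)])
  expect_gt(tab$delta[tab$column_id == "roi_1"], null_max)
  expect_gt(tab$delta[tab$column_id == "roi_dup"], null_max)
})

test_that("deltas are seed-deterministic and report Monte-Carlo error", {
  co <- toy_cohort(6L)
  Y <- toy_outcomes(co, q = 4, shift = list(`P-low` = 1))
  t1 <- jackknife_effect_sizes(Y, co, "group", K = 120, seed = 5)
  t2 <- jackknife_effect_sizes(Y, co, "group", K = 120, seed = 5)
  expect_identical(t1$delta, t2$delta)
  expect_true(all(t1$mc_se >= 0))
  # Monte-Carlo SE shrinks with K (factor ~ sqrt(K2/K1) on average)
  t3 <- jackknife_effect_sizes(Y, co, "group", K = 1000, seed = 5)
  expect_lt(mean(t3$mc_se), mean(t1$mc_se))
})

test_that("shuffling all columns jointly removes the term's pseudo-R2", {
  co <- toy_cohort(8L, seed = 41)
  Y <- toy_outcomes(co, q = 4, shift = list(changers = 1.5), seed = 42)
  des <- build_design(co, 1)
  G <- gower_center(pairwise_distances(Y))
  obs <- mdmr_fit(G, des, "group", n_perm = 99, seed = 1)
  # permuting whole rows of Y == raw relabeling null
  set.seed(43)
  null_r2 <- replicate(300, {
    Gp <- gower_center(pairwise_distances(Y[sample(nrow(Y)), ]))
    f <- mdmr_fit(Gp, des, "group", n_perm = 99, seed = 1)
    f$pseudo_R2
  })
  expect_gt(obs$pseudo_R2, mean(null_r2) + 4 * sd(null_r2) / sqrt(300))
  # the relabeled null retains well under half of the observed effect
  expect_lt(mean(null_r2), obs$pseudo_R2 / 2)
})

test_that("constant columns yield delta zero with a warning", {
  co <- toy_cohort(4L)
  Y <- toy_outcomes(co, q = 3)
  Y[, 2] <- 5
  expect_warning(tab <- jackknife_effect_sizes(Y, co, "group", K = 100,
                                               seed = 1),
                 "constant")
  expect_equal(tab$delta[2], 0)
})

test_that("rank_regions orders by delta with lexicographic tie-breaks", {
  tab <- structure(data.frame(column_id = c("b_left", "a_left", "c_left"),
                              delta = c(0.2, 0.2, 0.5), mc_se = 0, K = 100),
                   class = c("effect_size_table", "data.frame"))
  r <- rank_regions(tab)
  expect_equal(r$column_id, c("c_left", "a_left", "b_left"))
  expect_equal(r$rank, 1:3)
  expect_equal(nrow(rank_regions(tab, 2)), 2L)
  expect_error(rank_regions(tab, 4), "exceeds")
})
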