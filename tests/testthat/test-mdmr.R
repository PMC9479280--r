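test_that("pairwise distances match closed forms and a nested-loop reference", {
  Y <- rbind(a = c(1, 2), b = c(4, 6))
  expect_equal(pairwise_distances(Y, "manhattan")["a", "b"], 7)
  expect_equal(pairwise_distances(Y, "euclidean")["a", "b"], 5)
  expect_equal(pairwise_distances(rbind(c(1, 2), c(1, 2)))[1, 2], 0)

  set.seed(4)
  Y <- matrix(rnorm(50), 10, 5)
  for (metric in c("manhattan", "euclidean")) {
    D <- pairwise_distances(Y, metric)
    ref <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      d <- Y[i, ] - Y[j, ]
      ref[i, j] <- if (metric == "manhattan") sum(abs(d)) else sqrt(sum(d^2))
    }
    expect_equal(D, ref, tolerance = 1e-12, ignore_attr = TRUE)
    expect_symmetric(D)
    expect_true(all(diag(D) == 0))
  }
})

test_that("Gower centering satisfies its algebraic identities", {
  set.seed(5)
  Y <- matrix(rnorm(36), 12, 3)
  D <- pairwise_distances(Y, "euclidean")
  G <- gower_center(D)
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_symmetric(G)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(G, Yc %*% t(Yc), tolerance = 1e-8, ignore_attr = TRUE)
  # euclidean G is positive semidefinite
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # n = 2, d = 2 hand computation
  D2 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(gower_center(D2), matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE)
})

test_that("euclidean single-outcome pseudo-F equals the OLS/ANOVA F", {
  set.seed(6)
  for (r in 1:10) {
    co <- toy_cohort(sample(4:8, 1), seed = r)
    y <- matrix(rnorm(nrow(co)), dimnames = list(co$participant_id, "y"))
    G <- gower_center(pairwise_distances(y, "euclidean"))
    des <- build_design(co, 1)
    fit <- mdmr_fit(G, des, n_perm = 99, seed = 1)
    lm_f <- lm(y ~ age + sex + group, as.data.frame(co))
    lm_r <- lm(y ~ age + sex, as.data.frame(co))
    expect_equal(fit$pseudo_F[fit$term == "group"],
                 anova(lm_r, lm_f)$F[2], tolerance = 1e-8)
    # multivariate euclidean: term trace equals summed OLS model SS increments
    Y5 <- matrix(rnorm(nrow(co) * 5), nrow(co), 5)
    G5 <- gower_center(pairwise_distances(Y5, "euclidean"))
    f5 <- mdmr_fit(G5, des, n_perm = 99, seed = 1)
    ss <- sum(sapply(1:5, function(j) {
      a <- anova(lm(Y5[, j] ~ age + sex, as.data.frame(co)),
                 lm(Y5[, j] ~ age + sex + group, as.data.frame(co)))
      a$`Sum of Sq`[2]
    }))
    expect_equal(f5$pseudo_R2[f5$term == "group"] * sum(diag(G5)), ss,
                 tolerance = 1e-8)
  }
})

test_that("pseudo-R2 and pseudo-F agree with an independent PERMANOVA oracle", {
  set.seed(7)
  co <- toy_cohort(6L)
  Y <- toy_outcomes(co, q = 6, shift = list(changers = 1))
  D <- pairwise_distances(Y, "manhattan")
  fit <- mdmr_fit(gower_center(D), build_design(co, 1), n_perm = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(D) ~ age + sex + group, data = as.data.frame(co),
                       by = "margin", permutations = 99)
  expect_equal(fit$pseudo_F[fit$term == "group"],
               ad$F[rownames(ad) == "group"], tolerance = 1e-10)
  expect_equal(fit$pseudo_R2[fit$term == "group"],
               ad$R2[rownames(ad) == "group"], tolerance = 1e-10)
})

test_that("statistics and p-values are invariant to a global outcome rescaling", {
  co <- toy_cohort(5L)
  Y <- toy_outcomes(co, q = 5, shift = list(`P-low` = 0.8))
  for (metric in c("manhattan", "euclidean")) {
    f1 <- mdmr(Y, co, metric = metric, n_perm = 199, seed = 3)
    f2 <- mdmr(Y * 7.3, co, metric = metric, n_perm = 199, seed = 3)
    expect_equal(f1$pseudo_R2, f2$pseudo_R2, tolerance = 1e-10)
    expect_equal(f1$pseudo_F, f2$pseudo_F, tolerance = 1e-10)
    expect_identical(f1$p_value, f2$p_value)
  }
})

test_that("permutation p-values are reproducible, bounded and add-one", {
  co <- toy_cohort(5L)
  Y <- toy_outcomes(co, q = 4)
  f1 <- mdmr(Y, co, n_perm = 199, seed = 42)
  f2 <- mdmr(Y, co, n_perm = 199, seed = 42)
  expect_identical(f1$p_value, f2$p_value)
  expect_true(all(f1$p_value >= 1 / 200 & f1$p_value <= 1))
})

test_that("intercept-only model explains nothing of a centered G", {
  co <- toy_cohort(4L)
  Y <- toy_outcomes(co, q = 3)
  G <- gower_center(pairwise_distances(Y))
  des <- structure(list(X = matrix(1, nrow(co), 1), assign = 0L,
                        term_labels = character(0), n = nrow(co)),
                   class = "mdmr_design")
  fit <- mdmr_fit(G, des, terms = character(0), n_perm = 99)
  expect_equal(nrow(fit), 0L)
  expect_equal(attr(fit, "full_R2"), 0, tolerance = 1e-12)
})

test_that("pairwise contrasts re-center G on each two-group subset", {
  co <- toy_cohort(5L)
  Y <- toy_outcomes(co, q = 5, shift = list(changers = 1.2))
  D <- pairwise_distances(Y)
  pw <- pairwise_group_contrasts(D, co, n_perm = 199, seed = 5)
  expect_equal(pw$contrast, c("P-high vs P-low", "P-high vs changers",
                              "changers vs P-low"))
  # the reported statistic must equal a from-scratch fit on the subset's D
  idx <- which(co$group %in% c("P-high", "changers"))
  Gsub <- gower_center(D[idx, idx])
  sub <- as.data.frame(co)[idx, ]
  sub$group <- droplevels(sub$group)
  ref <- mdmr_fit(Gsub, build_design(sub, 1), terms = "group",
                  n_perm = 99, seed = 1)
  expect_equal(pw$pseudo_F[pw$contrast == "P-high vs changers"],
               ref$pseudo_F, tolerance = 1e-10)
  # and differ from the (incorrect) subset of the full-sample G
  Gfull <- gower_center(D)
  wrong <- sum(abs(Gfull[idx, idx] - Gsub))
  expect_gt(wrong, 1e-6)
})

test_that("group relabeling leaves a two-group contrast statistic unchanged", {
  co <- toy_cohort(5L)
  Y <- toy_outcomes(co, q = 4, shift = list(`P-low` = 1))
  D <- pairwise_distances(Y)
  idx <- which(co$group %in% c("P-high", "P-low"))
  sub <- as.data.frame(co)[idx, ]
  G <- gower_center(D[idx, idx])
  f_ab <- mdmr_fit(G, build_design(sub, 1), "group", n_perm = 99, seed = 1)
  sub2 <- sub
  sub2$group <- factor(ifelse(sub2$group == "P-high", "P-low", "P-high"))
  f_ba <- mdmr_fit(G, build_design(sub2, 1), "group", n_perm = 99, seed = 1)
  expect_equal(f_ab$pseudo_F, f_ba$pseudo_F, tolerance = 1e-10)
  expect_equal(f_ab$pseudo_R2, f_ba$pseudo_R2, tolerance = 1e-10)
})

test_that("permuting sex within groups destroys a planted interaction", {
  co <- toy_cohort(12L, seed = 31)
  Y <- toy_outcomes(co, q = 5, seed = 32)
  # sex-specific group effect: changers females shifted strongly
  sel <- co$group == "changers" & co$sex == "female"
  Y[sel, 2] <- Y[sel, 2] + 2.5
  D <- pairwise_distances(Y)
  ia <- interaction_test(D, co, n_perm = 199, seed = 8)
  expect_lt(ia$p_value, 0.05)
  # permute sex labels within groups: signal gone
  set.seed(9)
  co2 <- as.data.frame(co)
  for (g in levels(co2$group)) {
    i <- which(co2$group == g)
    co2$sex[i] <- co2$sex[sample(i)]
  }
  ia2 <- interaction_test(D, co2, n_perm = 199, seed = 8)
  expect_gt(ia2$p_value, 0.05)
})
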