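test_that("single-bin cluster test matches the exact sign-flip permutation p", {
  set.seed(5)
  d <- matrix(rnorm(10, mean = 0.5), ncol = 1)
  tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  tobs <- abs(tstat(d[, 1]))
  # brute-force enumeration of all 2^10 sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  tnull <- apply(signs, 1, function(s) abs(tstat(s * d[, 1])))
  p_exact <- mean(tnull >= tobs - 1e-12)

  res <- cluster_perm_ttest(d, cluster_alpha = 0.5, n_perm = 4000, seed = 2)
  expect_length(res$clusters, 1L)
  expect_lt(abs(res$clusters[[1]]$p - p_exact), 0.02)
  expect_equal(res$stat_map[1], tstat(d[, 1]))
})

test_that("cluster results are deterministic and structurally sound", {
  set.seed(6)
  d <- array(rnorm(12 * 2 * 20), dim = c(12, 2, 20))
  d[, 1, 5:8] <- d[, 1, 5:8] + 1.2
  r1 <- cluster_perm_ttest(d, n_perm = 300, seed = 9)
  r2 <- cluster_perm_ttest(d, n_perm = 300, seed = 9)
  expect_identical(r1$clusters, r2$clusters)
  expect_gte(length(r1$clusters), 1L)
  for (cl in r1$clusters) {
    expect_equal(cl$mass, sum(r1$stat_map[cl$members]))
    expect_gte(cl$p, 1 / 301)
    expect_lte(cl$p, 1)
    # connectedness under the chain: members are contiguous
    expect_true(all(diff(cl$members) == 1L))
  }
  big <- significant_clusters(r1, 0.05)
  expect_gte(length(big), 1L)
  expect_true(any(vapply(big, function(cl) any(cl$members %in% 5:8), TRUE)))

  expect_warning(cluster_perm_ttest(d, n_perm = 50, seed = 1), "100")
  expect_error(cluster_perm_ttest(d, adjacency = chain_adjacency(3)),
               "adjacency")
})

test_that("mixed ANOVA F maps match the aov split-plot oracle", {
  # worked dataset: 6 subjects, 3 groups of 2, two modalities, one bin
  y1 <- c(0.8, 1.2, 2.1, 2.7, 0.2, 0.4)
  y2 <- c(1.6, 2.2, 4.0, 4.6, 0.1, 0.5)
  g <- factor(c("a", "a", "b", "b", "c", "c"))
  f <- silenttrack:::mixed_anova_f(matrix(y1), matrix(y2), g)

  df <- data.frame(y = c(y1, y2), subj = factor(rep(1:6, 2)),
                   mod = factor(rep(1:2, each = 6)), g = rep(g, 2))
  sm <- summary(stats::aov(y ~ g * mod + Error(subj / mod), data = df))
  Fb <- sm[["Error: subj"]][[1]]["g", "F value"]
  Fw <- sm[["Error: subj:mod"]][[1]][c("mod", "g:mod"), "F value"]
  expect_equal(unname(f$group$F), Fb, tolerance = 1e-10)
  expect_equal(unname(f$modality$F), Fw[1], tolerance = 1e-10)
  expect_equal(unname(f$interaction$F), Fw[2], tolerance = 1e-10)
  expect_equal(c(f$group$df1, f$group$df2), c(2, 3))
  expect_equal(c(f$modality$df1, f$modality$df2), c(1, 3))

  # point ANOVA exposes the same Fs with parametric p
  pa <- point_anova(cbind(y1, y2), g)
  expect_equal(pa$effects$group$F, unname(f$group$F))
  expect_equal(pa$effects$modality$p,
               stats::pf(f$modality$F, 1, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical modalities: modality F = 0
  pa0 <- point_anova(cbind(y1, y1), g)
  expect_equal(pa0$effects$modality$F, 0)
})

test_that("cluster ANOVA detects a group effect and flags the right bins", {
  set.seed(31)
  N <- 15; B <- 20
  contrasts <- array(rnorm(N * 2 * B, sd = 0.5), dim = c(N, 2, B))
  g <- factor(rep(c("hearing", "dhh", "congenital"), each = 5))
  # group-dependent envelope-modality contrast in bins 4:8
  bump <- c(hearing = 1, dhh = 2, congenital = 0)
  for (i in seq_len(N)) {
    contrasts[i, 2, 4:8] <- contrasts[i, 2, 4:8] + bump[as.character(g[i])]
  }
  res <- cluster_perm_mixed_anova(contrasts, g, n_perm = 300, seed = 3)
  sig_g <- significant_clusters(res$effects$group$clusters, 0.05)
  expect_gte(length(sig_g), 1L)
  expect_true(any(vapply(sig_g, function(cl) any(cl$members %in% 4:8), TRUE)))
  sig_m <- significant_clusters(res$effects$modality$clusters, 0.05)
  expect_gte(length(sig_m), 1L)

  expect_error(cluster_perm_mixed_anova(contrasts, factor(rep("a", 15)),
                                        n_perm = 100),
               "at least 2")
})

test_that("group-effect family-wise error stays near the nominal level", {
  set.seed(77)
  hits <- vapply(seq_len(100), function(i) {
    contrasts <- array(rnorm(12 * 2 * 12), dim = c(12, 2, 12))
    g <- factor(rep(c("a", "b", "c"), each = 4))
    res <- cluster_perm_mixed_anova(contrasts, g, n_perm = 150,
                                    seed = 1000 + i)
    length(significant_clusters(res$effects$group$clusters, 0.05)) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.10)
})

test_that("post hoc tests reproduce the Satterthwaite closed form", {
  # textbook two-sample fixture
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
         23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 23.9, 13.3)
  tab <- posthoc_tests(c(x, y),
                       groups = rep(c("g1", "g2"), c(10, 20)))
  s1 <- var(x) / 10; s2 <- var(y) / 20
  t_hand <- (mean(x) - mean(y)) / sqrt(s1 + s2)
  df_hand <- (s1 + s2)^2 / (s1^2 / 9 + s2^2 / 19)
  expect_equal(tab$t, t_hand, tolerance = 1e-12)
  expect_equal(tab$df, df_hand, tolerance = 1e-12)
  expect_identical(tab$variant, "welch")

  # equal-variance equal-n limit: df ~ n1 + n2 - 2
  set.seed(41)
  a <- rnorm(30)
  tab2 <- posthoc_tests(c(a, a + 0.1), groups = rep(c("p", "q"), each = 30))
  expect_lt(abs(tab2$df - 58), 0.5)

  # identical samples: t = 0, p = 1
  tab3 <- posthoc_tests(c(a, a), groups = rep(c("p", "q"), each = 30))
  expect_equal(tab3$t, 0)
  expect_equal(tab3$p, 1)

  # paired branch
  b <- a + 0.1 + rnorm(30, sd = 0.02)
  tab4 <- posthoc_tests(NULL, paired_with = list(a, b))
  expect_identical(tab4$variant, "paired")
  expect_gt(tab4$t, 10)
  tab5 <- posthoc_tests(NULL, paired_with = list(a, a))
  expect_equal(tab5$t, 0); expect_equal(tab5$p, 1)
})

test_that("grid adjacency combines frequency chains with spatial neighbors", {
  adj <- grid_adjacency(3, chain_adjacency(2))
  # bin 1 = (f1, ch1): neighbors f2ch1 (2) and f1ch2 (4)
  expect_setequal(adj[[1]], c(2L, 4L))
  # bin 5 = (f2, ch2): neighbors f1ch2 (4), f3ch2 (6), f2ch1 (2)
  expect_setequal(adj[[5]], c(4L, 6L, 2L))
  # no spatial neighbors: frequency chain only, per channel
  adj2 <- grid_adjacency(3, NULL, n_chan = 2)
  expect_setequal(adj2[[4]], 5L)
})
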