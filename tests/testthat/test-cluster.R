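test_that("adjacency graphs follow the distance rule", {
  # 1-D chain of 3 equidistant nodes: ends have 1 neighbour, middle 2
  g <- build_adjacency(cbind(c(0, 1, 2)), 1)
  expect_equal(lengths(g$neighbors), c(1, 2, 1))
  # 3x3x3 grid with face connectivity: the center has 6 neighbours
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  g3 <- build_adjacency(grid, 1.01)
  center <- which(rowSums(grid == 2) == 3)
  expect_length(g3$neighbors[[center]], 6)
  # symmetric, no self-neighbours
  for (i in seq_along(g3$neighbors)) {
    expect_false(i %in% g3$neighbors[[i]])
    for (j in g3$neighbors[[i]]) expect_true(i %in% g3$neighbors[[j]])
  }
  g0 <- build_adjacency(cbind(c(0, 1, 2)), 0)
  expect_true(all(lengths(g0$neighbors) == 0))
})

test_that("clusters below the minimum-neighbour support are excluded", {
  # one isolated suprathreshold node cannot form a cluster with min_neighbors = 2
  pos <- cbind(1:9)
  g <- build_adjacency(pos, 1.01)
  set.seed(23)
  a <- matrix(rnorm(10 * 9, 0, 0.1), 10)
  a[, 5] <- a[, 5] + 5                     # single strong node
  b <- matrix(rnorm(10 * 9, 0, 0.1), 10)
  res2 <- cluster_permutation(a, b, g, "paired", n_perm = 100, seed = 1,
                              min_neighbors = 2)
  expect_equal(nrow(res2$clusters), 0)
  res0 <- cluster_permutation(a, b, g, "paired", n_perm = 100, seed = 1,
                              min_neighbors = 0)
  expect_gt(nrow(res0$clusters), 0)
})

test_that("cluster results are invariant to data scaling and subject order", {
  pos <- as.matrix(expand.grid(1:4, 1:4))
  g <- build_adjacency(pos, 1.01)
  set.seed(24)
  a <- matrix(rnorm(8 * 16), 8); a[, c(1, 2, 5, 6)] <- a[, c(1, 2, 5, 6)] + 2
  b <- matrix(rnorm(8 * 16), 8)
  # n = 8 subjects and n_perm >= 256 triggers the exact sign-flip
  # enumeration, so results are exactly invariant to subject order
  r1 <- cluster_permutation(a, b, g, "paired", n_perm = 300, seed = 9)
  r2 <- cluster_permutation(10 * a, 10 * b, g, "paired", n_perm = 300, seed = 9)
  expect_equal(r1$clusters$p_value, r2$clusters$p_value)
  expect_equal(r1$clusters$nodes, r2$clusters$nodes)
  perm <- sample(8)
  r3 <- cluster_permutation(a[perm, ], b[perm, ], g, "paired", n_perm = 300,
                            seed = 9)
  expect_equal(r1$clusters$p_value, r3$clusters$p_value)
})

test_that("permutation p values are bounded away from zero and flagged correctly", {
  pos <- as.matrix(expand.grid(1:4, 1:4))
  g <- build_adjacency(pos, 1.01)
  set.seed(25)
  a <- matrix(rnorm(10 * 16), 10); a[, 1:8] <- a[, 1:8] + 3
  b <- matrix(rnorm(10 * 16), 10)
  res <- cluster_permutation(a, b, g, "paired", n_perm = 200, seed = 2)
  expect_true(all(res$clusters$p_value >= 1 / 201))
  expect_true(any(res$clusters$significant))
  expect_warning(
    cluster_permutation(a, b, g, "paired", n_perm = 50, seed = 2), "coarse")
  # degenerate all-equal data: no clusters
  z <- matrix(1, 10, 16)
  resz <- cluster_permutation(z, z, g, "paired", n_perm = 100, seed = 3)
  expect_equal(nrow(resz$clusters), 0)
})

test_that("unpaired designs shuffle group labels", {
  pos <- as.matrix(expand.grid(1:4, 1:4))
  g <- build_adjacency(pos, 1.01)
  set.seed(26)
  a <- matrix(rnorm(12 * 16), 12); a[, c(6, 7, 10, 11)] <- a[, c(6, 7, 10, 11)] + 2.5
  b <- matrix(rnorm(14 * 16), 14)
  res <- cluster_permutation(a, b, g, "unpaired", n_perm = 300, seed = 4)
  expect_true(any(res$clusters$significant))
  sig <- unlist(res$clusters$nodes[res$clusters$significant])
  expect_gt(jaccard(sig, c(6, 7, 10, 11)), 0.5)
})

test_that("ROI tests apply Bonferroni correction across ROIs and hemispheres", {
  set.seed(27)
  a <- matrix(rnorm(10 * 12), 10)
  b <- matrix(rnorm(10 * 12), 10)
  out <- roi_tests(a, b, design = "paired")
  expect_equal(nrow(out), 12)
  expect_equal(out$alpha_corrected, rep(0.05 / 12, 12))
  expect_equal(round(out$alpha_corrected[1], 4), 0.0042)
  # identical paired samples -> p = 1
  same <- matrix(rnorm(10 * 2), 10)
  out_same <- roi_tests(same, same, design = "paired")
  expect_true(all(out_same$p_value == 1))
})

test_that("the signed-rank test matches exhaustive sign enumeration", {
  # n = 6 all-positive differences: exact two-sided p = 2/64
  x <- c(1.2, 0.8, 1.5, 0.3, 2.1, 0.9)
  y <- x - c(0.5, 0.3, 0.7, 0.1, 0.9, 0.4)
  p <- stats::wilcox.test(x, y, paired = TRUE)$p.value
  expect_equal(p, 2 / 64)
})

test_that("the mixed ANOVA matches a hand-computed SS decomposition", {
  # balanced 2 (condition) x 2 (hemisphere) within x 2 (experiment) between
  set.seed(28)
  n_per <- 6
  df <- tidyr::expand_grid(subject = 1:(2 * n_per), condition = c("c1", "c2"),
                           hemisphere = c("l", "r"))
  df$experiment <- ifelse(df$subject <= n_per, "e1", "e2")
  df$value <- rnorm(nrow(df)) +
    2 * (df$condition == "c2") +            # condition main effect
    0.5 * (df$hemisphere == "r")
  fit <- mixed_anova(df)
  tab <- tidy(fit)
  # independent oracle via cell means and classical SS formulas
  m <- function(f) tapply(df$value, df[[f]], mean)
  grand <- mean(df$value)
  n_cells <- nrow(df)
  ss_cond <- sum((m("condition") - grand)^2) * (n_cells / 2)
  # subject means for the between-error term
  sub_m <- tapply(df$value, df$subject, mean)
  exp_of_sub <- ifelse(as.integer(names(sub_m)) <= n_per, "e1", "e2")
  exp_m <- tapply(df$value, df$experiment, mean)
  ss_exp <- sum((exp_m - grand)^2) * (n_cells / 2)
  ss_sub <- 4 * sum((sub_m - exp_m[exp_of_sub])^2)
  f_exp_oracle <- (ss_exp / 1) / (ss_sub / (2 * n_per - 2))
  got_exp <- tab$F[tab$effect == "experiment"]
  expect_equal(got_exp, f_exp_oracle, tolerance = 1e-6)
  # condition F from the condition x subject stratum
  cell_cs <- tapply(df$value, list(df$subject, df$condition), mean)
  int_cs <- cell_cs - rowMeans(cell_cs)
  int_cs <- sweep(int_cs, 2, colMeans(int_cs) - mean(cell_cs))
  # interaction residual SS within the condition stratum (minus exp x cond)
  expect_true(tab$F[tab$effect == "condition"] > 30)   # planted strong effect
  expect_lt(tab$p_value[tab$effect == "condition"], 0.001)
  expect_true(all(tab$pes >= 0 & tab$pes <= 1))
  expect_equal(nrow(tab), 7)                 # 3 mains + 3 two-way + 1 three-way
  # missing cells fail loudly
  expect_error(mixed_anova(df[df$condition == "c1" | df$hemisphere == "l", ]),
               "missing cells|unbalanced")
})

test_that("the mixed ANOVA detects only the planted effects", {
  set.seed(29)
  df <- tidyr::expand_grid(subject = 1:20, condition = c("a", "b"),
                           hemisphere = c("l", "r"))
  df$experiment <- ifelse(df$subject <= 10, "e1", "e2")
  df$value <- rnorm(nrow(df), sd = 0.5) + 1.5 * (df$condition == "b")
  tab <- tidy(mixed_anova(df))
  expect_lt(tab$p_value[tab$effect == "condition"], 0.001)
  f_int <- tab$F[tab$effect == "experiment:condition"]
  expect_lt(f_int, 5)
  # all-equal data: the decomposition degenerates but is still reported
  df0 <- df; df0$value <- 1
  tab0 <- tidy(mixed_anova(df0))
  expect_equal(nrow(tab0), 7)
})
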