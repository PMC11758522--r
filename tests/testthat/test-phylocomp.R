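test_that("PGLS on a star tree equals ordinary least squares exactly", {
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, 10)
  set.seed(3)
  x <- setNames(rnorm(10), star$tip.label)
  y <- setNames(1.5 * x + rnorm(10, 0, 0.4), star$tip.label)
  pg <- pgls_fit(star, x, y)
  ols <- lm(y ~ x)
  expect_equal(pg$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(pg$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(pg$se_slope, summary(ols)$coefficients[2, 2],
               tolerance = 1e-10)
  expect_equal(pg$r2, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("PGLS agrees with nlme::gls under Brownian correlation on a structured tree", {
  skip_if_not_installed("nlme")
  set.seed(12)
  tree <- ape::rcoal(15)   # ultrametric: corBrownian expresses exactly this
  x <- setNames(rnorm(15), tree$tip.label)
  y <- setNames(0.26 * x + rnorm(15, 0, 0.3), tree$tip.label)
  pg <- pgls_fit(tree, x, y)
  d <- data.frame(x = x, y = y, sp = tree$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tree, form = ~sp),
                 method = "REML")
  expect_equal(pg$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(pg$intercept, unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(pg$se_slope,
               unname(summary(g)$tTable[2, 2]), tolerance = 1e-6)
})

test_that("perfectly collinear traits give slope 2 with r2 = 1", {
  tree <- balanced_tree(8)
  x <- setNames(1:8 / 4, tree$tip.label)
  y <- 2 * x
  pg <- pgls_fit(tree, x, y)
  expect_equal(pg$slope, 2, tolerance = 1e-10)
  expect_equal(pg$r2, 1, tolerance = 1e-10)
})

test_that("tip-name matching normalizes case and separators", {
  star <- ape::stree(4, type = "star")
  star$tip.label <- c("Genus species", "B_b", "C c", "Dd")
  star$edge.length <- rep(1, 4)
  x <- c(genus_species = 1, b_b = 2, C_C = 3, DD = 4)
  y <- c(GENUS_SPECIES = 2, `b b` = 4, c_c = 6, dd = 8)
  pg <- pgls_fit(star, x, y)
  expect_equal(pg$slope, 2, tolerance = 1e-10)
})

test_that("phylogenetic ANCOVA on a star tree matches classical ANCOVA", {
  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(1, 12)
  set.seed(6)
  x <- setNames(rnorm(12), star$tip.label)
  g <- setNames(rep(c("m", "r"), each = 6), star$tip.label)
  y <- setNames(1 + 0.5 * x + 2 * (g == "r") + rnorm(12, 0, 0.3),
                star$tip.label)
  pa <- phylo_ancova(star, x, y, g)
  gf <- factor(g)
  full <- lm(y ~ gf + x + gf:x)
  comm <- lm(y ~ gf + x)
  xonly <- lm(y ~ x)
  expect_equal(pa$slope_test$F, anova(comm, full)$F[2], tolerance = 1e-8)
  expect_equal(pa$mean_test$F, anova(xonly, comm)$F[2], tolerance = 1e-8)
  ss_g <- sum(resid(xonly)^2) - sum(resid(comm)^2)
  expect_equal(pa$mean_test$partial_eta_sq,
               ss_g / (ss_g + sum(resid(comm)^2)), tolerance = 1e-8)
})

test_that("groups with identical data give null slope and mean tests", {
  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(1, 12)
  set.seed(14)
  xs <- rnorm(6); ys <- 2 * xs + rnorm(6, 0, 0.2)
  x <- setNames(rep(xs, 2), star$tip.label)
  y <- setNames(rep(ys, 2), star$tip.label)
  g <- setNames(rep(c("m", "r"), each = 6), star$tip.label)
  pa <- phylo_ancova(star, x, y, g)
  expect_equal(pa$slope_test$F, 0, tolerance = 1e-8)
  expect_equal(pa$mean_test$F, 0, tolerance = 1e-8)
  expect_gt(pa$slope_test$p, 0.99)
  expect_gt(pa$mean_test$p, 0.99)
})

test_that("offset intercepts with a common slope are detected by the mean test", {
  tree <- balanced_tree(16, depth = 1)
  hits_mean <- 0L; hits_slope <- 0L
  for (s in 1:10) {
    tr <- simulate_phylo_traits(tree, sigma2 = 0.05, seed = 700 + s)
    x <- setNames(rnorm(16), tree$tip.label)
    g <- setNames(rep(c("m", "r"), 8), tree$tip.label)
    noise <- setNames(tr$trait, tr$tip)
    y <- 0.5 * x + 1.5 * (g == "r") + noise[tree$tip.label]
    pa <- phylo_ancova(tree, x, y, g)
    if (pa$mean_test$p < 0.05) hits_mean <- hits_mean + 1L
    if (pa$slope_test$p < 0.05) hits_slope <- hits_slope + 1L
  }
  expect_gte(hits_mean, 9)
  expect_lte(hits_slope, 2)
})

test_that("pooled ANOVA matches hand computation and the F = t^2 identity", {
  av <- pooled_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(av$F, 13.5)
  expect_equal(av$cohens_d, 3)
  expect_equal(av$df1, 1)
  expect_equal(av$df2, 4)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
  set.seed(31)
  g1 <- rnorm(20, 5, 2); g2 <- rnorm(25, 6, 2)
  av2 <- pooled_anova(g1, g2)
  t2 <- t.test(g2, g1, var.equal = TRUE)
  expect_equal(av2$F, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(sign(av2$cohens_d), sign(mean(g2) - mean(g1)))
  expect_true(all(is.finite(av2$shapiro$W)))
  # identical groups: F = 0; zero pooled variance errors
  expect_equal(pooled_anova(c(1, 2, 3), c(1, 2, 3))$F, 0)
  expect_error(pooled_anova(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("exponential-BM data prefers the exponential-BM model", {
  set.seed(50)
  tree <- ape::rtree(18)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  wins <- 0L; n_rep <- 5L
  for (s in 1:n_rep) {
    x <- setNames(runif(18, 0, 3), tree$tip.label)
    bm <- simulate_phylo_traits(tree, sigma2 = 0.05, seed = 900 + s)
    noise <- setNames(bm$trait, bm$tip)
    y <- 0.4 * exp(0.9 * x) + 1 + noise[tree$tip.label]
    cmp <- pgnlr_compare(tree, x, y, n_abc = 0, seed = s)
    if (cmp$best %in% c("OUGBM", "OUGOU")) wins <- wins + 1L
  }
  expect_gte(wins, 4)
})

test_that("ABC comparison returns posterior probabilities summing to 1", {
  set.seed(77)
  tree <- ape::rtree(10)
  x <- setNames(runif(10, 0, 2), tree$tip.label)
  y <- setNames(2 + 0.5 * x + rnorm(10, 0, 0.2), tree$tip.label)
  cmp <- pgnlr_compare(tree, x, y, n_abc = 50, seed = 2)
  expect_equal(sum(cmp$table$posterior), 1, tolerance = 1e-9)
  expect_true(all(cmp$table$posterior >= 0))
})

test_that("singular covariance from duplicated zero-length tips errors with guidance", {
  tree <- ape::read.tree(text = "((A:0,B:0):1,C:1);")
  x <- c(A = 1, B = 2, C = 3); y <- c(A = 1, B = 2, C = 3)
  expect_error(pgls_fit(tree, x, y), "singular")
})
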