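test_that("constant patch yields zero amplitude and flagged scale measures", {
  f <- compute_features(matrix(128, 20, 20))
  expect_equal(unname(f["Sa"]), 0)
  expect_equal(unname(f["Sq"]), 0)
  expect_equal(unname(f["Sz"]), 0)
  expect_true(is.nan(f["Ssk"]))
  expect_true(is.nan(f["Str"]))
  expect_true(attr(f, "degenerate"))
  expect_length(f, 21)
  expect_named(f, texture_measures())
})

test_that("horizontal sinusoid bands are strongly anisotropic with direction 0", {
  z <- matrix(rep(100 + 60 * sin(2 * pi * (1:64) / 8), 64), 64, 64)
  f <- compute_features(z)
  expect_lt(unname(f["Str"]), 0.2)
  expect_lt(min(unname(f["Std"]) %% 180, 180 - unname(f["Std"]) %% 180), 10)
  # vertical bands rotate the direction by 90
  fv <- compute_features(t(z))
  expect_lt(abs(unname(fv["Std"]) - 90), 10)
})

test_that("i.i.d. Gaussian patches are near-isotropic with near-zero skewness", {
  sk <- numeric(6); str <- numeric(6)
  for (s in 1:6) {
    set.seed(400 + s)
    z <- matrix(rnorm(48 * 48, 128, 10), 48, 48)
    f <- compute_features(z)
    sk[s] <- f["Ssk"]; str[s] <- f["Str"]
  }
  se_skew <- sqrt(6 / (48 * 48))
  expect_lt(abs(mean(sk)), 3 * se_skew)
  expect_gt(mean(str), 0.6)
})

test_that("amplitude measures are offset-invariant and Sq scales linearly", {
  set.seed(5)
  z <- matrix(runif(32 * 32, 40, 200), 32, 32)
  f1 <- compute_features(z)
  f2 <- compute_features(z + 30)
  amp <- c("Sa", "Sq", "Ssk", "Sku", "Sp", "Sv", "Sz")
  expect_equal(f1[amp], f2[amp], tolerance = 1e-12)
  f3 <- compute_features((z - mean(z)) * 2 + mean(z))
  expect_equal(unname(f3["Sq"]), 2 * unname(f1["Sq"]), tolerance = 1e-12)
  expect_equal(unname(f3["Sk"]), 2 * unname(f1["Sk"]), tolerance = 1e-9)
})

test_that("juvenile/adult subsampling equalizes patch sizes and excludes boundary layers", {
  sch <- growth_schedule("linear", c(10, 0), 10)
  rt <- render_cementum(clean_spec(sch, rows = 130, cols = 100, seed = 2))
  reg <- rt$image
  pk <- detect_peaks(extract_transects(
    trim_region(reg, rt$ground_truth$hyaline_um,
                rt$ground_truth$fringe_start_um))[[1]])
  ps <- subsample_patches(reg, cutoff_year = 5, pk)
  expect_equal(nrow(ps$juvenile$pixels), nrow(ps$adult$pixels))
  expect_equal(ncol(ps$juvenile$pixels), ncol(ps$adult$pixels))
  # width is twice the radial length unless clamped
  expect_equal(ncol(ps$juvenile$pixels),
               min(2 * nrow(ps$juvenile$pixels), ncol(reg$pixels)))
  expect_error(subsample_patches(reg, 20, pk), "outside recorded years")
  # asymmetric split: shared radial length is the shorter side
  ps2 <- subsample_patches(reg, cutoff_year = 3, pk)
  expect_lt(nrow(ps2$juvenile$pixels) * reg$voxel_size_um,
            3 * 10 + 1)
})

test_that("ANOVA screening retains only measures significant in every dataset", {
  # hand-checked one-way ANOVA: {1,2,3} vs {4,5,6} has F = 13.5
  av <- pooled_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(av$F, 13.5)
  set.seed(21)
  mkds <- function(shifted) {
    n <- 6
    data.frame(
      stage = rep(c("juvenile", "adult"), each = n),
      good = c(rnorm(n, 0, 0.3), rnorm(n, 5, 0.3)),
      flat = rnorm(2 * n, 0, 1),
      const = rep(1, 2 * n))
  }
  ds <- list(a = mkds(TRUE), b = mkds(TRUE))
  expect_message(keep <- screen_measures(ds), "zero variance")
  expect_true("good" %in% keep)
  expect_false("flat" %in% keep)
  expect_false("const" %in% keep)
  # significant in one dataset only -> dropped
  ds$b$good <- rnorm(12, 0, 1)
  keep2 <- suppressMessages(screen_measures(ds))
  expect_false("good" %in% keep2)
})

test_that("texture PCA gives orthonormal loadings and complete reconstruction", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- paste0("m", 1:5)
  sp <- texture_pca(X)
  L <- sp$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(sp$var_explained), 1, tolerance = 1e-10)
  Z <- scale(X)
  expect_equal(sp$scores %*% t(L), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # two perfectly correlated measures load on a single component
  X2 <- cbind(a = X[, 1], b = 2 * X[, 1])
  sp2 <- suppressMessages(texture_pca(X2))
  expect_equal(sp2$var_explained[1], 1, tolerance = 1e-10)
})

test_that("hull overlap is 0 for disjoint clusters and 1 for identical sets", {
  sq <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  far <- sq + 10
  pts <- rbind(sq, far)
  hs <- hull_separation(pts, rep(c("j", "a"), each = 5))
  expect_equal(hs$overlap, 0)
  expect_true(hs$distinct)
  same <- rbind(sq, sq)
  hs2 <- hull_separation(same, rep(c("j", "a"), each = 5))
  expect_equal(hs2$overlap, 1, tolerance = 1e-9)
  expect_false(hs2$distinct)
  # known partial overlap: unit squares shifted by half
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 0.5
  hs3 <- hull_separation(rbind(sq, sq2), rep(c("j", "a"), each = 5))
  expect_equal(hs3$overlap, 0.5 / 1.5, tolerance = 1e-9)
  # collinear degenerate input falls back to segment overlap
  line <- cbind(1:4, 1:4)
  hs4 <- hull_separation(rbind(line, line + 10),
                         rep(c("j", "a"), each = 4))
  expect_true(hs4$degenerate)
  expect_true(hs4$distinct)
})

test_that("a maturity texture shift separates juvenile and adult texture space", {
  sch <- growth_schedule("linear", c(10, -0.2), 10)
  run_cohort <- function(shift, seed) {
    feats <- list(); stages <- character(0)
    for (i in 1:8) {
      sp <- synthetic_spec(sch,
                          texture_params(0.55, 2, 8,
                                         juvenile_adult_shift = shift),
                          maturity_year = 5,
                          image_shape = c(130, 110), seed = seed * 100 + i)
      out <- render_cementum(sp)
      pk <- detect_peaks(extract_transects(
        trim_region(out$image, out$ground_truth$hyaline_um,
                    out$ground_truth$fringe_start_um))[[1]])
      ps <- tryCatch(subsample_patches(out$image, 5, pk),
                     error = function(e) NULL)
      if (is.null(ps)) next
      for (st in c("juvenile", "adult")) {
        f <- compute_features(ps[[st]])
        feats[[length(feats) + 1]] <- f
        stages <- c(stages, st)
      }
    }
    X <- do.call(rbind, feats)
    ok <- apply(X, 2, function(v) all(is.finite(v)) && var(v) > 0)
    hs <- hull_separation(suppressMessages(texture_pca(X[, ok])), stages)
    hs$distinct
  }
  strong <- list(contrast = 0.25, anisotropy = 8, noise_sd = -6)
  expect_true(run_cohort(strong, seed = 1))
  expect_false(run_cohort(NULL, seed = 1))
})
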