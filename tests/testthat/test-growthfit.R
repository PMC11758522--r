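test_that("exact quadratic data is interpolated with r2 = 1", {
  t <- 1:10
  y <- 9 + 0.5 * t - 0.12 * t^2
  fits <- fit_models(list(t = t, y = y), families = "quadratic")
  f <- fits$quadratic
  expect_true(f$converged)
  expect_equal(f$params, c(9, 0.5, -0.12), tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("flat series fits linear/quadratic with near-zero slope", {
  t <- 1:8; y <- rep(5, 8) + c(1, -1, 1, -1, 1, -1, 1, -1) * 1e-9
  fits <- fit_models(list(t = t, y = y),
                     families = c("linear", "quadratic"))
  expect_lt(abs(fits$linear$params[2]), 1e-8)
  expect_lt(abs(fits$quadratic$params[3]), 1e-8)
})

test_that("families with too few points are skipped with a notice", {
  t <- 1:4; y <- c(8, 7, 5, 2)
  expect_message(fits <- fit_models(list(t = t, y = y),
                                    families = c("hill_sigmoid", "linear")),
                 "skipped")
  expect_null(fits$hill_sigmoid)
  expect_true(fits$linear$converged)
})

test_that("selection takes lowest AIC with r2 breaking near-ties", {
  mk <- function(fam, aic, r2) structure(
    list(family = fam, aic = aic, r2 = r2, converged = TRUE,
         params = 1, rss = 1, n = 10, fitted = 1),
    class = "growth_model_fit")
  expect_equal(select_best(list(mk("a", 10, 0.9), mk("b", 20, 0.99)))$family,
               "a")
  # delta AIC < 2: the higher r2 wins
  sel <- select_best(list(mk("a", 10.5, 0.99), mk("b", 10.0, 0.90)))
  expect_equal(sel$family, "a")
  expect_equal(sel$runner_up, "b")
  one <- select_best(list(mk("only", 5, 0.5)))
  expect_equal(one$family, "only")
  expect_error(select_best(list(structure(list(converged = FALSE),
                                          class = "growth_model_fit"))),
               "no converged")
})

test_that("hill-sigmoid data at realistic msGR scale selects a sigmoid-compatible model", {
  # decreasing-sigmoid generating process, noise SD 0.5, msGR ~4-12
  wins <- 0L
  n_rep <- 12L
  for (s in seq_len(n_rep)) {
    set.seed(300 + s)
    t <- 1:11
    y <- eval_family("hill_sigmoid", c(11, 4.5, 5, 5), t) + rnorm(11, 0, 0.5)
    fits <- fit_models(list(t = t, y = y), n_starts = 12, seed = s)
    best <- select_best(fits)
    aics <- vapply(Filter(function(f) isTRUE(f$converged), fits),
                   function(f) f$aic, numeric(1))
    sig_ok <- best$family %in% c("hill_sigmoid", "logistic") ||
      (("hill_sigmoid" %in% names(aics)) &&
         aics[["hill_sigmoid"]] - min(aics) < 2)
    if (sig_ok) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("AIC ordering is invariant to a consistent affine year rescale", {
  set.seed(11)
  t <- 1:10
  y <- eval_family("gaussian", c(10, 2, 4), t) + rnorm(10, 0, 0.3)
  f1 <- fits_table(fit_models(list(t = t, y = y),
                              families = c("linear", "quadratic",
                                           "logarithmic")))
  # affine rescale of the year axis (logarithmic dropped: not closed
  # under affine maps)
  t2 <- 2 * t + 3
  f2 <- fits_table(fit_models(list(t = t2, y = y),
                              families = c("linear", "quadratic",
                                           "logarithmic")))
  o1 <- f1$family[f1$family != "logarithmic"]
  o2 <- f2$family[f2$family != "logarithmic"]
  expect_equal(o1, o2)
})

test_that("truncation window matches the exhaustive-window oracle", {
  # frozen example: steepest drop 8->5, theta = 0.8 excludes the 5->3 drop
  tw <- find_truncation(list(year = 1:6, y = c(8, 8, 8, 5, 3, 3)))
  expect_false(tw$none)
  expect_equal(c(tw$min_age, tw$max_age),
               unname(oracle_truncation(1:6, c(8, 8, 8, 5, 3, 3))))
  expect_equal(c(tw$min_age, tw$max_age), c(3, 4))
  # a smaller theta admits the second drop and widens the window
  tw2 <- find_truncation(list(year = 1:6, y = c(8, 8, 8, 5, 3, 3)),
                         theta = 2 / 3)
  expect_equal(c(tw2$min_age, tw2$max_age), c(3, 5))
  # random series of length <= 12 agree with the oracle
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- round(cumsum(rnorm(n, -0.3, 1.5)) + 10, 2)
    tw <- find_truncation(list(year = 1:n, y = y))
    oc <- oracle_truncation(1:n, y)
    if (is.null(oc)) {
      expect_true(tw$none)
    } else {
      expect_equal(c(tw$min_age, tw$max_age), unname(oc))
    }
  }
})

test_that("monotone non-decreasing series has no truncation; linear decline flags non-sigmoidal", {
  tw <- find_truncation(list(year = 1:5, y = c(3, 4, 5, 6, 7)))
  expect_true(tw$none)
  lin <- find_truncation(list(year = 1:6, y = c(10, 8, 6, 4, 2, 0)))
  expect_false(lin$none)
  expect_true(lin$non_sigmoidal)
  expect_equal(c(lin$min_age, lin$max_age), c(1, 6))
})

test_that("maturity range shifts the window by the calibration offsets", {
  w <- structure(list(none = FALSE, min_age = 5, max_age = 7),
                 class = "truncation_window")
  m0 <- maturity_range(w, offsets = c(0, 0))
  expect_equal(c(m0$min_age, m0$max_age), c(5, 7))
  m1 <- maturity_range(w, offsets = c(-1, 1))
  expect_equal(c(m1$min_age, m1$max_age), c(4, 8))
  expect_error(maturity_range(w, numeric(0)), "empty")
  expect_equal(maturity_offsets(c(2, 3), c(1, 4)), c(1, -1))
  # offsets recovered exactly from noise-free synthetic extant series
  sch <- growth_schedule("hill_sigmoid", c(12, 4, 5, 6), 10)
  y <- schedule_widths(sch)
  tw <- find_truncation(list(year = 1:10, y = y))
  known_maturity <- 5
  expect_equal(maturity_offsets(known_maturity, tw$min_age),
               known_maturity - tw$min_age)
})
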