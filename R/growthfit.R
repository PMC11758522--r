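#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# Start-value boxes per family, scaled to the data; rows are parameters,
# columns lower/upper.
.start_box <- function(family, t, y) {
  ry <- max(diff(range(y)), 1e-6)
  ymin <- min(y); ymax <- max(y)
  tmin <- min(t); tmax <- max(t); tr <- max(tmax - tmin, 1)
  switch(family,
    gaussian = rbind(a = c(0.5 * ymax, 2 * ymax),
                     b = c(tmin - tr, tmax),
                     c = c(0.5, 3 * tr)),
    exponential = rbind(a = c(0.1 * ry, 5 * ry),
                        b = c(-2, -0.01),
                        c = c(ymin - ry, ymax)),
    hill_sigmoid = rbind(a = c(ymax - 0.25 * ry, ymax + ry),
                         c = c(ymin - ry, ymin + 0.25 * ry),
                         e = c(tmin, 1.5 * tmax),
                         h = c(0.5, 12)),
    von_bertalanffy = rbind(a = c(0.5 * ymin, 2 * ymax),
                            b = c(-3, 3),
                            k = c(0.05, 2)),
    logistic = rbind(a = c(0.8 * ymax, 3 * ymax),
                     b = c(-3, 3),
                     c = c(tmin, tmax)),
    gompertz = rbind(a = c(0.5 * ymax, 3 * ymax),
                     b = c(0.01, 5),
                     k = c(-2, 2)),
    power = rbind(a = c(0.1 * abs(y[1]), 3 * ymax),
                  b = c(-3, 3)),
    stop("no start box for family ", family))
}

.fit_linear_family <- function(family, t, y) {
  X <- switch(family,
    linear      = cbind(1, t),
    quadratic   = cbind(1, t, t^2),
    logarithmic = cbind(1, log(t)))
  fit <- stats::lm.fit(X, y)
  params <- unname(fit$coefficients)
  fitted <- as.numeric(X %*% params)
  list(params = params, fitted = fitted, converged = TRUE)
}

.fit_nls_family <- function(family, t, y, n_starts, seed) {
  box <- .start_box(family, t, y)
  p <- nrow(box)
  U <- with_local_seed(seed, lhs::randomLHS(n_starts, p))
  starts <- sweep(sweep(U, 2, box[, 2] - box[, 1], "*"), 2, box[, 1], "+")
  pn <- rownames(box)
  form <- switch(family,
    gaussian        = y ~ a * exp(-(t - b)^2 / (2 * c^2)),
    exponential     = y ~ a * exp(b * t) + c,
    hill_sigmoid    = y ~ c + (a - c) / (1 + (t / e)^h),
    von_bertalanffy = y ~ a * (1 - b * exp(-k * t)),
    logistic        = y ~ a / (1 + exp(b * (t - c))),
    gompertz        = y ~ a * exp(-b * exp(-k * t)),
    power           = y ~ a * t^b)
  lower <- switch(family,
    hill_sigmoid = c(a = -Inf, c = -Inf, e = 1e-6, h = 1e-3),
    gaussian = c(a = -Inf, b = -Inf, c = 1e-3),
    power = c(a = 1e-9, b = -Inf),
    rep(-Inf, p))
  dat <- data.frame(t = t, y = y)
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- as.list(starts[i, ]); names(st) <- pn
    fit <- tryCatch(
      suppressWarnings(nlsLM(form, data = dat, start = st, lower = lower,
                             control = nls.lm.control(maxiter = 200,
                                                      ftol = 1e-9))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(list(converged = FALSE))
  cf <- stats::coef(best$fit)
  list(params = unname(cf[pn]), fitted = as.numeric(stats::fitted(best$fit)),
       converged = TRUE)
}

#' Fit candidate growth models to a per-year growth series
#'
#' Fits each family by least squares (exact linear algebra for the
#' linear-in-parameters families, Levenberg-Marquardt with seeded
#' Latin-hypercube multistart otherwise) and scores each fit with
#' `AIC = n * ln(RSS / n) + 2k` (k = number of curve parameters + 1 for
#' the error variance) and `r2 = 1 - RSS/TSS`.
#'
#' @param series A `taxon_growth_series` data frame (columns `year` and
#'   `msgr` or `mean_width_um`), or a list/data.frame with `t` and `y`.
#' @param families Character vector of families (default all 10).
#' @param n_starts Multistart count per nonlinear family (default 20).
#' @param seed Seed for the multistart design.
#' @return List of `growth_model_fit` objects (family, params, rss, aic,
#'   r2, fitted, converged, n). Families with fewer data points than
#'   parameters + 1 are skipped with a message.
#' @export
fit_models <- function(series, families = growth_families(),
                       n_starts = 20L, seed = 1L) {
  if (is.data.frame(series) && "year" %in% names(series)) {
    t <- series$year
    y <- if ("msgr" %in% names(series)) series$msgr else series$mean_width_um
  } else {
    t <- series$t; y <- series$y
  }
  stopifnot(length(t) == length(y), length(t) >= 3)
  families <- match.arg(families, growth_families(), several.ok = TRUE)
  n <- length(t)
  fits <- list()
  for (fam in families) {
    p <- .family_npar[[fam]]
    if (n < p + 1) {
      message(sprintf("family '%s' skipped: %d points < %d parameters + 1",
                      fam, n, p))
      next
    }
    res <- if (fam %in% c("linear", "quadratic", "logarithmic")) {
      .fit_linear_family(fam, t, y)
    } else {
      .fit_nls_family(fam, t, y, n_starts, seed)
    }
    if (!isTRUE(res$converged)) {
      fits[[fam]] <- structure(list(family = fam, converged = FALSE),
                               class = "growth_model_fit")
      next
    }
    rss <- sum((y - res$fitted)^2)
    tss <- sum((y - mean(y))^2)
    k <- p + 1
    aic <- n * log(max(rss, 1e-300) / n) + 2 * k
    fits[[fam]] <- structure(list(
      family = fam, params = res$params, n = n, rss = rss,
      aic = aic, r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      fitted = res$fitted, converged = TRUE),
      class = "growth_model_fit")
  }
  fits
}

#' Select the best growth model fit
#'
#' Lowest AIC wins; when the top two fits are within 2 AIC units the tie
#' goes to the higher r-squared. Non-converged fits are excluded.
#'
#' @param fits List of `growth_model_fit` (from [fit_models()]).
#' @return The winning `growth_model_fit`, with `runner_up` (family) and
#'   `delta_aic` (winner vs runner-up) attached.
#' @export
select_best <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(ok)) stop("no converged fits to select from", call. = FALSE)
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  o <- order(aics)
  best <- ok[[o[1]]]
  if (length(ok) >= 2) {
    second <- ok[[o[2]]]
    if (aics[o[2]] - aics[o[1]] < 2 &&
        isTRUE(second$r2 > best$r2)) {
      tmp <- best; best <- second; second <- tmp
    }
    best$runner_up <- second$family
    best$delta_aic <- abs(second$aic - best$aic)
  } else {
    best$runner_up <- NA_character_
    best$delta_aic <- NA_real_
  }
  best
}

#' Summarize a list of growth-model fits as a table
#' @param fits List from [fit_models()].
#' @return Data frame: family, n_params, rss, aic, delta_aic, r2,
#'   converged; sorted by AIC.
#' @export
fits_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (!isTRUE(f$converged)) {
      return(data.frame(family = f$family, n_params = NA_integer_,
                        rss = NA_real_, aic = NA_real_, r2 = NA_real_,
                        converged = FALSE))
    }
    data.frame(family = f$family, n_params = length(f$params),
               rss = f$rss, aic = f$aic, r2 = f$r2, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  rownames(out) <- NULL
  out
}

#' Locate the growth-rate truncation window
#'
#' Computes consecutive-year msGR differences `d[t] = y[t+1] - y[t]` and
#' finds the maximal contiguous run of steep declines: years whose
#' difference is within a factor `theta` of the most negative
#' difference (`d[t] <= theta * min(d)`), restricted to the run
#' containing the minimum. The window start is the first year of the
#' run; the window end is one year past the last.
#'
#' @param series `taxon_growth_series` data frame or list with `year`
#'   and `msgr` (or `y`).
#' @param theta Steepness fraction in (0, 1]; default 0.8.
#' @return A `truncation_window` list: `min_age`, `max_age`,
#'   `slope_sequence`, `non_sigmoidal` (`TRUE` when every decline
#'   qualifies, e.g. a strictly linear fall), or `none = TRUE` for a
#'   monotone non-decreasing series.
#' @export
find_truncation <- function(series, theta = 0.8) {
  if (is.data.frame(series) && "year" %in% names(series)) {
    years <- series$year
    y <- if ("msgr" %in% names(series)) series$msgr else series$mean_width_um
  } else {
    years <- series$year %||% seq_along(series$y); y <- series$y
  }
  stopifnot(length(y) >= 4, theta > 0, theta <= 1)
  o <- order(years); years <- years[o]; y <- y[o]
  d <- diff(y)
  if (min(d) >= 0) {
    return(structure(list(none = TRUE, slope_sequence = d),
                     class = "truncation_window"))
  }
  elig <- d <= theta * min(d)
  imin <- which.min(d)
  a <- imin; while (a > 1 && elig[a - 1]) a <- a - 1L
  b <- imin; while (b < length(d) && elig[b + 1]) b <- b + 1L
  structure(list(none = FALSE,
                 min_age = years[a], max_age = years[b] + 1L,
                 slope_sequence = d,
                 non_sigmoidal = all(elig)),
            class = "truncation_window")
}

#' Age-at-maturity range from a truncation window
#'
#' Maps the growth-rate truncation window to a sexual-maturity age range
#' using offsets (maturity age minus truncation onset age) calibrated on
#' extant taxa; the result is floored at 0.
#'
#' @param window A `truncation_window` from [find_truncation()].
#' @param offsets Numeric vector of extant calibration offsets (years).
#' @return A `maturity_estimate` list: `min_age`, `max_age`, `offsets`.
#' @export
maturity_range <- function(window, offsets) {
  stopifnot(inherits(window, "truncation_window"))
  if (isTRUE(window$none)) {
    stop("no truncation window: maturity range undefined", call. = FALSE)
  }
  if (!length(offsets)) stop("empty calibration offsets", call. = FALSE)
  structure(list(min_age = max(0, window$min_age + min(offsets)),
                 max_age = max(0, window$max_age + max(offsets)),
                 offsets = offsets),
            class = "maturity_estimate")
}

#' Calibration offsets from extant maturity and truncation data
#'
#' @param maturity_years Known ages at sexual maturity (one per taxon).
#' @param truncation_min_age Truncation-onset ages for the same taxa.
#' @return Numeric vector of offsets `maturity - truncation onset`.
#' @export
maturity_offsets <- function(maturity_years, truncation_min_age) {
  stopifnot(length(maturity_years) == length(truncation_min_age))
  maturity_years - truncation_min_age
}
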