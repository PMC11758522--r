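#' Validation studies over synthetic cohorts
#'
#' These functions run the package's end-to-end validation studies:
#' each generates synthetic data with known ground truth, runs the
#' corresponding analysis stage, and reports recovery statistics. They
#' back the analysis scripts and the acceptance checks.
#'
#' @name validation_studies
#' @keywords internal
NULL

# One realistic decreasing-schedule parameterization per family, at the
# scale of the measured fossil/extant series (first-year widths ~9-12
# um, declining through life).
.study_family_params <- function() {
  list(quadratic = c(10, -0.35, -0.02),
       gaussian = c(10, 1, 6),
       exponential = c(8, -0.25, 3),
       hill_sigmoid = c(12, 4, 5, 4),
       von_bertalanffy = c(5, -1.5, 0.4),
       logistic = c(12, 0.35, 10),
       gompertz = c(12, 0.05, -0.3),
       linear = c(10, -0.5),
       power = c(10, -0.35),
       logarithmic = c(10, -2.2))
}

#' Life-span and width recovery over a synthetic specimen sample
#'
#' Renders `n_specimens` synthetic cementum images with schedules drawn
#' across the ten growth families, life spans of 6-12 years, and a
#' repeating additive-noise ladder (SD 0, 4, 8, 12 gray levels), then
#' measures each specimen with the transect/peak pipeline and compares
#' consensus growth-layer-group counts and per-year widths to ground
#' truth.
#'
#' @param n_specimens Number of specimens (default 100).
#' @param seed Integer seed.
#' @return List: `lifespan_within1_pct` (specimens whose consensus count
#'   is within +/-1 year of truth), `exact_pct`, `width_within1vox_pct`
#'   (widths within 1 voxel of the true spacing, zero-noise specimens),
#'   `noise_levels`, `n`.
#' @export
study_increment_recovery <- function(n_specimens = 100L, seed = 1L) {
  fams <- growth_families()
  pars <- .study_family_params()
  noise_ladder <- c(0, 4, 8, 12)
  ok1 <- logical(n_specimens); exact <- logical(n_specimens)
  wdev <- list()
  with_local_seed(seed, {
    for (i in seq_len(n_specimens)) {
      fam <- fams[(i - 1L) %% length(fams) + 1L]
      ny <- sample(6:12, 1)
      bw <- runif(1, 9, 12)
      ns <- noise_ladder[(i - 1L) %% length(noise_ladder) + 1L]
      sch <- growth_schedule(fam, pars[[fam]], ny, base_width_um = bw)
      sp <- synthetic_spec(sch,
                           texture_params(runif(1, 0.55, 0.8),
                                          runif(1, 10, 50), ns),
                           voxel_size_um = 1,
                           image_shape = c(ceiling(sum(schedule_widths(sch))) + 12L,
                                           96L),
                           seed = sample.int(1e6, 1))
      out <- render_cementum(sp)
      gt <- out$ground_truth
      reg <- trim_region(out$image, gt$hyaline_um, gt$fringe_start_um)
      series <- measure_region(reg)
      cons <- specimen_lifespan(series)$lifespan_years
      ok1[i] <- abs(cons - ny) <= 1
      exact[i] <- cons == ny
      if (ns == 0) {
        w <- series[[1]]$widths_um
        k <- min(length(w), length(gt$widths_um))
        if (k > 0) wdev[[length(wdev) + 1]] <-
            abs(w[seq_len(k)] - gt$widths_um[seq_len(k)])
      }
    }
  })
  dev <- unlist(wdev)
  list(lifespan_within1_pct = 100 * mean(ok1),
       exact_pct = 100 * mean(exact),
       width_within1vox_pct = 100 * mean(dev <= 1),
       max_width_dev_vox = max(dev),
       noise_levels = noise_ladder, n = n_specimens)
}

#' Growth-model selection rate under a known generating family
#'
#' Simulates per-year msGR series from a generating family at the scale
#' of the measured taxa (values ~4-12, up to 12 years, Gaussian noise
#' SD 0.5), fits all ten families, and scores a replicate as a success
#' when the generating family is selected or lies within 2 AIC units of
#' the winner.
#'
#' @param generating Family name.
#' @param params Generating parameters (defaults: the crown-mammal-like
#'   Hill sigmoid `c(11, 4.5, 5, 5)` over 11 years, or the
#'   mammaliaform-like quadratic `c(5.6, -0.05, -0.012)` over 9 years).
#' @param n_years Series length.
#' @param noise_sd Noise SD (default 0.5).
#' @param n_rep Replicates (default 50).
#' @param seed Seed.
#' @return List: `selection_pct`, `win_pct` (outright wins), `n`.
#' @export
study_model_selection <- function(generating = "hill_sigmoid",
                                  params = NULL, n_years = NULL,
                                  noise_sd = 0.5, n_rep = 50L,
                                  seed = 1L) {
  defaults <- list(hill_sigmoid = list(p = c(11, 4.5, 5, 5), ny = 11L),
                   quadratic = list(p = c(5.6, -0.05, -0.012), ny = 12L))
  if (is.null(params)) params <- defaults[[generating]]$p
  if (is.null(n_years)) n_years <- defaults[[generating]]$ny
  sig_like <- c("hill_sigmoid", "logistic")
  ok <- logical(n_rep); won <- logical(n_rep)
  with_local_seed(seed, {
    for (r in seq_len(n_rep)) {
      t <- seq_len(n_years)
      y <- eval_family(generating, params, t) + rnorm(n_years, 0, noise_sd)
      fits <- fit_models(list(t = t, y = y), n_starts = 20,
                         seed = sample.int(1e6, 1))
      conv <- Filter(function(f) isTRUE(f$converged), fits)
      aics <- vapply(conv, function(f) f$aic, numeric(1))
      best <- select_best(fits)$family
      won[r] <- best == generating ||
        (generating %in% sig_like && best %in% sig_like)
      ok[r] <- won[r] ||
        (generating %in% names(aics) &&
           aics[[generating]] - min(aics) < 2)
    }
  })
  list(selection_pct = 100 * mean(ok), win_pct = 100 * mean(won),
       n = n_rep)
}

#' Juvenile/adult texture discrimination rate over synthetic cohorts
#'
#' Simulates cohorts of specimens with (or without) a juvenile-to-adult
#' texture shift at the maturity year — adult cementum rendered with
#' higher contrast, greater anisotropy and less grayscale noise — then
#' runs the texture pipeline (patch subsampling, 21 measures, PCA,
#' convex-hull comparison in PC1-PC2) and reports how often the two
#' stages occupy distinct texture space.
#'
#' @param shift `TRUE` for therian-like cohorts (stage shift on),
#'   `FALSE` for mammaliaform-like cohorts (no shift).
#' @param n_cohorts Number of cohorts (default 50).
#' @param n_specimens Specimens per cohort (default 8).
#' @param seed Seed.
#' @return List: `distinct_pct`, `mean_overlap`, `n`.
#' @export
study_texture_discrimination <- function(shift = TRUE, n_cohorts = 50L,
                                         n_specimens = 8L, seed = 1L) {
  delta <- if (shift) list(contrast = 0.25, anisotropy = 8,
                           noise_sd = -6) else NULL
  distinct <- logical(n_cohorts); overlaps <- numeric(n_cohorts)
  with_local_seed(seed, {
    for (cc in seq_len(n_cohorts)) {
      feats <- list(); stages <- character(0)
      for (i in seq_len(n_specimens)) {
        # specimens vary in growth and image quality, as real cohorts do
        sch <- growth_schedule("linear", c(10, -0.2), 10,
                               base_width_um = runif(1, 9, 11))
        sp <- synthetic_spec(sch,
                             texture_params(runif(1, 0.45, 0.65),
                                            runif(1, 1, 3),
                                            runif(1, 6, 10),
                                            juvenile_adult_shift = delta),
                             maturity_year = 5,
                             image_shape = c(140L, 110L),
                             seed = sample.int(1e6, 1))
        out <- render_cementum(sp)
        gt <- out$ground_truth
        pk <- detect_peaks(extract_transects(
          trim_region(out$image, gt$hyaline_um, gt$fringe_start_um))[[1]])
        ps <- tryCatch(subsample_patches(out$image, 5, pk),
                       error = function(e) NULL)
        if (is.null(ps) || nrow(ps$juvenile$pixels) < 16) next
        for (st in c("juvenile", "adult")) {
          feats[[length(feats) + 1]] <- compute_features(ps[[st]])
          stages <- c(stages, st)
        }
      }
      X <- do.call(rbind, feats)
      keep <- apply(X, 2, function(v) all(is.finite(v)) && var(v) > 0)
      hs <- hull_separation(
        suppressMessages(texture_pca(X[, keep, drop = FALSE])), stages)
      distinct[cc] <- hs$distinct
      overlaps[cc] <- hs$overlap
    }
  })
  list(distinct_pct = 100 * mean(distinct),
       mean_overlap = mean(overlaps), n = n_cohorts)
}

#' PGLS star-tree exactness and Brownian confidence-interval coverage
#'
#' Two checks of the PGLS implementation: (1) on star phylogenies the
#' fit must equal ordinary least squares (maximum absolute deviation of
#' slope/intercept/SE over replicate datasets); (2) on a structured
#' tree with data simulated under the fitted model (Brownian residuals
#' around a linear trend with slope 0.26, the body-mass/life-span
#' allometry scale), the 95% CI for the slope must cover the truth at
#' its nominal rate.
#'
#' @param n_rep Coverage replicates (default 200).
#' @param n_tips Tips in the simulation tree (default 30).
#' @param seed Seed.
#' @return List: `star_max_abs_dev`, `coverage_pct`, `n`.
#' @export
study_pgls <- function(n_rep = 200L, n_tips = 30L, seed = 1L) {
  star_dev <- with_local_seed(seed, {
    devs <- vapply(1:10, function(r) {
      star <- ape::stree(12, type = "star")
      star$edge.length <- rep(1, 12)
      x <- stats::setNames(rnorm(12), star$tip.label)
      y <- stats::setNames(0.26 * x + rnorm(12, 0, 0.3), star$tip.label)
      pg <- pgls_fit(star, x, y)
      ols <- stats::lm(y ~ x)
      max(abs(pg$slope - stats::coef(ols)[2]),
          abs(pg$intercept - stats::coef(ols)[1]),
          abs(pg$se_slope - summary(ols)$coefficients[2, 2]))
    }, numeric(1))
    max(devs)
  })
  slope_true <- 0.26; intercept_true <- 0.16
  cover <- with_local_seed(seed + 1L, {
    tree <- ape::rcoal(n_tips)
    hits <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      xs <- simulate_phylo_traits(tree, sigma2 = 1,
                                  seed = sample.int(1e6, 1))
      es <- simulate_phylo_traits(tree, sigma2 = 0.09,
                                  seed = sample.int(1e6, 1))
      x <- stats::setNames(xs$trait, xs$tip)
      y <- intercept_true + slope_true * x +
        stats::setNames(es$trait, es$tip)[names(x)]
      pg <- pgls_fit(tree, x, y)
      hits[r] <- abs(pg$slope - slope_true) <= pg$ci95_slope
    }
    100 * mean(hits)
  })
  list(star_max_abs_dev = star_dev, coverage_pct = cover, n = n_rep)
}

#' Truncation-window detection rate on noisy sigmoid series
#'
#' Simulates pooled per-year msGR series — the input
#' [find_truncation()] consumes — from a decreasing Hill sigmoid with
#' its inflection at a known year. Each per-year value is the mean over
#' `n_pool` specimens whose individual measurements carry Gaussian
#' noise of SD `noise_sd` (so the series-level noise is the standard
#' error `noise_sd / sqrt(n_pool)`, as in taxon pooling). Reports how
#' often the detected truncation window contains the true inflection
#' year, plus agreement of the window rule with exhaustive enumeration
#' over random short series.
#'
#' @param n_rep Sigmoid replicates (default 100).
#' @param inflection_year True inflection age (default 5).
#' @param n_pool Specimens averaged per year (default 5).
#' @param noise_sd Per-specimen measurement noise SD (default 0.5).
#' @param seed Seed.
#' @return List: `hit_pct`, `oracle_agreement_pct`, `n`.
#' @export
study_truncation <- function(n_rep = 100L, inflection_year = 5,
                             n_pool = 5L, noise_sd = 0.5, seed = 1L) {
  hits <- with_local_seed(seed, {
    h <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      ny <- sample(10:12, 1)
      t <- seq_len(ny)
      mu <- eval_family("hill_sigmoid", c(11, 4.5, inflection_year, 5), t)
      y <- vapply(mu, function(m)
        mean(m + rnorm(n_pool, 0, noise_sd)), numeric(1))
      tw <- find_truncation(list(year = t, y = y))
      h[r] <- !isTRUE(tw$none) &&
        tw$min_age <= inflection_year && inflection_year <= tw$max_age
    }
    h
  })
  agree <- with_local_seed(seed + 1L, {
    ok <- logical(50)
    for (i in 1:50) {
      n <- sample(4:12, 1)
      y <- round(cumsum(rnorm(n, -0.3, 1.5)) + 10, 2)
      tw <- find_truncation(list(year = 1:n, y = y))
      d <- diff(y)
      if (min(d) >= 0) { ok[i] <- isTRUE(tw$none); next }
      elig <- d <= 0.8 * min(d)
      imin <- which.min(d)
      best <- NULL
      for (a in seq_along(d)) for (b in a:length(d)) {
        if (a <= imin && imin <= b && all(elig[a:b])) {
          if (is.null(best) || (b - a) > (best[2] - best[1]))
            best <- c(a, b)
        }
      }
      ok[i] <- !isTRUE(tw$none) && tw$min_age == best[1] &&
        tw$max_age == best[2] + 1L
    }
    ok
  })
  list(hit_pct = 100 * mean(hits),
       oracle_agreement_pct = 100 * mean(agree), n = n_rep)
}
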