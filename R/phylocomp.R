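#' @importFrom ape vcv cophenetic.phylo is.ultrametric
NULL

# Normalize tip/trait names: case-insensitive, spaces = underscores.
.norm_names <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))

# Align named trait vectors to the tree tip order; errors on mismatch.
.align_traits <- function(tree, ...) {
  tips <- .norm_names(tree$tip.label)
  vals <- list(...)
  out <- lapply(vals, function(v) {
    stopifnot(!is.null(names(v)))
    nm <- .norm_names(names(v))
    if (!all(tips %in% nm)) {
      stop("trait values missing for tips: ",
           paste(tree$tip.label[!tips %in% nm], collapse = ", "),
           call. = FALSE)
    }
    as.numeric(v[match(tips, nm)])
  })
  out
}

# Whitening matrix W with W' W = C^{-1} (from the Cholesky factor).
.whitener <- function(C) {
  L <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance (duplicate or zero-length tips)",
         call. = FALSE))
  backsolve(L, diag(nrow(C)), transpose = TRUE)
}

#' Phylogenetic generalized least squares (Brownian motion)
#'
#' Linear regression of `y` on `x` with error covariance proportional to
#' the Brownian shared-branch-length matrix of the tree. On a star
#' phylogeny the estimates reduce exactly to ordinary least squares.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param x,y Named numeric vectors (names matched to tip labels,
#'   case-insensitively with spaces/underscores normalized); typically
#'   log10-transformed traits.
#' @return A `pgls_fit` list: `slope`, `intercept`, `r2`, `sigma2`,
#'   `se_slope`, `ci95_slope` (half-width), `ci95_intercept`,
#'   `prediction` (data frame with fit and 95% predictor-interval
#'   bounds per tip), `ultrametric` (reported, not enforced), `n`.
#' @export
pgls_fit <- function(tree, x, y) {
  stopifnot(inherits(tree, "phylo"))
  al <- .align_traits(tree, x = x, y = y)
  x <- al$x; y <- al$y
  n <- length(y)
  stopifnot(n >= 3)
  C <- ape::vcv(tree)
  W <- .whitener(C)
  X <- cbind(intercept = 1, slope = x)
  Xw <- W %*% X; yw <- W %*% y
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  df <- n - 2
  sigma2 <- rss / df
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  tcrit <- stats::qt(0.975, df)
  # GLS R^2 against the GLS intercept-only model
  onew <- W %*% rep(1, n)
  b0 <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - onew * b0)^2)
  fit_vals <- as.numeric(X %*% beta)
  cbar <- mean(diag(C))
  h <- rowSums((X %*% solve(XtX)) * X)
  pse <- sqrt(sigma2 * (cbar + h))
  structure(list(
    slope = unname(beta[2]), intercept = unname(beta[1]),
    r2 = 1 - rss / tss,
    sigma2 = sigma2, se_slope = unname(se[2]),
    ci95_slope = unname(tcrit * se[2]),
    ci95_intercept = unname(tcrit * se[1]),
    prediction = data.frame(tip = tree$tip.label, x = x, fit = fit_vals,
                            pi_lo = fit_vals - tcrit * pse,
                            pi_hi = fit_vals + tcrit * pse),
    ultrametric = ape::is.ultrametric(tree), n = n),
    class = "pgls_fit")
}

# Profile -2 log likelihood of a GLS fit with correlation R.
.gls_m2ll <- function(rss_w, n, R_logdet) {
  n * log(2 * pi) + n * log(rss_w / n) + R_logdet + n
}

.fit_mean_model <- function(Wm, x, y, mean_model, seed = 1L) {
  yw <- Wm %*% y
  if (mean_model == "linear") {
    Xw <- Wm %*% cbind(1, x)
    beta <- qr.coef(qr(Xw), yw)
    rss <- sum((yw - Xw %*% beta)^2)
    return(list(params = c(a = beta[1], b = beta[2]), rss = rss, p = 2))
  }
  # exponential mean: y = a * exp(b * x) + c
  resid_fn <- function(p) as.numeric(yw - Wm %*% (p[1] * exp(p[2] * x) + p[3]))
  ry <- max(diff(range(y)), 1e-6)
  starts <- with_local_seed(seed, {
    U <- lhs::randomLHS(10, 3)
    cbind(a = 0.1 * ry + U[, 1] * 3 * ry,
          b = -1 + U[, 2] * 2,
          c = min(y) - ry + U[, 3] * 2 * ry)
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         control = nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(f$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(params = c(a = f$par[1], b = f$par[2], c = f$par[3]),
                   rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  c(best, list(p = 3))
}

#' Phylogenetically informed nonlinear regression
#'
#' Fits `y = a*exp(b*x) + c` (or a linear mean) with phylogenetic error
#' covariance under Brownian motion or an Ornstein-Uhlenbeck process
#' (correlation `exp(-alpha * d_ij)` in patristic distance, alpha
#' profiled by 1D optimization), by maximum likelihood with the error
#' variance profiled out.
#'
#' @param tree `ape::phylo`.
#' @param x,y Named numeric tip traits.
#' @param mean_model `"exponential"` or `"linear"`.
#' @param evolution `"brownian"` or `"ou"`.
#' @param seed Seed for the nonlinear multistart.
#' @return A `pgnlr_fit` list: `params`, `alpha` (OU only; `NA` and a
#'   flag when it hits the search bound), `sigma2`, `m2ll`, `aic`, `k`,
#'   `mean_model`, `evolution`, `fitted`.
#' @export
pgnlr_fit <- function(tree, x, y,
                      mean_model = c("exponential", "linear"),
                      evolution = c("brownian", "ou"), seed = 1L) {
  mean_model <- match.arg(mean_model)
  evolution <- match.arg(evolution)
  al <- .align_traits(tree, x = x, y = y)
  x <- al$x; y <- al$y
  n <- length(y)
  stopifnot(n >= 5)
  fit_for <- function(R) {
    Wm <- .whitener(R)
    ld <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
    mf <- .fit_mean_model(Wm, x, y, mean_model, seed)
    if (is.null(mf)) return(NULL)
    c(mf, list(logdet = ld, m2ll = .gls_m2ll(mf$rss, n, ld)))
  }
  alpha <- NA_real_; alpha_bounded <- FALSE
  if (evolution == "brownian") {
    res <- fit_for(ape::vcv(tree))
    k <- res$p + 1
  } else {
    D <- stats::cophenetic(tree)
    obj <- function(a) {
      r <- fit_for(exp(-a * D))
      if (is.null(r)) 1e10 else r$m2ll
    }
    opt <- stats::optimize(obj, c(1e-4, 50))
    alpha <- opt$minimum
    if (alpha < 2e-4 || alpha > 49) alpha_bounded <- TRUE
    res <- fit_for(exp(-alpha * D))
    k <- res$p + 2
  }
  if (is.null(res)) stop("nonlinear mean model failed to converge",
                         call. = FALSE)
  p <- res$params
  fitted <- if (mean_model == "linear") p[1] + p[2] * x else
    p[1] * exp(p[2] * x) + p[3]
  structure(list(params = p, alpha = alpha,
                 alpha_bounded = alpha_bounded,
                 sigma2 = res$rss / n, m2ll = res$m2ll,
                 aic = res$m2ll + 2 * k, k = k,
                 mean_model = mean_model, evolution = evolution,
                 fitted = fitted, n = n),
            class = "pgnlr_fit")
}

#' Compare the four phylogenetic nonlinear regression models
#'
#' Fits exponential/linear mean crossed with Brownian/OU error
#' covariance, ranks by AIC, and optionally adds a rejection-ABC
#' comparison: parameters are drawn from wide uniform priors around the
#' maximum-likelihood fits, data are simulated under each model, the
#' RMS tip-residual distance to the observed data is computed, and the
#' best `accept_q` fraction of all draws is accepted; posterior
#' probabilities are the acceptance shares.
#'
#' @param tree,x,y As in [pgnlr_fit()].
#' @param n_abc ABC repeats per model (default 500; 0 skips ABC).
#' @param accept_q Acceptance quantile (default 0.05).
#' @param seed Seed.
#' @return List: `fits` (the four `pgnlr_fit`s, named OUGBM, OUGOU,
#'   OUBM, OUOU for exponential-BM, exponential-OU, linear-BM,
#'   linear-OU), `table` (model, aic, delta_aic, posterior), `best`
#'   (name of the lowest-AIC model).
#' @export
pgnlr_compare <- function(tree, x, y, n_abc = 500L, accept_q = 0.05,
                          seed = 1L) {
  combos <- list(OUGBM = c("exponential", "brownian"),
                 OUGOU = c("exponential", "ou"),
                 OUBM = c("linear", "brownian"),
                 OUOU = c("linear", "ou"))
  fits <- lapply(combos, function(cb)
    pgnlr_fit(tree, x, y, cb[1], cb[2], seed = seed))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  post <- rep(NA_real_, length(fits))
  if (n_abc > 0) {
    al <- .align_traits(tree, x = x, y = y)
    xo <- al$x; yo <- al$y
    D <- stats::cophenetic(tree)
    Cbm <- ape::vcv(tree)
    dists <- list()
    with_local_seed(seed + 1L, {
      for (m in seq_along(fits)) {
        f <- fits[[m]]
        p <- f$params
        lo <- p - (2 * abs(p) + 0.5); hi <- p + (2 * abs(p) + 0.5)
        sig_hi <- 4 * sqrt(f$sigma2)
        d <- numeric(n_abc)
        for (i in seq_len(n_abc)) {
          th <- runif(length(p), lo, hi)
          sg <- runif(1, 0, sig_hi)
          mu <- if (f$mean_model == "linear") th[1] + th[2] * xo else
            th[1] * exp(th[2] * xo) + th[3]
          Cm <- if (f$evolution == "brownian") Cbm else {
            a <- if (is.finite(f$alpha)) f$alpha else 1
            exp(-a * D)
          }
          ysim <- mu + sg * as.numeric(t(chol(Cm)) %*% rnorm(length(yo)))
          d[i] <- sqrt(mean((ysim - yo)^2))
        }
        dists[[m]] <- d
      }
    })
    all_d <- unlist(dists)
    cut <- stats::quantile(all_d, accept_q, names = FALSE)
    acc <- vapply(dists, function(d) sum(d <= cut), numeric(1))
    post <- acc / sum(acc)
  }
  tab <- data.frame(model = names(combos), aic = aic,
                    delta_aic = aic - min(aic), posterior = post)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  list(fits = fits, table = tab, best = tab$model[1])
}

#' Phylogenetic ANCOVA
#'
#' Generalized least squares ANCOVA under Brownian covariance: tests
#' slope homogeneity (group-by-covariate interaction) and, under a
#' common slope, group mean separation, on phylogenetically whitened
#' data.
#'
#' @param tree `ape::phylo`.
#' @param x,y Named numeric tip traits.
#' @param group Named factor/character of group membership per tip
#'   (two levels, each with >= 3 tips).
#' @return List with `slope_test` (F, df1, df2, p) for the interaction,
#'   `mean_test` (F, df1, df2, p, partial_eta_sq) for the group effect
#'   under a common slope, and the common-slope fit coefficients.
#' @export
phylo_ancova <- function(tree, x, y, group) {
  stopifnot(inherits(tree, "phylo"))
  al <- .align_traits(tree, x = x, y = y)
  xv <- al$x; yv <- al$y
  gn <- .norm_names(names(group))
  tips <- .norm_names(tree$tip.label)
  if (!all(tips %in% gn)) stop("group labels missing for some tips",
                               call. = FALSE)
  g <- factor(as.character(group)[match(tips, gn)])
  if (nlevels(g) != 2 || any(table(g) < 3)) {
    stop("need two groups with at least 3 tips each", call. = FALSE)
  }
  n <- length(yv)
  W <- .whitener(ape::vcv(tree))
  gd <- as.numeric(g == levels(g)[2])
  rss_of <- function(X) {
    Xw <- W %*% X
    sum(qr.resid(qr(Xw), W %*% yv)^2)
  }
  rss_full <- rss_of(cbind(1, gd, xv, gd * xv))
  rss_comm <- rss_of(cbind(1, gd, xv))
  rss_xonly <- rss_of(cbind(1, xv))
  df_full <- n - 4; df_comm <- n - 3
  F_slope <- (rss_comm - rss_full) / (rss_full / df_full)
  F_mean <- (rss_xonly - rss_comm) / (rss_comm / df_comm)
  ss_grp <- rss_xonly - rss_comm
  Xc <- W %*% cbind(1, gd, xv)
  beta <- qr.coef(qr(Xc), W %*% yv)
  list(slope_test = list(F = F_slope, df1 = 1, df2 = df_full,
                         p = stats::pf(F_slope, 1, df_full,
                                       lower.tail = FALSE)),
       mean_test = list(F = F_mean, df1 = 1, df2 = df_comm,
                        p = stats::pf(F_mean, 1, df_comm,
                                      lower.tail = FALSE),
                        partial_eta_sq = ss_grp / (ss_grp + rss_comm)),
       common_slope = list(intercept = beta[1], group_offset = beta[2],
                           slope = beta[3]))
}

#' Pooled one-way ANOVA of two msGR samples
#'
#' Classical one-way ANOVA F with Cohen's d (pooled SD; positive when
#' the second group's mean exceeds the first's) and per-group
#' Shapiro-Wilk normality statistics reported alongside (never used to
#' gate the test).
#'
#' @param group1,group2 Numeric vectors (each length >= 2).
#' @return List: `F`, `df1`, `df2`, `p`, `cohens_d`, `shapiro` (data
#'   frame of per-group W and p), `n`.
#' @export
pooled_anova <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  n1 <- length(group1); n2 <- length(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  vals <- c(group1, group2)
  grp <- factor(rep(c("g1", "g2"), c(n1, n2)))
  av <- summary(stats::aov(vals ~ grp))[[1]]
  sw <- function(v) {
    if (length(v) >= 3 && length(v) <= 5000 && stats::var(v) > 0) {
      s <- stats::shapiro.test(v); c(W = unname(s$statistic), p = s$p.value)
    } else c(W = NA_real_, p = NA_real_)
  }
  s1 <- sw(group1); s2 <- sw(group2)
  list(F = av[["F value"]][1], df1 = av[["Df"]][1], df2 = av[["Df"]][2],
       p = av[["Pr(>F)"]][1],
       cohens_d = (mean(group2) - mean(group1)) / sqrt(sp2),
       shapiro = data.frame(group = c("group1", "group2"),
                            W = c(s1["W"], s2["W"]),
                            p = c(s1["p"], s2["p"])),
       n = n1 + n2)
}
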