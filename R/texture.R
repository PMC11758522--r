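#' Subsample juvenile and adult texture patches
#'
#' Splits a straightened region at the radius of a cutoff year into two
#' equal-sized patches for texture comparison. The shared radial length
#' is the shorter of the juvenile extent (inner boundary to cutoff,
#' excluding the bright hyaline layer) and the adult extent (cutoff to
#' the start of the last recorded year, which is excluded as possibly
#' incomplete). Patch width is twice the radial length, clamped to the
#' region width with a notice when the dataset is too small.
#'
#' @param region A `straightened_cementum`.
#' @param cutoff_year Year of life separating juvenile from adult
#'   cementum (for fossils, typically the mean growth-rate truncation
#'   point).
#' @param peaks A `peak_set` for this region locating the annual light
#'   increments.
#' @param hyaline_um Radial extent of the hyaline layer to exclude from
#'   the juvenile patch (default 3 voxels).
#' @return List with `juvenile` and `adult`, each a `texture_patch`
#'   (fields `pixels`, `stage`, `radial_extent_um`,
#'   `circumferential_extent_um`).
#' @export
subsample_patches <- function(region, cutoff_year, peaks,
                              hyaline_um = 3 * region$voxel_size_um) {
  p <- peaks$peak_positions_um
  if (length(p) < 3) stop("need at least 3 peaks to subsample",
                          call. = FALSE)
  if (cutoff_year < 1 || cutoff_year >= length(p)) {
    stop(sprintf("cutoff year %s outside recorded years [1, %d)",
                 cutoff_year, length(p)), call. = FALSE)
  }
  vx <- region$voxel_size_um
  n <- length(p)
  cutoff_um <- (p[cutoff_year] + p[cutoff_year + 1]) / 2
  adult_end_um <- (p[n - 1] + p[n]) / 2      # excludes the last year
  juv_lo <- max(1L, ceiling(hyaline_um / vx) + 1L)
  cut_row <- floor(cutoff_um / vx)
  adult_hi <- floor(adult_end_um / vx)
  juv_len <- cut_row - juv_lo + 1L
  adult_len <- adult_hi - cut_row
  len <- min(juv_len, adult_len)
  if (len < 4) stop("juvenile or adult portion too short to subsample",
                    call. = FALSE)
  nc <- ncol(region$pixels)
  width <- 2L * len
  if (width > nc) {
    message(sprintf("patch width clamped from %d to region width %d",
                    width, nc))
    width <- nc
  }
  c0 <- (nc - width) %/% 2 + 1L
  cols <- c0:(c0 + width - 1L)
  mk <- function(rows, stage) {
    structure(list(pixels = region$pixels[rows, cols, drop = FALSE],
                   stage = stage,
                   radial_extent_um = length(rows) * vx,
                   circumferential_extent_um = width * vx,
                   specimen_id = region$provenance$specimen_id %||% "unknown"),
              class = "texture_patch")
  }
  list(juvenile = mk((cut_row - len + 1L):cut_row, "juvenile"),
       adult = mk((cut_row + 1L):(cut_row + len), "adult"))
}

#' Names of the areal texture measures
#' @return Character vector of the 21 measure names.
#' @export
texture_measures <- function() {
  c("Sa", "Sq", "Ssk", "Sku", "Sp", "Sv", "Sz",        # amplitude
    "Sal", "Str", "Std",                               # spatial
    "Sdq", "Sdr",                                      # hybrid
    "Sk", "Spk", "Svk", "Smr1", "Smr2",                # core/bearing
    "Sxp", "Vmp", "Vmc", "Vvv")                        # extra bearing
}

# ISO-style core parameters from the areal material ratio (bearing)
# curve: heights sorted descending against material ratio in (0, 1].
.bearing_params <- function(z) {
  h <- sort(as.numeric(z), decreasing = TRUE)
  n <- length(h)
  mr <- (seq_len(n) - 0.5) / n
  # minimal-slope 40% secant of the bearing curve
  w <- max(2L, round(0.4 * n))
  i0 <- seq_len(n - w)
  slopes <- (h[i0 + w] - h[i0]) / (mr[i0 + w] - mr[i0])
  j <- i0[which.max(slopes)]          # slopes negative; max = least steep
  sl <- slopes[which.max(slopes)]
  ic <- h[j] - sl * mr[j]
  top <- ic                            # line value at mr = 0
  bot <- ic + sl                       # line value at mr = 1
  Sk <- top - bot
  Smr1 <- if (any(h >= top)) max(mr[h >= top]) else 0
  Smr2 <- if (any(h <= bot)) min(mr[h <= bot]) else 1
  A1 <- sum(pmax(h - top, 0)) / n
  A2 <- sum(pmax(bot - h, 0)) / n
  Spk <- if (Smr1 > 0) 2 * A1 / Smr1 else 0
  Svk <- if (Smr2 < 1) 2 * A2 / (1 - Smr2) else 0
  hq <- function(p) stats::quantile(h, 1 - p, names = FALSE, type = 7)
  Sxp <- hq(0.025) - hq(0.5)
  Vm <- function(p) { hp <- hq(p); sum(pmax(h - hp, 0) * (mr <= p)) / n }
  Vv <- function(p) { hp <- hq(p); sum(pmax(hp - h, 0) * (mr >= p)) / n }
  c(Sk = Sk, Spk = Spk, Svk = Svk, Smr1 = Smr1, Smr2 = Smr2,
    Sxp = Sxp, Vmp = Vm(0.10), Vmc = Vm(0.80) - Vm(0.10), Vvv = Vv(0.80))
}

# Normalized 2D autocorrelation via FFT (periodic), DC-centered.
.acf2d <- function(z) {
  P <- Mod(stats::fft(z))^2
  ac <- Re(stats::fft(P, inverse = TRUE)) / length(z)
  ac <- ac / ac[1, 1]
  nr <- nrow(ac); nc <- ncol(ac)
  ac[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
}

# Decay length of the centered ACF along a ray at `ang` radians:
# distance (pixels) where it first drops below 1/e.
.acf_decay <- function(ac, ang) {
  nr <- nrow(ac); nc <- ncol(ac)
  cy <- nr %/% 2 + 1; cx <- nc %/% 2 + 1
  rmax <- min(cy, cx) - 2
  prev <- 1
  for (r in seq(0.5, rmax, by = 0.5)) {
    y <- cy + r * sin(ang); x <- cx + r * cos(ang)
    v <- .bilinear(ac, x, y)
    if (v < exp(-1)) {
      # linear interpolation between the last two radii
      f <- (prev - exp(-1)) / max(prev - v, 1e-12)
      return(r - 0.5 + 0.5 * f)
    }
    prev <- v
  }
  rmax
}

#' Compute areal texture features of a cementum patch
#'
#' Treats the mean-subtracted grayscale of the patch as a height field
#' and computes 21 areal texture measures in four groups: amplitude
#' (Sa, Sq, Ssk, Sku, Sp, Sv, Sz), spatial (Sal autocorrelation decay
#' length at the 1/e criterion, Str texture aspect ratio, Std dominant
#' band orientation in degrees), hybrid (Sdq RMS gradient, Sdr developed
#' area ratio), and bearing-curve functional measures (Sk, Spk, Svk,
#' Smr1, Smr2, Sxp, Vmp, Vmc, Vvv). Heights are in gray levels and
#' lateral distances in pixels unless `voxel_size_um` is given.
#'
#' @param patch A `texture_patch` or plain grayscale matrix (>= 16 x 16).
#' @param voxel_size_um Lateral scale for Sal (default 1 = pixels).
#' @return Named numeric vector of the 21 measures. For a constant
#'   patch the amplitude measures are 0 and scale-dependent measures are
#'   `NaN`, with attribute `degenerate = TRUE`.
#' @export
compute_features <- function(patch, voxel_size_um = 1) {
  z <- if (inherits(patch, "texture_patch")) patch$pixels else as.matrix(patch)
  stopifnot(nrow(z) >= 16, ncol(z) >= 16)
  z <- z - mean(z)
  n <- length(z)
  Sq <- sqrt(mean(z^2))
  out <- stats::setNames(rep(NA_real_, 21), texture_measures())
  out["Sa"] <- mean(abs(z))
  out["Sq"] <- Sq
  out["Sp"] <- max(z); out["Sv"] <- -min(z)
  out["Sz"] <- out["Sp"] + out["Sv"]
  if (Sq == 0) {
    out[c("Ssk", "Sku", "Sal", "Str", "Std")] <- NaN
    out[c("Sdq", "Sdr")] <- 0
    out[c("Sk", "Spk", "Svk", "Sxp", "Vmp", "Vmc", "Vvv")] <- 0
    out[c("Smr1", "Smr2")] <- NaN
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out["Ssk"] <- mean(z^3) / Sq^3
  out["Sku"] <- mean(z^4) / Sq^4
  ac <- .acf2d(z)
  angs <- seq(0, pi - pi / 36, by = pi / 36)
  dec <- vapply(angs, function(a) .acf_decay(ac, a), numeric(1))
  out["Sal"] <- min(dec) * voxel_size_um
  out["Str"] <- min(dec) / max(dec)
  # dominant orientation from the power spectrum peak (excluding DC);
  # 0 degrees = bands parallel to the column (x) axis
  P <- Mod(stats::fft(z))^2
  nr <- nrow(z); nc <- ncol(z)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  P[1, 1] <- 0
  imax <- which.max(P)
  iy <- ((imax - 1) %% nr) + 1; ix <- ((imax - 1) %/% nr) + 1
  spec_ang <- atan2(fy[iy], fx[ix]) * 180 / pi
  out["Std"] <- (spec_ang - 90) %% 180
  gx <- (z[, c(2:nc, nc)] - z[, c(1, 1:(nc - 1))]) / 2
  gy <- (z[c(2:nr, nr), ] - z[c(1, 1:(nr - 1)), ]) / 2
  out["Sdq"] <- sqrt(mean(gx^2 + gy^2))
  out["Sdr"] <- mean(sqrt(1 + gx^2 + gy^2) - 1) * 100
  out[names(.bearing_params(z))] <- .bearing_params(z)
  attr(out, "degenerate") <- FALSE
  out
}

#' Screen texture measures by juvenile-vs-adult ANOVA
#'
#' One-way ANOVA of each measure against stage, per dataset; a measure
#' is retained only if it separates the stages (p < alpha) in every
#' dataset. Zero-variance measures are excluded with a notice.
#'
#' @param datasets Named list of data frames, each with a `stage` column
#'   and one column per measure.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of retained measure names. The per-dataset
#'   p-value matrix is attached as attribute `"p_values"`.
#' @export
screen_measures <- function(datasets, alpha = 0.05) {
  stopifnot(length(datasets) >= 1)
  measures <- setdiff(names(datasets[[1]]), "stage")
  pmat <- matrix(NA_real_, nrow = length(measures),
                 ncol = length(datasets),
                 dimnames = list(measures, names(datasets)))
  for (d in seq_along(datasets)) {
    df <- datasets[[d]]
    stopifnot("stage" %in% names(df), length(unique(df$stage)) == 2)
    for (m in measures) {
      v <- df[[m]]
      if (!all(is.finite(v)) || stats::var(v) == 0) {
        message(sprintf("measure '%s' has zero variance or NAs in '%s'; excluded",
                        m, names(datasets)[d]))
        next
      }
      fit <- stats::aov(v ~ factor(df$stage))
      pmat[m, d] <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
  }
  keep <- apply(pmat, 1, function(p) all(is.finite(p)) && all(p < alpha))
  out <- measures[keep]
  attr(out, "p_values") <- pmat
  out
}

#' PCA of a retained-measure feature matrix
#'
#' Columns are z-scored (correlation-matrix PCA) before decomposition.
#'
#' @param features Numeric matrix or data frame, rows = patches,
#'   columns = retained measures.
#' @return A `texture_space` list: `scores`, `loadings` (orthonormal),
#'   `var_explained` (sums to 1), `measures`, `n_components` (reduced
#'   with a notice when the matrix is rank deficient).
#' @export
texture_pca <- function(features) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 3)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ncomp <- sum(pc$sdev > 1e-10)
  if (ncomp < ncol(X)) {
    message(sprintf("rank-deficient feature matrix: %d of %d components kept",
                    ncomp, ncol(X)))
  }
  structure(list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 var_explained = pc$sdev[seq_len(ncomp)]^2 /
                   sum(pc$sdev^2),
                 measures = colnames(X), n_components = ncomp),
            class = "texture_space")
}

# Shoelace area of a polygon (n x 2 matrix).
.poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clip of convex `subject` against convex `clip`
# (both counter-clockwise n x 2 matrices).
.convex_clip <- function(subject, clip) {
  out <- subject
  nclip <- nrow(clip)
  for (i in seq_len(nclip)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[(i %% nclip) + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2]); d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
      p + t * d1
    }
    res <- list()
    n <- nrow(out)
    for (j in seq_len(n)) {
      cur <- out[j, ]; nxt <- out[(j %% n) + 1, ]
      ci <- inside(cur); ni <- inside(nxt)
      if (ci) res[[length(res) + 1]] <- cur
      if (ci != ni) res[[length(res) + 1]] <- inter(cur, nxt)
    }
    out <- if (length(res)) do.call(rbind, res) else NULL
  }
  out
}

# Counter-clockwise convex hull of points (n x 2).
.ccw_hull <- function(pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (.signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  hull
}

.signed_area <- function(p) {
  n <- nrow(p); i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

#' Convex-hull overlap of two groups in PC1-PC2 space
#'
#' Computes the Jaccard overlap of the two groups' convex hulls in the
#' first two principal components: intersection area over union area.
#' Groups are called distinct when the overlap falls below `threshold`.
#' Degenerate (collinear) hulls fall back to a 1D segment-overlap test
#' along the groups' common principal direction.
#'
#' @param space A `texture_space` (or matrix of scores with >= 2
#'   columns).
#' @param labels Two-level factor/character vector, one per row of the
#'   scores.
#' @param threshold Overlap below which the groups are distinct
#'   (default 0.05).
#' @return List: `overlap` (in `[0, 1]`), `distinct`, `areas` (named:
#'   group areas, intersection, union).
#' @export
hull_separation <- function(space, labels, threshold = 0.05) {
  S <- if (inherits(space, "texture_space")) space$scores else as.matrix(space)
  stopifnot(ncol(S) >= 2, length(labels) == nrow(S))
  labels <- as.character(labels)
  lv <- unique(labels)
  stopifnot(length(lv) == 2)
  P <- S[, 1:2, drop = FALSE]
  g1 <- P[labels == lv[1], , drop = FALSE]
  g2 <- P[labels == lv[2], , drop = FALSE]
  stopifnot(nrow(g1) >= 3, nrow(g2) >= 3)
  h1 <- .ccw_hull(g1); h2 <- .ccw_hull(g2)
  a1 <- .poly_area(h1); a2 <- .poly_area(h2)
  eps <- 1e-9 * max(1, a1, a2)
  if (a1 < eps || a2 < eps) {
    # collinear fallback: interval overlap along the dominant direction
    v <- stats::prcomp(P, center = TRUE)$rotation[, 1]
    t1 <- range(g1 %*% v); t2 <- range(g2 %*% v)
    inter <- max(0, min(t1[2], t2[2]) - max(t1[1], t2[1]))
    uni <- max(t1[2], t2[2]) - min(t1[1], t2[1])
    ov <- if (uni > 0) inter / uni else 1
    return(list(overlap = ov, distinct = ov < threshold,
                areas = c(inter = inter, union = uni), degenerate = TRUE))
  }
  ip <- .convex_clip(h1, h2)
  ai <- if (is.null(ip)) 0 else .poly_area(ip)
  au <- a1 + a2 - ai
  ov <- ai / au
  list(overlap = ov, distinct = ov < threshold,
       areas = c(area1 = a1, area2 = a2, inter = ai, union = au),
       degenerate = FALSE)
}
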