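# Shared fixture builders (all fixtures are generated in code).

# Noise-free, highly coherent banding spec for a given schedule.
clean_spec <- function(schedule, rows = NULL, cols = 96, voxel = 1,
                       seed = 1L, ...) {
  if (is.null(rows)) {
    rows <- ceiling(sum(schedule_widths(schedule)) / voxel) + 10L
  }
  synthetic_spec(schedule,
                 texture_params(contrast = 0.7, anisotropy = 100,
                                noise_sd = 0),
                 voxel_size_um = voxel, image_shape = c(rows, cols),
                 seed = seed, ...)
}

# Render and trim to the measurable cementum (hyaline and fringe
# excluded), returning image + ground truth.
render_trimmed <- function(spec) {
  out <- render_cementum(spec)
  gt <- out$ground_truth
  list(image = trim_region(out$image, gt$hyaline_um, gt$fringe_start_um),
       ground_truth = gt)
}

# Brute-force peak oracle: all strict local maxima above the segment
# mean + SD threshold of their own segment (independent of the
# run-based implementation path).
oracle_peaks <- function(values, positions, n_segments = 5L) {
  n <- length(values)
  base <- n %/% n_segments
  seg <- rep(seq_len(n_segments),
             times = c(rep(base, n_segments - 1),
                       n - base * (n_segments - 1)))
  thr <- numeric(n)
  for (s in seq_len(n_segments)) {
    v <- values[seg == s]
    thr[seg == s] <- mean(v) + sd(v)
  }
  idx <- which(values > thr)
  idx <- idx[idx > 1 & idx < n]
  idx <- idx[values[idx] >= values[idx - 1] & values[idx] >= values[idx + 1]]
  positions[idx]
}

# Exhaustive truncation-window oracle: maximal contiguous eligible run
# containing the most negative year-to-year difference.
oracle_truncation <- function(years, y, theta = 0.8) {
  d <- diff(y)
  if (min(d) >= 0) return(NULL)
  elig <- d <= theta * min(d)
  imin <- which.min(d)
  best <- NULL
  for (i in seq_along(d)) for (j in i:length(d)) {
    if (i <= imin && imin <= j && all(elig[i:j])) {
      if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
    }
  }
  c(min_age = years[best[1]], max_age = years[best[2]] + 1L)
}

# Small non-ultrametric-safe test tree with known structure.
balanced_tree <- function(n_tips, depth = 1) {
  tr <- ape::stree(n_tips, type = "balanced")
  tr$edge.length <- rep(depth / ceiling(log2(n_tips)), nrow(tr$edge))
  tr
}
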