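#' Extract radial grayscale transects from a straightened region
#'
#' Averages bands of adjacent columns into 1D radial grayscale profiles,
#' evenly spaced around the circumference. Eight 10-pixel-thick
#' transects per region is the default sampling density.
#'
#' @param region A `straightened_cementum`.
#' @param n_transects Number of transects (default 8).
#' @param thickness_px Columns averaged per transect (default 10).
#' @return List of `transect_profile` objects, each with `values`
#'   (grayscale means), `positions_um` (strictly increasing radial
#'   positions at voxel centers), `transect_index`, `specimen_id`.
#'   If the region is too narrow the transect count is reduced with a
#'   warning; fewer than 3 possible is an error.
#' @export
extract_transects <- function(region, n_transects = 8L,
                              thickness_px = 10L) {
  px <- region$pixels
  nc <- ncol(px)
  if (nc < n_transects * thickness_px) {
    n_new <- max(nc %/% thickness_px, 0L)
    if (n_new < 3) stop("region too narrow for even 3 transects",
                        call. = FALSE)
    warning(sprintf("region %d px wide supports only %d transects of %d px",
                    nc, n_new, thickness_px))
    n_transects <- n_new
  }
  starts <- floor((seq_len(n_transects) - 1) * nc / n_transects) + 1L
  starts <- pmin(starts, nc - thickness_px + 1L)
  step_um <- if (length(unique(region$col_step_um)) == 1)
    region$col_step_um[1] else region$voxel_size_um
  lapply(seq_len(n_transects), function(k) {
    band <- px[, starts[k]:(starts[k] + thickness_px - 1L), drop = FALSE]
    structure(list(
      values = rowMeans(band),
      positions_um = (region$origin_um %||% 0) +
        (seq_len(nrow(px)) - 0.5) * step_um,
      transect_index = k - 1L,
      specimen_id = region$provenance$specimen_id %||% "unknown"),
      class = "transect_profile")
  })
}

# Equal-count segment id per sample; remainder samples go to the last
# segment.
.segment_ids <- function(n, n_segments) {
  base <- n %/% n_segments
  ids <- rep(seq_len(n_segments), times = c(rep(base, n_segments - 1),
                                            n - base * (n_segments - 1)))
  ids
}

#' Detect annual light increments on a grayscale transect
#'
#' Implements the segment-wise peak rule: the transect is split into
#' `n_segments` segments of equal length, and a light increment is any
#' maximal run of consecutive samples whose grayscale exceeds its
#' segment's mean + SD. Runs that straddle a segment boundary are
#' re-evaluated against the segment containing the run's maximum. Each
#' peak is localized to sub-voxel precision as the grayscale-weighted
#' centroid of its run; peaks closer than `min_separation_um` merge into
#' the higher one.
#'
#' @param profile A `transect_profile` (or list with `values`,
#'   `positions_um`).
#' @param n_segments Number of segments (default 5).
#' @param min_separation_um Minimum peak separation; default 2 voxels
#'   (twice the local sample spacing).
#' @return A `peak_set`: `peak_positions_um` (increasing),
#'   `peak_heights`, `segment_stats` (per-segment mean, sd),
#'   `degenerate` (`TRUE` for a flat profile with zero SD everywhere).
#' @export
detect_peaks <- function(profile, n_segments = 5L,
                         min_separation_um = NULL) {
  v <- profile$values
  pos <- profile$positions_um
  n <- length(v)
  stopifnot(n >= 3 * n_segments, length(pos) == n, !is.unsorted(pos))
  if (is.null(min_separation_um)) {
    min_separation_um <- 2 * median(diff(pos))
  }
  seg <- .segment_ids(n, n_segments)
  seg_mean <- tapply(v, seg, mean)
  seg_sd <- tapply(v, seg, sd)
  thr <- as.numeric((seg_mean + seg_sd)[seg])
  stats_tab <- data.frame(segment = seq_len(n_segments),
                          mean = as.numeric(seg_mean),
                          sd = as.numeric(seg_sd))
  if (all(seg_sd == 0) && length(unique(v)) == 1) {
    return(structure(list(peak_positions_um = numeric(0),
                          peak_heights = numeric(0),
                          segment_stats = stats_tab,
                          degenerate = TRUE), class = "peak_set"))
  }
  above <- v > thr
  if (!any(above)) {
    return(structure(list(peak_positions_um = numeric(0),
                          peak_heights = numeric(0),
                          segment_stats = stats_tab,
                          degenerate = FALSE), class = "peak_set"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]

  centers <- numeric(0); heights <- numeric(0)
  for (k in seq_len(nrow(runs))) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    # rebuild the run against the threshold of the segment holding its
    # maximum, so peaks split by a segment boundary are re-joined
    imax <- i0 + which.max(v[i0:i1]) - 1L
    th <- as.numeric(seg_mean[seg[imax]] + seg_sd[seg[imax]])
    a <- imax; while (a > 1 && v[a - 1] > th) a <- a - 1L
    b <- imax; while (b < n && v[b + 1] > th) b <- b + 1L
    i0 <- a; i1 <- b
    idx <- i0:i1
    centers <- c(centers, sum(pos[idx] * v[idx]) / sum(v[idx]))
    heights <- c(heights, max(v[idx]))
  }
  o <- order(centers)
  centers <- centers[o]; heights <- heights[o]
  dup <- c(FALSE, diff(centers) < 1e-9)
  centers <- centers[!dup]; heights <- heights[!dup]
  # merge peaks closer than min_separation to the higher one
  repeat {
    if (length(centers) < 2) break
    gaps <- diff(centers)
    j <- which(gaps < min_separation_um)
    if (!length(j)) break
    j <- j[1]
    drop <- if (heights[j] >= heights[j + 1]) j + 1L else j
    centers <- centers[-drop]; heights <- heights[-drop]
  }
  structure(list(peak_positions_um = centers, peak_heights = heights,
                 segment_stats = stats_tab, degenerate = FALSE),
            class = "peak_set")
}

#' Measure growth layer group widths from detected peaks
#'
#' Widths are distances between subsequent light-increment peak centers;
#' the interval beyond the last peak (the possibly incomplete final year
#' of life) is never reported.
#'
#' @param peaks A `peak_set`.
#' @return An `increment_series`: `widths_um` (per-year, year 1 first),
#'   `glg_count` (number of peaks = growth layer groups),
#'   `complete_years` (`glg_count - 1`).
#' @export
measure_widths <- function(peaks) {
  p <- peaks$peak_positions_um
  widths <- if (length(p) >= 2) diff(p) else numeric(0)
  structure(list(widths_um = widths,
                 glg_count = length(p),
                 complete_years = max(length(p) - 1L, 0L)),
            class = "increment_series")
}

#' Consensus life span for one specimen
#'
#' Aggregates growth-layer-group counts over all measured transects
#' (up to 8 transects x 9 virtual thin sections = 72) into a consensus
#' count: the mode, with ties broken to the higher count.
#'
#' @param all_series List of `increment_series` for one specimen.
#' @return List: `lifespan_years` (consensus count), `count_sd`
#'   (dispersion of counts across transects), `counts`.
#' @export
specimen_lifespan <- function(all_series) {
  stopifnot(length(all_series) >= 1)
  counts <- as.integer(vapply(all_series, function(s)
    as.numeric(s$glg_count), numeric(1)))
  tab <- table(counts)
  best <- as.integer(names(tab)[tab == max(tab)])
  list(lifespan_years = max(best),
       count_sd = if (length(counts) > 1) sd(counts) else 0,
       counts = counts)
}

#' Filter a specimen cohort by preservation and sampling rules
#'
#' Keeps preservational categories a and b only (category c specimens
#' are excluded from all analyses), then keeps taxa with at least 3
#' specimens identified at genus level or at least 5 specimens at
#' ordinal level.
#'
#' @param metadata Data frame with columns `specimen_id`, `taxon`,
#'   `rank` (`"genus"` or `"order"`), `category` (`"a"`, `"b"`, `"c"`).
#' @return The accepted subset of `metadata` (possibly zero rows).
#' @export
filter_cohort <- function(metadata) {
  stopifnot(all(c("specimen_id", "taxon", "rank", "category") %in%
                  names(metadata)))
  keep <- metadata[metadata$category %in% c("a", "b"), , drop = FALSE]
  if (!nrow(keep)) return(keep)
  ok_taxa <- vapply(split(keep, keep$taxon), function(d) {
    need <- if (d$rank[1] == "order") 5L else 3L
    nrow(d) >= need
  }, logical(1))
  keep[keep$taxon %in% names(ok_taxa)[ok_taxa], , drop = FALSE]
}

#' Pool increment series to a taxon-level growth series
#'
#' Per-year widths are first averaged within each specimen (across its
#' transects and virtual thin sections), then summarized across
#' specimens. Years represented by fewer than `min_n` specimens are
#' dropped. If a body mass and ratio strategy are supplied, per-year
#' mass-specific growth rates (msGR) are attached.
#'
#' @param series_by_specimen Named list (one entry per specimen) of
#'   lists of `increment_series`.
#' @param taxon Taxon label.
#' @param mass_g Optional body mass (g) for msGR conversion.
#' @param strategy Optional [msgr_strategy()]; default used when
#'   `mass_g` given.
#' @param min_n Minimum specimens per reported year (default 3).
#' @return A `taxon_growth_series` data frame: `taxon`, `year`,
#'   `mean_width_um`, `sd_width_um`, `n_specimens`, and `msgr` when mass
#'   is supplied; zero rows (with a message) if no year reaches `min_n`.
#' @export
pool_taxon <- function(series_by_specimen, taxon, mass_g = NULL,
                       strategy = msgr_strategy(), min_n = 3L) {
  per_spec <- lapply(series_by_specimen, function(series_list) {
    wlists <- lapply(series_list, function(s) s$widths_um)
    max_y <- max(vapply(wlists, length, integer(1)), 0L)
    if (max_y == 0) return(NULL)
    vapply(seq_len(max_y), function(y) {
      vals <- unlist(lapply(wlists, function(w)
        if (length(w) >= y) w[y] else NA_real_))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  })
  per_spec <- per_spec[!vapply(per_spec, is.null, logical(1))]
  max_y <- max(vapply(per_spec, length, integer(1)), 0L)
  rows <- lapply(seq_len(max_y), function(y) {
    vals <- unlist(lapply(per_spec, function(w)
      if (length(w) >= y && is.finite(w[y])) w[y] else NULL))
    if (length(vals) < min_n) return(NULL)
    data.frame(taxon = taxon, year = y,
               mean_width_um = mean(vals),
               sd_width_um = if (length(vals) > 1) sd(vals) else 0,
               n_specimens = length(vals))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    message(sprintf("taxon '%s': no year reaches n >= %d specimens",
                    taxon, min_n))
    out <- data.frame(taxon = character(0), year = integer(0),
                      mean_width_um = numeric(0), sd_width_um = numeric(0),
                      n_specimens = integer(0))
  }
  if (!is.null(mass_g) && nrow(out)) {
    out$mass_g <- mass_g
    out$msgr <- msgr(out$mean_width_um, mass_g, strategy)
  }
  class(out) <- c("taxon_growth_series", class(out))
  out
}

#' Measure all transects of a straightened region
#'
#' Convenience wrapper: extract transects, detect peaks, measure widths.
#'
#' @param region A `straightened_cementum`.
#' @param n_transects,thickness_px Passed to [extract_transects()].
#' @param n_segments Passed to [detect_peaks()].
#' @return List of `increment_series`, one per transect.
#' @export
measure_region <- function(region, n_transects = 8L, thickness_px = 10L,
                           n_segments = 5L) {
  profs <- extract_transects(region, n_transects, thickness_px)
  lapply(profs, function(p) measure_widths(detect_peaks(p, n_segments)))
}
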