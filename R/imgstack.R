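#' Straightened cementum array
#'
#' Container for a radial-by-circumferential grayscale array: row 1 lies
#' at the inner cementum boundary (cementum-dentine junction), rows
#' increase outward, columns run along the root circumference.
#'
#' @param pixels Integer/numeric matrix, grayscale in `[0, 255]`.
#' @param voxel_size_um Voxel edge length in micrometers.
#' @param col_step_um Optional per-column radial step in micrometers
#'   (after straightening, the radial scale can differ by column);
#'   defaults to `voxel_size_um` for every column.
#' @param provenance List of identifiers (specimen_id, vts_index, ...).
#' @return Object of class `straightened_cementum`.
#' @export
straightened_cementum <- function(pixels, voxel_size_um,
                                  col_step_um = NULL,
                                  provenance = list(), origin_um = 0) {
  pixels <- as.matrix(pixels)
  stopifnot(voxel_size_um > 0, min(pixels) >= 0, max(pixels) <= 255)
  if (is.null(col_step_um)) col_step_um <- rep(voxel_size_um, ncol(pixels))
  stopifnot(length(col_step_um) == ncol(pixels))
  structure(list(pixels = pixels, voxel_size_um = voxel_size_um,
                 col_step_um = col_step_um, provenance = provenance,
                 origin_um = origin_um),
            class = "straightened_cementum")
}

#' Trim a straightened region to the measurable cementum
#'
#' Crops rows outside `[inner_um, outer_um)` — typically the bright
#' hyaline layer at the inner boundary and the phase-fringe band (plus
#' anything beyond the root surface) at the outer boundary, which are
#' not growth increments. The radial origin is tracked so absolute
#' positions stay comparable.
#'
#' @param region A `straightened_cementum`.
#' @param inner_um Keep rows at or beyond this radial position.
#' @param outer_um Keep rows strictly inside this position (`NULL` =
#'   no outer crop).
#' @return A `straightened_cementum` with updated `origin_um`.
#' @export
trim_region <- function(region, inner_um = 0, outer_um = NULL) {
  vx <- region$voxel_size_um
  pos <- region$origin_um + (seq_len(nrow(region$pixels)) - 0.5) * vx
  keep <- pos >= inner_um & (if (is.null(outer_um)) TRUE else pos < outer_um)
  stopifnot(sum(keep) >= 2)
  straightened_cementum(region$pixels[keep, , drop = FALSE], vx,
                        col_step_um = region$col_step_um,
                        provenance = region$provenance,
                        origin_um = pos[which(keep)[1]] - 0.5 * vx)
}

#' @export
print.straightened_cementum <- function(x, ...) {
  cat(sprintf("<straightened_cementum> %d x %d px, %.3g um/voxel\n",
              nrow(x$pixels), ncol(x$pixels), x$voxel_size_um))
  invisible(x)
}

#' Write / read an 8-bit grayscale cementum TIFF
#'
#' @param x A `straightened_cementum` (or plain matrix in `[0,255]`).
#' @param path Output file.
#' @export
write_cementum_tiff <- function(x, path) {
  m <- if (inherits(x, "straightened_cementum")) x$pixels else as.matrix(x)
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_cementum_tiff
#' @param voxel_size_um Micrometer scale to attach on read.
#' @export
read_cementum_tiff <- function(path, voxel_size_um = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  straightened_cementum(round(m * 255), voxel_size_um,
                        provenance = list(source = path))
}

#' Build a virtual thin section by z-projection
#'
#' Averages a window of aligned tomographic slices to boost increment
#' contrast, mirroring the standard z-projection of 10 transverse slices.
#'
#' @param stack 3D array `[rows, cols, slices]` or list of matrices.
#' @param center_slice Index of the window center slice.
#' @param n_slices Window size (default 10).
#' @param voxel_size_um Micrometer scale carried through.
#' @param specimen_id Identifier carried through.
#' @return Object of class `virtual_thin_section` with fields `pixels`
#'   (8-bit, mean rounded half-up), `voxel_size_um`, `source_slices`
#'   `(start, count)`, `specimen_id`.
#' @export
make_vts <- function(stack, center_slice, n_slices = 10L,
                     voxel_size_um = 1, specimen_id = "unknown") {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3, n_slices >= 1)
  nz <- dim(stack)[3]
  start <- center_slice - floor((n_slices - 1) / 2)
  end <- start + n_slices - 1L
  if (start < 1 || end > nz) {
    stop(sprintf(
      "slice window [%d, %d] outside stack; valid center range is [%d, %d]",
      start, end, 1 + floor((n_slices - 1) / 2), nz - ceiling((n_slices - 1) / 2)),
      call. = FALSE)
  }
  m <- apply(stack[, , start:end, drop = FALSE], c(1, 2), mean)
  m <- floor(m + 0.5)                 # round half-up for reproducibility
  m[] <- pmin(255, pmax(0, m))
  structure(list(pixels = m, voxel_size_um = voxel_size_um,
                 source_slices = c(start = start, count = n_slices),
                 specimen_id = specimen_id),
            class = "virtual_thin_section")
}

# Bilinear interpolation at (x, y) in 1-based pixel-center coordinates.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Resample a polyline (n x 2 matrix, columns x, y) at k equally spaced
# arc-length positions; returns positions and unit tangents.
.resample_polyline <- function(poly, k) {
  d <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  tgt <- seq(0, total, length.out = k)
  seg <- findInterval(tgt, s, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1), nrow(poly) - 1)
  frac <- (tgt - s[seg]) / pmax(d[seg], 1e-12)
  pts <- poly[seg, , drop = FALSE] +
    (poly[seg + 1, , drop = FALSE] - poly[seg, , drop = FALSE]) * frac
  tans <- poly[seg + 1, , drop = FALSE] - poly[seg, , drop = FALSE]
  tans <- tans / pmax(sqrt(rowSums(tans^2)), 1e-12)
  list(points = pts, tangents = tans)
}

# First positive intersection distance of ray p + t*dir with polyline.
.ray_polyline_dist <- function(p, dir, poly) {
  best <- Inf
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    e <- b - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a - p
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    u <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) best <- min(best, t)
  }
  best
}

#' Straighten an annotated cementum region
#'
#' Samples grayscale along local normals of the inner boundary, from the
#' inner to the outer polyline, producing a radial-by-circumferential
#' array. Columns whose normal misses the outer boundary, or that touch
#' the exclusion mask, are dropped with a warning; if more than 20% of
#' columns drop, the straightening fails.
#'
#' @param vts A `virtual_thin_section` (or `straightened_cementum`, whose
#'   pixels are used directly).
#' @param roi List with `inner` and `outer` polylines (`n x 2` matrices
#'   of 0-based `(x, y)` pixel coordinates; inner = cementum-dentine
#'   junction, outer = root surface) and optional logical
#'   `exclusion_mask` matching the image dimensions.
#' @param radial_samples Number of output rows (>= 2).
#' @param circumferential_samples Number of output columns (>= 2).
#' @return A `straightened_cementum`; `col_step_um` records the local
#'   radial micrometer step of each retained column.
#' @export
straighten <- function(vts, roi, radial_samples = 64L,
                       circumferential_samples = 64L) {
  stopifnot(radial_samples >= 2, circumferential_samples >= 2,
            !is.null(roi$inner), !is.null(roi$outer))
  img <- if (inherits(vts, "straightened_cementum")) vts$pixels else vts$pixels
  vx <- vts$voxel_size_um
  inner <- as.matrix(roi$inner) + 1   # to 1-based
  outer <- as.matrix(roi$outer) + 1
  rs <- .resample_polyline(inner, circumferential_samples)

  cols <- vector("list", circumferential_samples)
  steps <- numeric(circumferential_samples)
  keep <- logical(circumferential_samples)
  for (c in seq_len(circumferential_samples)) {
    p <- rs$points[c, ]; tg <- rs$tangents[c, ]
    n <- c(-tg[2], tg[1])
    # orient toward the nearer outer-boundary crossing (handles both
    # straight and annular ROIs)
    t_pos <- .ray_polyline_dist(p, n, outer)
    t_neg <- .ray_polyline_dist(p, -n, outer)
    if (t_neg < t_pos) { n <- -n; t_int <- t_neg } else t_int <- t_pos
    if (!is.finite(t_int)) next
    step <- t_int / (radial_samples - 1)
    xs <- p[1] + n[1] * step * (0:(radial_samples - 1))
    ys <- p[2] + n[2] * step * (0:(radial_samples - 1))
    if (!is.null(roi$exclusion_mask)) {
      ri <- pmin(pmax(round(ys), 1), nrow(img))
      ci <- pmin(pmax(round(xs), 1), ncol(img))
      if (any(roi$exclusion_mask[cbind(ri, ci)])) next
    }
    cols[[c]] <- .bilinear(img, xs, ys)
    steps[c] <- step * vx
    keep[c] <- TRUE
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(sprintf("dropped %d of %d columns (missed outer boundary or exclusion mask)",
                    dropped, circumferential_samples))
  }
  if (dropped > 0.2 * circumferential_samples) {
    stop("more than 20% of columns dropped during straightening",
         call. = FALSE)
  }
  m <- do.call(cbind, cols[keep])
  m[] <- pmin(255, pmax(0, m))
  straightened_cementum(m, voxel_size_um = vx, col_step_um = steps[keep],
                        provenance = list(
                          specimen_id = vts$specimen_id %||%
                            vts$provenance$specimen_id %||% "unknown"))
}

#' Indices of evenly spaced VTS centers through a usable slice range
#'
#' @param range_start,range_end First and last usable slice.
#' @param n_vts Number of virtual thin sections (default 9).
#' @return Integer vector of center-slice indices.
#' @export
vts_centers <- function(range_start, range_end, n_vts = 9L) {
  stopifnot(range_end >= range_start, n_vts >= 1)
  spacing <- floor((range_end - range_start + 1) / n_vts)
  if (spacing < 1) stop("slice range too short for requested VTS count")
  as.integer(range_start + spacing %/% 2 + spacing * (seq_len(n_vts) - 1))
}

# Connected-component labelling (EBImage's bwlabel).
.label_components <- function(mask) {
  EBImage::bwlabel(mask * 1)
}

#' Screen a straightened region for cellular voids
#'
#' Detects dark connected blobs (grayscale below `gray_threshold`, area
#' at least `min_area_px`) that indicate cellular cementum; regions with
#' any void are rejected for increment analysis.
#'
#' @param region A `straightened_cementum`.
#' @param gray_threshold Void grayscale ceiling (default 30).
#' @param min_area_px Minimum blob area in pixels (default 5).
#' @return List: `void_count`, `accept` (`TRUE` iff no voids), and
#'   `degenerate` (`TRUE` when over half the region is below threshold,
#'   e.g. a fully dark image, in which case the region is rejected with
#'   `void_count = NA`).
#' @export
screen_voids <- function(region, gray_threshold = 30, min_area_px = 5) {
  px <- region$pixels
  mask <- px < gray_threshold
  if (mean(mask) > 0.5) {
    return(list(void_count = NA_integer_, accept = FALSE,
                degenerate = TRUE))
  }
  lab <- .label_components(mask)
  sizes <- tabulate(lab)
  n <- sum(sizes >= min_area_px)
  list(void_count = n, accept = n == 0L, degenerate = FALSE)
}
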