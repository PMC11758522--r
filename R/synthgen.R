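#' @importFrom stats rnorm runif rpois sd var median quantile
NULL

# Evaluate an expression with a temporary RNG state so generator calls are
# deterministic under a fixed seed and do not disturb the caller's stream.
with_local_seed <- function(seed, expr) {
  seed <- as.integer(seed)  # force now: a lazy seed argument drawn from
                            # the caller's RNG must advance that stream
                            # before we snapshot it
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Texture parameters for synthetic cementum
#'
#' Controls the appearance of the rendered growth-layer banding.
#'
#' @param contrast Light/dark band amplitude in `[0, 1]`; the light-band
#'   peak rises `contrast * 127` gray levels above the dark baseline.
#' @param anisotropy Orientation coherence of the banding, `>= 0`. Large
#'   values give straight parallel bands; 0 gives strongly wavy bands.
#' @param noise_sd Additive Gaussian grayscale noise SD, 8-bit units.
#' @param juvenile_adult_shift Optional named list of deltas
#'   (`contrast`, `anisotropy`, `noise_sd`) applied to cementum deposited
#'   after the maturity year, emulating the tighter, more regular adult
#'   incrementation of extant therians.
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(contrast = 0.7, anisotropy = 4, noise_sd = 8,
                           juvenile_adult_shift = NULL) {
  stopifnot(contrast >= 0, contrast <= 1, anisotropy >= 0, noise_sd >= 0)
  if (!is.null(juvenile_adult_shift)) {
    stopifnot(is.list(juvenile_adult_shift),
              all(names(juvenile_adult_shift) %in%
                    c("contrast", "anisotropy", "noise_sd")))
  }
  structure(list(contrast = contrast, anisotropy = anisotropy,
                 noise_sd = noise_sd,
                 juvenile_adult_shift = juvenile_adult_shift),
            class = "texture_params")
}

#' Specification of one synthetic cementum image
#'
#' @param schedule A [growth_schedule()] giving per-year increment widths.
#' @param texture A [texture_params()].
#' @param maturity_year Integer year after which the juvenile/adult
#'   texture shift applies, or `NULL` for none.
#' @param voxel_size_um Voxel edge length in micrometers.
#' @param image_shape Integer `(rows, cols)`; rows are radial (row 1 at
#'   the inner cementum-dentine junction), columns circumferential.
#' @param include_hyaline Render a bright hyaline layer at the inner
#'   boundary.
#' @param include_phase_fringe Render a bright fringe band at the outer
#'   (cementum-air) boundary.
#' @param void_density Expected cellular voids per square millimeter
#'   (emulating patches of cellular cementum); 0 for none.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(schedule, texture = texture_params(),
                           maturity_year = NULL, voxel_size_um = 1,
                           image_shape = c(160L, 96L),
                           include_hyaline = TRUE,
                           include_phase_fringe = TRUE,
                           void_density = 0, seed = 1L) {
  stopifnot(inherits(schedule, "growth_schedule"),
            inherits(texture, "texture_params"),
            voxel_size_um > 0, length(image_shape) == 2,
            all(image_shape >= 8), void_density >= 0)
  if (!is.null(maturity_year)) {
    stopifnot(maturity_year >= 1, maturity_year <= schedule$n_years)
  }
  structure(list(schedule = schedule, texture = texture,
                 maturity_year = maturity_year,
                 voxel_size_um = voxel_size_um,
                 image_shape = as.integer(image_shape),
                 include_hyaline = isTRUE(include_hyaline),
                 include_phase_fringe = isTRUE(include_phase_fringe),
                 void_density = void_density, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth per-column radial displacement field (micrometers). Coherent
# banding (large anisotropy) keeps the field near zero.
.waviness <- function(n_cols, anisotropy, mean_width_um) {
  amp <- 0.35 * mean_width_um / (1 + anisotropy)
  if (amp <= 0 || n_cols < 3) return(numeric(n_cols))
  raw <- cumsum(rnorm(n_cols))
  k <- max(3L, min(n_cols, 15L))
  sm <- stats::filter(c(rev(raw[seq_len(k)]), raw, rev(raw[n_cols - seq_len(k) + 1])),
                      rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)[(k + 1):(k + n_cols)]
  sm <- sm - mean(sm)
  s <- sd(sm)
  if (s == 0) return(numeric(n_cols))
  sm / s * amp
}

#' Render a synthetic straightened cementum image
#'
#' Produces an 8-bit grayscale radial-by-circumferential array with one
#' light (favorable-season) raised-cosine band and one dark interband per
#' year of life, an optional bright hyaline layer at the inner boundary
#' and phase-fringe band at the outer boundary, optional cellular voids,
#' and additive Gaussian noise — together with a ground-truth sidecar
#' giving the true peak centers and spacings.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `image` (a `straightened_cementum`) and
#'   `ground_truth` (list: `peak_positions_um`, `widths_um` —
#'   center-to-center light-band spacings, the quantity increment
#'   measurement recovers — `schedule_widths_um`, `n_years`,
#'   `maturity_year`, `void_centers`, `seed`).
#' @export
render_cementum <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sch <- spec$schedule
  w <- schedule_widths(sch)          # errors on non-positive widths
  vx <- spec$voxel_size_um
  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  hy_um <- if (spec$include_hyaline) 3 * vx else 0
  fringe_um <- if (spec$include_phase_fringe) 3 * vx else 0
  bounds <- hy_um + cumsum(c(0, w))  # year boundaries, um from inner edge
  total_um <- bounds[length(bounds)] + fringe_um
  if (total_um > rows * vx) {
    stop(sprintf(
      "cumulative band thickness %.1f um exceeds radial extent %.1f um",
      total_um, rows * vx), call. = FALSE)
  }
  light_frac <- 0.8                   # dark:light width ratio 0.25
  band_lo <- bounds[seq_len(sch$n_years)]
  band_L <- light_frac * w
  peaks <- band_lo + band_L / 2
  mat_boundary <- if (is.null(spec$maturity_year)) Inf else
    bounds[spec$maturity_year + 1]

  tx <- spec$texture
  shift <- tx$juvenile_adult_shift
  adult <- list(
    contrast = min(1, max(0, tx$contrast + (shift$contrast %||% 0))),
    anisotropy = max(0, tx$anisotropy + (shift$anisotropy %||% 0)),
    noise_sd = max(0, tx$noise_sd + (shift$noise_sd %||% 0)))

  base_gray <- 60
  img <- with_local_seed(spec$seed, {
    wav_j <- .waviness(cols, tx$anisotropy, mean(w))
    wav_a <- .waviness(cols, adult$anisotropy, mean(w))
    x0 <- (seq_len(rows) - 0.5) * vx
    m <- matrix(base_gray, nrow = rows, ncol = cols)
    for (cc in seq_len(cols)) {
      juv_px <- x0 < mat_boundary
      x <- x0 + ifelse(juv_px, wav_j[cc], wav_a[cc])
      amp <- ifelse(juv_px, tx$contrast, adult$contrast) * 127
      g <- rep(base_gray, rows)
      for (i in seq_len(sch$n_years)) {
        d <- x - peaks[i]
        in_band <- abs(d) <= band_L[i] / 2
        if (any(in_band)) {
          g[in_band] <- g[in_band] +
            amp[in_band] * 0.5 * (1 + cos(2 * pi * d[in_band] / (2 * (band_L[i] / 2 + 1e-12))))
        }
      }
      if (hy_um > 0) g[x0 < hy_um] <- base_gray + tx$contrast * 127
      fr0 <- bounds[length(bounds)]
      if (fringe_um > 0) {
        in_fr <- x0 >= fr0 & x0 < fr0 + fringe_um
        g[in_fr] <- base_gray + max(tx$contrast, adult$contrast) * 127
      }
      ns <- ifelse(juv_px, tx$noise_sd, adult$noise_sd)
      if (any(ns > 0)) g <- g + rnorm(rows, 0, ns)
      m[, cc] <- g
    }
    void_centers <- NULL
    if (spec$void_density > 0) {
      area_mm2 <- (rows * vx / 1000) * (cols * vx / 1000)
      n_v <- rpois(1, spec$void_density * area_mm2)
      if (n_v > 0) {
        vr <- runif(n_v, 4, rows - 3)
        vc <- runif(n_v, 4, cols - 3)
        rad <- runif(n_v, 2, 4)
        void_centers <- cbind(row = vr, col = vc, radius_px = rad)
        for (k in seq_len(n_v)) {
          rr <- pmax(1, floor(vr[k] - rad[k])):pmin(rows, ceiling(vr[k] + rad[k]))
          ccs <- pmax(1, floor(vc[k] - rad[k])):pmin(cols, ceiling(vc[k] + rad[k]))
          for (r2 in rr) for (c2 in ccs) {
            if ((r2 - vr[k])^2 + (c2 - vc[k])^2 <= rad[k]^2) m[r2, c2] <- 15
          }
        }
      }
    }
    attr(m, "void_centers") <- void_centers
    m
  })
  void_centers <- attr(img, "void_centers")
  attr(img, "void_centers") <- NULL
  img[] <- pmin(255, pmax(0, floor(img + 0.5)))
  storage.mode(img) <- "integer"

  sc <- straightened_cementum(img, voxel_size_um = vx,
                              provenance = list(specimen_id = "synthetic",
                                                seed = spec$seed))
  gt <- list(peak_positions_um = peaks,
             widths_um = diff(peaks),
             schedule_widths_um = w,
             n_years = sch$n_years,
             maturity_year = spec$maturity_year,
             maturity_boundary_um = if (is.finite(mat_boundary)) mat_boundary else NA_real_,
             hyaline_um = hy_um,
             fringe_start_um = bounds[length(bounds)],
             void_centers = void_centers,
             seed = spec$seed)
  list(image = sc, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of specimens for one or more taxa
#'
#' Renders one synthetic cementum image per specimen. Individual life
#' spans are censored by a discrete uniform draw on `[2, n_years]`, so
#' later years of life are represented by progressively fewer specimens,
#' as in real age-structured samples.
#'
#' @param taxon_specs List of per-taxon descriptors, each a list with
#'   `taxon`, `mass_g`, `spec` (a [synthetic_spec()] whose schedule gives
#'   the maximum life span), `n_specimens`, and optional `rank`
#'   (`"genus"` or `"order"`, default genus) and `category`
#'   (preservational `"a"`/`"b"`/`"c"`, default `"a"`).
#' @param seed Integer master seed; per-specimen seeds derive from it.
#' @param out_dir Optional directory: writes per-specimen TIFFs and a
#'   `metadata.csv`/`ground_truth.csv` pair.
#' @param censor Life-span censoring: `"uniform"` (default) or `"none"`
#'   (all specimens reach `n_years`).
#' @return List with `images` (named list of `straightened_cementum`),
#'   `ground_truth` (named list), and `metadata` (data.frame with
#'   specimen_id, taxon, rank, mass_g, category, voxel_size_um,
#'   true_lifespan).
#' @export
simulate_cohort <- function(taxon_specs, seed = 1L, out_dir = NULL,
                            censor = c("uniform", "none")) {
  censor <- match.arg(censor)
  stopifnot(length(taxon_specs) >= 1)
  images <- list(); gts <- list(); meta <- list()
  idx <- 0L
  for (ts in taxon_specs) {
    stopifnot(ts$n_specimens >= 1, inherits(ts$spec, "synthetic_spec"))
    n_max <- ts$spec$schedule$n_years
    lifespans <- with_local_seed(seed + 1000L * idx, {
      if (censor == "uniform" && n_max > 2) {
        sample(2:n_max, ts$n_specimens, replace = TRUE)
      } else rep(n_max, ts$n_specimens)
    })
    for (j in seq_len(ts$n_specimens)) {
      idx <- idx + 1L
      L <- lifespans[j]
      sch <- ts$spec$schedule
      sch_j <- growth_schedule(sch$model_family, sch$params, L,
                               sch$base_width_um)
      spec_j <- ts$spec
      spec_j$schedule <- sch_j
      if (!is.null(spec_j$maturity_year) && spec_j$maturity_year > L) {
        spec_j$maturity_year <- NULL
      }
      spec_j$seed <- as.integer((seed * 131L + idx * 7L) %% .Machine$integer.max)
      id <- sprintf("%s_%02d", gsub("\\s+", "_", ts$taxon), j)
      out <- render_cementum(spec_j)
      out$image$provenance$specimen_id <- id
      images[[id]] <- out$image
      gts[[id]] <- out$ground_truth
      meta[[id]] <- data.frame(
        specimen_id = id, taxon = ts$taxon,
        rank = ts$rank %||% "genus",
        mass_g = ts$mass_g,
        category = ts$category %||% "a",
        voxel_size_um = spec_j$voxel_size_um,
        true_lifespan = L, stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  res <- list(images = images, ground_truth = gts, metadata = metadata)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(images)) {
      write_cementum_tiff(images[[id]],
                          file.path(out_dir, paste0(id, ".tif")))
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    gt_rows <- do.call(rbind, lapply(names(gts), function(id) {
      g <- gts[[id]]
      data.frame(specimen_id = id,
                 year = seq_along(g$widths_um),
                 width_um = g$widths_um,
                 peak_um = g$peak_positions_um[seq_along(g$widths_um)],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(gt_rows, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  res
}

#' Simulate continuous traits on a phylogeny under Brownian motion
#'
#' Thin, seeded wrapper around [phytools::fastBM()]. Tip traits are
#' multivariate normal with mean `root_state` and covariance
#' `sigma2 * C`, where `C[i, j]` is the shared root-to-tip path length of
#' tips i and j.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), `>= 0`.
#' @param root_state Trait value at the root.
#' @param seed Integer seed.
#' @return Data frame with columns `tip` and `trait`.
#' @export
simulate_phylo_traits <- function(tree, sigma2 = 1, root_state = 0,
                                  seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branches; tips will duplicate ancestors")
  }
  if (sigma2 == 0) {
    return(data.frame(tip = tree$tip.label,
                      trait = rep(root_state, length(tree$tip.label)),
                      stringsAsFactors = FALSE))
  }
  x <- with_local_seed(seed,
                       phytools::fastBM(tree, a = root_state, sig2 = sigma2))
  data.frame(tip = names(x), trait = as.numeric(x),
             stringsAsFactors = FALSE)
}
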