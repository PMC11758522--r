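#' Default pipeline configuration
#'
#' @param taxa List of taxon descriptors for [simulate_cohort()] (each:
#'   `taxon`, `mass_g`, `spec`, `n_specimens`, optional `rank`,
#'   `category`).
#' @param seed Master seed.
#' @param out_dir Output directory for result tables (`NULL` = none).
#' @param n_transects,thickness_px,n_segments Increment-measurement
#'   parameters.
#' @param min_n Minimum specimens per pooled year.
#' @param cutoff_year Juvenile/adult cutoff for texture analysis.
#' @param run_texture Toggle the texture stage.
#' @return A `run_config` list; every defaulted parameter is recorded so
#'   a saved manifest reproduces the run.
#' @export
pipeline_config <- function(taxa, seed = 1L, out_dir = NULL,
                            n_transects = 8L, thickness_px = 10L,
                            n_segments = 5L, min_n = 3L,
                            cutoff_year = 5L, run_texture = TRUE) {
  structure(list(taxa = taxa, seed = as.integer(seed), out_dir = out_dir,
                 n_transects = n_transects, thickness_px = thickness_px,
                 n_segments = n_segments, min_n = min_n,
                 cutoff_year = cutoff_year,
                 run_texture = isTRUE(run_texture)),
            class = "run_config")
}

#' Run the cementochronology pipeline on a synthetic cohort
#'
#' Stages, in dependency order: cohort simulation, increment measurement
#' (transects, peak detection, widths), consensus life spans, cohort
#' filtering, taxon pooling with msGR conversion, growth-model fitting
#' and selection, truncation-window detection, msSMR estimation from
#' life span, and (optionally) juvenile/adult texture comparison. Any
#' stage failure halts with the stage and specimen named.
#'
#' @param config A [pipeline_config()].
#' @return List of result tables: `metadata`, `lifespans` (specimen,
#'   consensus count, dispersion, msSMR), `pooled` (per-taxon per-year
#'   widths and msGR), `model_selection` (per-taxon best family, AIC,
#'   r2), `truncation` (per-taxon window), `texture` (per-taxon hull
#'   overlap, when enabled), `manifest` (the config, serializable).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cohort <- stage("synthgen",
                  simulate_cohort(config$taxa, seed = config$seed))
  meta <- cohort$metadata

  series <- list(); peaksets <- list()
  for (id in names(cohort$images)) {
    stage(paste0("measure:", id), {
      gt <- cohort$ground_truth[[id]]
      region <- trim_region(cohort$images[[id]], gt$hyaline_um,
                            gt$fringe_start_um)
      profs <- extract_transects(region, config$n_transects,
                                 config$thickness_px)
      ps <- lapply(profs, detect_peaks, n_segments = config$n_segments)
      series[[id]] <- lapply(ps, measure_widths)
      peaksets[[id]] <- ps
    })
  }

  lifespans <- stage("lifespan", {
    rows <- lapply(names(series), function(id) {
      ls <- specimen_lifespan(series[[id]])
      data.frame(specimen_id = id, lifespan_years = ls$lifespan_years,
                 count_sd = ls$count_sd,
                 mssmr_mammal = lifespan_to_mssmr(ls$lifespan_years,
                                                  "mammal"))
    })
    do.call(rbind, rows)
  })

  accepted <- stage("filter", filter_cohort(meta))

  pooled_list <- list(); sel_rows <- list(); trunc_rows <- list()
  for (tx in unique(accepted$taxon)) {
    ids <- accepted$specimen_id[accepted$taxon == tx]
    mass <- accepted$mass_g[accepted$taxon == tx][1]
    pooled <- stage(paste0("pool:", tx),
                    pool_taxon(series[ids], tx, mass_g = mass,
                               min_n = config$min_n))
    pooled_list[[tx]] <- pooled
    if (nrow(pooled) >= 4) {
      fits <- stage(paste0("fitgrowth:", tx),
                    fit_models(pooled, seed = config$seed))
      best <- select_best(fits)
      sel_rows[[tx]] <- data.frame(taxon = tx, family = best$family,
                                   aic = best$aic, r2 = best$r2,
                                   runner_up = best$runner_up,
                                   delta_aic = best$delta_aic)
      tw <- find_truncation(pooled)
      trunc_rows[[tx]] <- data.frame(
        taxon = tx,
        trunc_min_age = if (isTRUE(tw$none)) NA_integer_ else tw$min_age,
        trunc_max_age = if (isTRUE(tw$none)) NA_integer_ else tw$max_age)
    }
  }

  texture_tab <- NULL
  if (config$run_texture) {
    tex_rows <- list()
    for (tx in unique(accepted$taxon)) {
      ids <- accepted$specimen_id[accepted$taxon == tx]
      feats <- list(); stages <- character(0)
      for (id in ids) {
        ps <- peaksets[[id]][[1]]
        patches <- tryCatch(
          subsample_patches(cohort$images[[id]], config$cutoff_year, ps),
          error = function(e) NULL)
        if (is.null(patches) || nrow(patches$juvenile$pixels) < 16 ||
            ncol(patches$juvenile$pixels) < 16) next
        for (st in c("juvenile", "adult")) {
          f <- compute_features(patches[[st]])
          if (isTRUE(attr(f, "degenerate"))) next
          feats[[length(feats) + 1]] <- f
          stages <- c(stages, st)
        }
      }
      if (length(feats) >= 6 && length(unique(stages)) == 2 &&
          min(table(stages)) >= 3) {
        X <- do.call(rbind, feats)
        ok <- apply(X, 2, function(v) all(is.finite(v)) && stats::var(v) > 0)
        sp <- texture_pca(X[, ok, drop = FALSE])
        hs <- hull_separation(sp, stages)
        tex_rows[[tx]] <- data.frame(taxon = tx, overlap = hs$overlap,
                                     distinct = hs$distinct)
      }
    }
    texture_tab <- if (length(tex_rows)) do.call(rbind, tex_rows) else NULL
  }

  res <- list(metadata = meta, lifespans = lifespans,
              pooled = do.call(rbind, pooled_list),
              model_selection = do.call(rbind, sel_rows),
              truncation = do.call(rbind, trunc_rows),
              texture = texture_tab,
              manifest = unclass(config)[setdiff(names(config), "taxa")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("metadata", "lifespans", "pooled", "model_selection",
                 "truncation", "texture")) {
      if (!is.null(res[[nm]]) && nrow(res[[nm]])) {
        utils::write.csv(res[[nm]],
                         file.path(config$out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(res$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
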