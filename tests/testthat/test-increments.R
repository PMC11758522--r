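test_that("transect bands tile the region evenly", {
  reg <- straightened_cementum(matrix(100, 60, 80), 1)
  profs <- extract_transects(reg, n_transects = 8, thickness_px = 10)
  expect_length(profs, 8)
  # horizontally constant image: all transects identical
  vals <- vapply(profs, function(p) p$values, numeric(60))
  expect_true(all(apply(vals, 1, function(r) length(unique(r)) == 1)))
  # narrow region: count reduced with warning, < 3 errors
  narrow <- straightened_cementum(matrix(100, 60, 45), 1)
  expect_warning(p2 <- extract_transects(narrow, 8, 10), "supports only")
  expect_length(p2, 4)
  tiny <- straightened_cementum(matrix(100, 60, 25), 1)
  expect_error(extract_transects(tiny, 8, 10), "3 transects")
})

test_that("each transect of a banded image counts the true number of years", {
  sch <- growth_schedule("quadratic", c(11, -0.6, -0.01), 9)
  rt <- render_trimmed(clean_spec(sch, seed = 13))
  counts <- vapply(extract_transects(rt$image), function(p)
    measure_widths(detect_peaks(p))$glg_count, integer(1))
  expect_true(all(counts == rt$ground_truth$n_years))
})

test_that("segment-rule peaks match the brute-force oracle on a clean cosine", {
  i <- 1:100
  v <- 100 + 50 * cos(2 * pi * 5 * (i - 10) / 100)
  prof <- list(values = v, positions_um = as.numeric(i))
  pk <- detect_peaks(prof, n_segments = 5)
  expect_length(pk$peak_positions_um, 5)
  expect_equal(pk$peak_positions_um, c(10, 30, 50, 70, 90),
               tolerance = 0.5 / 10)
  op <- oracle_peaks(v, as.numeric(i))
  expect_equal(length(op), length(pk$peak_positions_um))
  expect_true(all(abs(op - pk$peak_positions_um) <= 0.5))
})

test_that("constant profile yields zero peaks with a degenerate flag", {
  prof <- list(values = rep(80, 40), positions_um = as.numeric(1:40))
  pk <- detect_peaks(prof)
  expect_length(pk$peak_positions_um, 0)
  expect_true(pk$degenerate)
})

test_that("a rectangular pulse localizes to its symmetric center", {
  pos <- as.numeric(0:29)
  v <- rep(10, 30); v[pos %in% 10:14] <- 100
  pk <- detect_peaks(list(values = v, positions_um = pos))
  expect_length(pk$peak_positions_um, 1)
  expect_equal(pk$peak_positions_um, 12)
})

test_that("widths are inter-peak distances with the final year excluded", {
  pk <- structure(list(peak_positions_um = c(5, 15, 25),
                       peak_heights = c(1, 1, 1)), class = "peak_set")
  iw <- measure_widths(pk)
  expect_equal(iw$widths_um, c(10, 10))
  expect_equal(iw$glg_count, 3L)
  expect_equal(iw$complete_years, 2L)
  one <- structure(list(peak_positions_um = 7, peak_heights = 1),
                   class = "peak_set")
  iw1 <- measure_widths(one)
  expect_length(iw1$widths_um, 0)
  expect_equal(iw1$glg_count, 1L)
})

test_that("width conservation: spacings plus end offsets span the cementum", {
  sch <- growth_schedule("hill_sigmoid", c(12, 5, 4, 3), 9,
                         base_width_um = 11)
  rt <- render_trimmed(clean_spec(sch, seed = 31))
  gt <- rt$ground_truth
  prof <- extract_transects(rt$image)[[1]]
  pk <- detect_peaks(prof)
  total <- sum(gt$schedule_widths_um)
  first_off <- pk$peak_positions_um[1] - gt$hyaline_um
  last_part <- gt$hyaline_um + total - max(pk$peak_positions_um)
  covered <- sum(measure_widths(pk)$widths_um) + first_off + last_part
  expect_lt(abs(covered - total), 2)
})

test_that("consensus life span is the mode with ties to the higher count", {
  mk <- function(k) structure(list(widths_um = rep(10, k - 1),
                                   glg_count = k,
                                   complete_years = k - 1L),
                              class = "increment_series")
  expect_equal(specimen_lifespan(lapply(c(8, 8, 8, 7), mk))$lifespan_years, 8)
  expect_equal(specimen_lifespan(lapply(c(7, 8), mk))$lifespan_years, 8)
  out <- specimen_lifespan(lapply(c(9, 9, 10), mk))
  expect_equal(out$lifespan_years, 9)
  expect_gt(out$count_sd, 0)
})

test_that("cohort filter applies category and minimum-sample rules", {
  meta <- data.frame(
    specimen_id = sprintf("s%02d", 1:13),
    taxon = c(rep("GenusA", 3), rep("GenusB", 2), rep("OrderC", 5),
              rep("OrderD", 3)),
    rank = c(rep("genus", 5), rep("order", 8)),
    category = c("a", "a", "b", "a", "a", rep("a", 5), rep("a", 3)))
  acc <- filter_cohort(meta)
  expect_setequal(unique(acc$taxon), c("GenusA", "OrderC"))
  # category c excluded regardless of counts
  meta$category[1] <- "c"
  acc2 <- filter_cohort(meta)
  expect_false("GenusA" %in% acc2$taxon)
})

test_that("taxon pooling averages within specimens first and enforces n >= 3", {
  mk <- function(widths) structure(list(widths_um = widths,
                                        glg_count = length(widths) + 1L,
                                        complete_years = length(widths)),
                                   class = "increment_series")
  series <- list(s1 = list(mk(c(10, 8)), mk(c(10, 8))),
                 s2 = list(mk(c(10, 8, 6))),
                 s3 = list(mk(c(10, 9))))
  tg <- pool_taxon(series, "Tax", min_n = 3)
  expect_equal(nrow(tg), 2)               # year 3 covered by one specimen
  expect_equal(tg$mean_width_um[1], 10)
  expect_equal(tg$sd_width_um[1], 0)
  expect_equal(tg$n_specimens, c(3, 3))
  expect_equal(tg$mean_width_um[2], mean(c(8, 8, 9)))
  # msGR attached when a mass is supplied; heavier taxon smaller msGR
  tg_light <- pool_taxon(series, "Tax", mass_g = 10)
  tg_heavy <- pool_taxon(series, "Tax", mass_g = 100)
  expect_true(all(tg_heavy$msgr < tg_light$msgr))
})

test_that("pooled synthetic cohort recovers schedule widths within 1 SE", {
  sch <- growth_schedule("linear", c(10, -0.5), 8)
  ts <- list(list(taxon = "Pool", mass_g = 30,
                  spec = synthetic_spec(sch, texture_params(0.7, 50, 3),
                                        image_shape = c(110, 96), seed = 1),
                  n_specimens = 20))
  co <- simulate_cohort(ts, seed = 17)
  series <- lapply(names(co$images), function(id) {
    gt <- co$ground_truth[[id]]
    measure_region(trim_region(co$images[[id]], gt$hyaline_um,
                               gt$fringe_start_um))
  })
  names(series) <- names(co$images)
  tg <- pool_taxon(series, "Pool", min_n = 3)
  expect_gt(nrow(tg), 3)
  w <- schedule_widths(sch)
  # ground truth spacings blend adjacent years; compare to that
  for (k in seq_len(nrow(tg))) {
    y <- tg$year[k]
    truth <- 0.6 * w[y] + 0.4 * w[y + 1]
    se <- max(tg$sd_width_um[k] / sqrt(tg$n_specimens[k]), 0.25)
    expect_lt(abs(tg$mean_width_um[k] - truth), 3 * se + 0.5)
  }
})

test_that("count accuracy degrades monotonically with noise", {
  sch <- growth_schedule("linear", c(9, -0.3), 8)
  acc <- vapply(c(0, 8, 20), function(ns) {
    hits <- 0L
    for (s in 1:6) {
      sp <- synthetic_spec(sch, texture_params(0.6, 30, ns),
                           image_shape = c(100, 96), seed = 100 + s)
      rt <- render_trimmed(sp)
      cs <- vapply(extract_transects(rt$image), function(p)
        measure_widths(detect_peaks(p))$glg_count, integer(1))
      if (specimen_lifespan(lapply(cs, function(k)
        structure(list(glg_count = k), class = "increment_series")
      ))$lifespan_years == 8) hits <- hits + 1L
    }
    hits / 6
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1)
})
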