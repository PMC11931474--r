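test_that("median filter: identity cases and impulse rejection", {
  const <- channel_image(matrix(7, 16, 16), 27)
  expect_equal(median_filter_image(const, 2)$pixels, const$pixels)
  expect_equal(median_filter_image(const, 0)$pixels, const$pixels)
  imp <- matrix(0, 16, 16)
  imp[8, 8] <- 100
  expect_true(all(median_filter_image(channel_image(imp, 27), 2)$pixels == 0))
})

test_that("median filter equals the brute-force disc median with reflect padding", {
  set.seed(42)
  for (radius in c(1, 2, 3)) {
    img <- matrix(runif(32 * 32), 32)
    got <- median_filter_image(channel_image(img, 27), radius)$pixels
    expect_equal(got, oracle_median_filter(img, radius))
  }
})

test_that("radius-2 median filtering moves an ideal spot's diameter by under a pixel", {
  # On a noise-free Gaussian spot the disc median slightly erodes the
  # convex suprathreshold boundary; the effect stays below one pixel.
  img <- spot_image(matrix(c(864, 864), 1), amplitudes = 1500)
  prm <- detection_params(min_intensity = 75, noise_tolerance = 50,
                          median_radius = 0, min_area = 0, max_area = 50)
  before <- segment_puncta(img, find_maxima(img, prm), prm)
  filt <- median_filter_image(img, 2)
  after <- segment_puncta(filt, find_maxima(filt, prm), prm)
  expect_lt(abs(after$table$eq_diam_nm - before$table$eq_diam_nm), 27)
})

test_that("a constant image has no maxima; a single spot has exactly one", {
  prm <- detection_params(min_intensity = 0, noise_tolerance = 0)
  expect_identical(nrow(find_maxima(channel_image(matrix(5, 32, 32), 27),
                                    prm)), 0L)
  img <- spot_image(matrix(c(27 * 20.3, 27 * 12.4), 1))
  mx <- find_maxima(img, detection_params(min_intensity = 100,
                                          noise_tolerance = 10))
  expect_identical(nrow(mx), 1L)
  peak <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  expect_equal(c(mx$row, mx$col), unname(peak[1, ]))
  # a point on exact pixel symmetry yields a merged plateau at its centroid
  sym <- spot_image(matrix(c(27 * 20, 27 * 12), 1))
  mx_sym <- find_maxima(sym, detection_params(min_intensity = 100,
                                              noise_tolerance = 10))
  expect_identical(nrow(mx_sym), 1L)
  expect_equal(c(mx_sym$row, mx_sym$col), c(12.5, 20.5))
})

test_that("maxima count flips exactly at the oracle prominence of a saddle", {
  img <- spot_image(rbind(c(533.1, 541.7), c(807.3, 539.9)),
                    amplitudes = c(1000, 700), shape = c(40L, 40L))
  om <- oracle_all_maxima(img$pixels)
  expect_identical(nrow(om), 2L)
  prom2 <- min(om$prominence) # the lower peak
  below <- detection_params(min_intensity = 0, noise_tolerance = prom2 * 0.999)
  above <- detection_params(min_intensity = 0, noise_tolerance = prom2 * 1.001)
  expect_identical(nrow(find_maxima(img, below)), 2L)
  expect_identical(nrow(find_maxima(img, above)), 1L)
})

test_that("find_maxima agrees exactly with the exhaustive prominence oracle", {
  set.seed(7)
  prm <- detection_params(min_intensity = 0, noise_tolerance = 0.15)
  for (i in 1:15) {
    img <- matrix(runif(32 * 32), 32)
    got <- find_maxima(channel_image(img, 27), prm)
    om <- oracle_all_maxima(img)
    om <- om[om$prominence >= 0.15, , drop = FALSE]
    got <- got[order(got$row, got$col), ]
    om <- om[order(om$row, om$col), ]
    expect_identical(nrow(got), nrow(om))
    expect_equal(got$row, om$row)
    expect_equal(got$col, om$col)
    expect_equal(got$prominence, om$prominence, tolerance = 1e-12)
  }
})

test_that("segmentation partitions the suprathreshold support among maxima", {
  prm <- detection_params(min_intensity = 100, noise_tolerance = 20,
                          min_area = 0, max_area = 50)
  one <- spot_image(matrix(c(864, 864), 1))
  ps1 <- segment_puncta(one, find_maxima(one, prm), prm)
  comp <- oracle_flood(one$pixels >= 100,
                       round(ps1$table$row), round(ps1$table$col))
  expect_identical(unname(ps1$labels > 0), unname(comp))
  # two overlapping spots: disjoint masks whose union is the support
  two <- spot_image(rbind(c(702.4, 871.3), c(998.9, 869.1)),
                    amplitudes = c(1200, 900))
  ps2 <- segment_puncta(two, find_maxima(two, prm), prm)
  expect_identical(nrow(ps2$table), 2L)
  expect_identical(unname(ps2$labels > 0), unname(two$pixels >= 100))
  expect_identical(sum(ps2$table$n_px), sum(two$pixels >= 100))
  # blank image
  blank <- channel_image(matrix(0, 32, 32), 27)
  ps0 <- segment_puncta(blank, find_maxima(blank, prm), prm)
  expect_identical(nrow(ps0$table), 0L)
})

test_that("size filtering keeps exactly the in-window puncta", {
  mk_ps <- function(areas_um2) {
    n <- length(areas_um2)
    n_px <- round(areas_um2 / (0.027^2))
    structure(list(
      table = data.frame(id = seq_len(n), row = rep(1, n), col = rep(1, n),
                         x_nm = rep(0, n), y_nm = rep(0, n), peak = rep(1, n),
                         n_px = n_px, area_um2 = n_px * 0.027^2,
                         eq_diam_nm = 2000 * sqrt(n_px * 0.027^2 / pi)),
      labels = matrix(0L, 4, 4), pixel_size_nm = 27, channel = "t",
      params = NULL, fov_shape = c(4L, 4L)), class = "puncta_set")
  }
  ps <- mk_ps(c(0.01, 0.05, 4.9, 5.1))
  got <- suppressMessages(filter_puncta_by_size(ps, 0.05, 5))
  expect_equal(got$table$id, c(2L, 3L))
  # marker window drops a 0.01 um^2 speck
  expect_identical(
    nrow(suppressMessages(filter_puncta_by_size(mk_ps(0.01), 0.02, 5))$table),
    0L)
  # empty in, empty out
  empty <- mk_ps(numeric(0))
  expect_identical(nrow(filter_puncta_by_size(empty, 0.02, 5)$table), 0L)
})

test_that("the filter-effect estimate matches direct recomputation", {
  img <- spot_image(rbind(c(500, 500), c(1200, 1100), c(400, 1300)),
                    amplitudes = c(1500, 1200, 1000))
  prm <- detection_params(min_intensity = 75, noise_tolerance = 50,
                          min_area = 0, max_area = 50)
  before <- segment_puncta(img, find_maxima(img, prm), prm)
  same <- measure_filter_effect(before, before, n_boot = 200)
  expect_identical(same$diff_nm, 0)
  filt_oracle <- channel_image(oracle_median_filter(img$pixels, 2), 27)
  after <- segment_puncta(filt_oracle, find_maxima(filt_oracle, prm), prm)
  eff <- measure_filter_effect(before, after, n_boot = 200)
  expect_equal(eff$diff_nm,
               mean(after$table$eq_diam_nm) - mean(before$table$eq_diam_nm))
  expect_true(eff$ci[1] <= eff$diff_nm && eff$diff_nm <= eff$ci[2])
  empty <- suppressMessages(filter_puncta_by_size(before, 49, 50))
  expect_error(measure_filter_effect(empty, after), "empty")
})

test_that("noiseless detection recovers every true point with no false positives", {
  hits <- 0L
  total <- 0L
  fp <- 0L
  for (s in 1:5) {
    cfg <- synth_config(density_pre = 0.2, paired_fraction_pre = 0,
                        noise_sd = 0, seed = s)
    gt <- generate_synapse_field(cfg)
    img <- render_channel(gt$points$pre, cfg, noise = FALSE)
    mx <- find_maxima(img, detection_params(min_intensity = 75,
                                            noise_tolerance = 50))
    d_true <- oracle_nn(cbind(gt$points$pre$x_nm, gt$points$pre$y_nm),
                        cbind(mx$x_nm, mx$y_nm))
    hits <- hits + sum(d_true <= 2 * 27)
    total <- total + nrow(gt$points$pre)
    d_max <- oracle_nn(cbind(mx$x_nm, mx$y_nm),
                       cbind(gt$points$pre$x_nm, gt$points$pre$y_nm))
    fp <- fp + sum(d_max > 2 * 27)
  }
  expect_gte(hits / total, 0.99)
  expect_identical(fp, 0L)
})

test_that("recall does not increase with read noise", {
  recall_at <- function(noise_sd) {
    hits <- 0L
    total <- 0L
    for (s in 1:3) {
      cfg <- synth_config(density_pre = 0.2, paired_fraction_pre = 0,
                          noise_sd = noise_sd, seed = s)
      gt <- generate_synapse_field(cfg)
      img <- render_channel(gt$points$pre, cfg, noise = noise_sd > 0,
                            seed = s + 70)
      mx <- find_maxima(img, detection_params(min_intensity = 75,
                                              noise_tolerance = 50))
      if (nrow(mx) > 0) {
        d_true <- oracle_nn(cbind(gt$points$pre$x_nm, gt$points$pre$y_nm),
                            cbind(mx$x_nm, mx$y_nm))
        hits <- hits + sum(d_true <= 2 * 27)
      }
      total <- total + nrow(gt$points$pre)
    }
    hits / total
  }
  r <- vapply(c(0, 40, 120), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_gte(r[1], 0.99)
})

test_that("FISH particle counting matches connected-component counting", {
  blank <- channel_image(matrix(0, 64, 64), 27)
  rois <- list(matrix(rep(c(TRUE, FALSE), each = 64 * 32), 64),
               matrix(rep(c(FALSE, TRUE), each = 64 * 32), 64))
  expect_identical(count_fish_particles(blank, rois, 2, 10), c(0L, 0L))
  expect_identical(count_fish_particles(blank, list(), 2, 10), integer(0))
  # k well-separated spots inside one ROI
  img <- spot_image(rbind(c(200, 300), c(700, 300), c(300, 900), c(760, 1200)),
                    amplitudes = 1500)
  left <- matrix(FALSE, 64, 64)
  left[, 1:40] <- TRUE
  got <- count_fish_particles(img, list(left), blur_sigma = 2,
                              threshold = 100)
  sm <- synaptica:::gaussian_blur(img$pixels, 2)
  expect_identical(got, oracle_component_count(sm >= 100 & left))
  # negative-control style calibration: a high threshold keeps counts <= 3
  set.seed(1)
  noise <- channel_image(matrix(pmax(rnorm(64 * 64, 20, 10), 0), 64), 27)
  expect_lte(count_fish_particles(noise, list(left), 2, 45), 3L)
})
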