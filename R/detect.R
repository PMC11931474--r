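#' Per-channel puncta detection parameters
#'
#' Mirrors ImageJ-style detection settings: an intensity window for accepted
#' maxima, a noise tolerance (minimum topographic prominence: peak minus the
#' highest saddle connecting it to a higher maximum), a median pre-filter
#' radius, and calibrated particle-size thresholds. Size thresholds default
#' to the synaptic-marker convention (0.02-5 um^2); use 0.05 for the
#' receptor channels.
#'
#' @param min_intensity,max_intensity accepted peak intensity range;
#'   `min_intensity` is also the segmentation support threshold.
#' @param noise_tolerance minimum prominence of an accepted maximum (>= 0).
#' @param median_radius disc radius (pixels) of the median pre-filter
#'   (0 = no filtering; default 2).
#' @param min_area,max_area particle size window in um^2.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_intensity, max_intensity = Inf,
                             noise_tolerance = 0, median_radius = 2L,
                             min_area = 0.02, max_area = 5) {
  if (!(min_intensity <= max_intensity))
    stop("min_intensity must be <= max_intensity")
  if (noise_tolerance < 0) stop("noise_tolerance must be >= 0")
  if (!(min_area >= 0 && min_area < max_area))
    stop("need 0 <= min_area < max_area")
  if (median_radius < 0) stop("median_radius must be >= 0")
  structure(list(min_intensity = min_intensity, max_intensity = max_intensity,
                 noise_tolerance = noise_tolerance,
                 median_radius = as.integer(median_radius),
                 min_area = min_area, max_area = max_area),
            class = "detection_params")
}

#' Median-filter a channel image over a disc neighborhood
#'
#' Each pixel is replaced by the median over the disc of the given radius
#' (pixels with `dr^2 + dc^2 <= radius^2`), with reflect padding at the
#' borders so diameter measurements are not biased by dark edges. Radius 0
#' is the identity.
#'
#' @param img a [channel_image].
#' @param radius integer disc radius in pixels.
#' @return The filtered [channel_image].
#' @export
median_filter_image <- function(img, radius = 2L) {
  stopifnot(inherits(img, "channel_image"), radius >= 0)
  if (radius == 0) return(img)
  channel_image(.median_filter_disc_cpp(img$pixels, as.integer(radius)),
                img$pixel_size_nm, img$channel)
}

#' Find intensity maxima by topographic prominence
#'
#' Returns the local maxima whose peak intensity lies in
#' `[min_intensity, max_intensity]` and whose prominence (peak minus the
#' highest saddle connecting it to a higher maximum; the global maximum uses
#' peak minus the image minimum) is at least `noise_tolerance` and strictly
#' positive (a perfectly flat image has no maxima). Equal-valued
#' summit plateaus are merged and reported at the plateau centroid (possibly
#' fractional pixel coordinates).
#'
#' @param img a [channel_image].
#' @param params a [detection_params()].
#' @return Data frame with columns `row`, `col` (1-based, possibly
#'   fractional), `x_nm`, `y_nm`, `peak`, `prominence`, ordered by
#'   decreasing peak intensity.
#' @export
find_maxima <- function(img, params) {
  stopifnot(inherits(img, "channel_image"), inherits(params, "detection_params"))
  mx <- .find_maxima_cpp(img$pixels)
  keep <- mx$peak >= params$min_intensity & mx$peak <= params$max_intensity &
    mx$prominence >= params$noise_tolerance & mx$prominence > 0
  mx <- mx[keep, , drop = FALSE]
  mx <- mx[order(-mx$peak), , drop = FALSE]
  mx$x_nm <- (mx$col - 0.5) * img$pixel_size_nm
  mx$y_nm <- (mx$row - 0.5) * img$pixel_size_nm
  rownames(mx) <- NULL
  mx[, c("row", "col", "x_nm", "y_nm", "peak", "prominence")]
}

#' Segment puncta around detected maxima
#'
#' One punctum per maximum: the suprathreshold support
#' (`pixels >= min_intensity`) is partitioned among the maxima by a
#' marker-seeded watershed on inverted intensity (regions grow downhill from
#' each seed, brightest frontier first), so masks are disjoint by
#' construction. Maxima falling outside the suprathreshold support are
#' dropped with a message.
#'
#' @param img the [channel_image] the maxima were detected on.
#' @param maxima result of [find_maxima()] on the same image.
#' @param params the same [detection_params()].
#' @return A `puncta_set`: list with `$table` (one row per punctum: `id`,
#'   `row`, `col`, `x_nm`, `y_nm`, `peak`, `n_px`, `area_um2`,
#'   `eq_diam_nm`), `$labels` (integer pixel matrix, 0 = background),
#'   `$pixel_size_nm`, `$channel`, `$params`, `$fov_shape`.
#' @export
segment_puncta <- function(img, maxima, params) {
  stopifnot(inherits(img, "channel_image"))
  nr <- nrow(img$pixels)
  nc <- ncol(img$pixels)
  mask <- img$pixels >= params$min_intensity
  seeds <- matrix(0L, nr, nc)
  sr <- pmin(pmax(round(maxima$row), 1L), nr)
  sc <- pmin(pmax(round(maxima$col), 1L), nc)
  ok <- rep(TRUE, length(sr))
  for (i in seq_along(sr)) {
    if (!mask[sr[i], sc[i]] || seeds[sr[i], sc[i]] != 0L) {
      ok[i] <- FALSE
    } else {
      seeds[sr[i], sc[i]] <- i
    }
  }
  if (any(!ok))
    message(sum(!ok), " maxima outside the threshold support were dropped")
  labels <- .seeded_watershed_cpp(img$pixels, seeds, mask)
  kept <- which(ok)
  n_px <- tabulate(labels[labels > 0], nbins = length(sr))
  px <- img$pixel_size_nm
  tab <- data.frame(
    id = seq_along(kept),
    row = maxima$row[kept], col = maxima$col[kept],
    x_nm = maxima$x_nm[kept], y_nm = maxima$y_nm[kept],
    peak = maxima$peak[kept],
    n_px = n_px[kept]
  )
  tab$area_um2 <- tab$n_px * (px / 1000)^2
  tab$eq_diam_nm <- 2000 * sqrt(tab$area_um2 / pi)
  # renumber labels to the kept ids
  relab <- integer(length(sr))
  relab[kept] <- seq_along(kept)
  pos <- labels > 0
  labels[pos] <- relab[labels[pos]]
  structure(list(table = tab, labels = labels, pixel_size_nm = px,
                 channel = img$channel, params = params,
                 fov_shape = c(nr, nc)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %s: %d puncta on %d x %d px (%.1f nm/px)\n",
              if (nzchar(x$channel)) x$channel else "(unlabeled)",
              nrow(x$table), x$fov_shape[1], x$fov_shape[2], x$pixel_size_nm))
  invisible(x)
}

#' Detect puncta in one channel (filter, find maxima, segment, size-gate)
#'
#' Convenience composition of [median_filter_image()], [find_maxima()],
#' [segment_puncta()] and [filter_puncta_by_size()].
#'
#' @inheritParams find_maxima
#' @return A `puncta_set`.
#' @export
detect_puncta <- function(img, params) {
  f <- median_filter_image(img, params$median_radius)
  mx <- find_maxima(f, params)
  ps <- segment_puncta(f, mx, params)
  filter_puncta_by_size(ps, params$min_area, params$max_area)
}

#' Filter a puncta set by calibrated particle size
#'
#' Keeps puncta with `min_area <= area <= max_area` (um^2); the removed
#' count is reported with a message. Masks of removed puncta are cleared
#' from the label image.
#'
#' @param ps a `puncta_set`.
#' @param min_area,max_area size window in um^2.
#' @return The filtered `puncta_set`.
#' @export
filter_puncta_by_size <- function(ps, min_area, max_area) {
  stopifnot(inherits(ps, "puncta_set"), min_area >= 0, min_area < max_area)
  keep <- ps$table$area_um2 >= min_area & ps$table$area_um2 <= max_area
  if (any(!keep)) {
    message(sum(!keep), " puncta removed by size filter [", min_area, ", ",
            max_area, "] um^2")
    drop_ids <- ps$table$id[!keep]
    ps$labels[ps$labels %in% drop_ids] <- 0L
  }
  ps$table <- ps$table[keep, , drop = FALSE]
  rownames(ps$table) <- NULL
  ps
}

#' Effect of the median pre-filter on puncta diameter
#'
#' Difference in mean equivalent diameter (nm) between two detections of the
#' same image (typically with and without the median filter, at identical
#' thresholds), with a percentile-bootstrap 95% CI resampling puncta within
#' each set independently.
#'
#' @param before,after `puncta_set`s from the same image and thresholds.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @return list with `diff_nm`, `ci` (length 2), `n_before`, `n_after`.
#' @export
measure_filter_effect <- function(before, after, n_boot = 2000, conf = 0.95) {
  stopifnot(inherits(before, "puncta_set"), inherits(after, "puncta_set"))
  db <- before$table$eq_diam_nm
  da <- after$table$eq_diam_nm
  if (length(db) == 0 || length(da) == 0)
    stop("cannot measure the filter effect on an empty puncta set")
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(da, replace = TRUE)) - mean(sample(db, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(diff_nm = mean(da) - mean(db),
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       n_before = length(db), n_after = length(da))
}

# separable Gaussian blur with reflect padding (sigma in pixels)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- ceiling(3 * sigma)
  k <- dnorm(-w:w, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(w) + 1L), seq_len(n), n - seq_len(w)) # reflect
    vp <- v[pmin(pmax(idx, 1L), n)]
    out <- numeric(n)
    for (j in seq_len(n)) out[j] <- sum(vp[j:(j + 2 * w)] * k)
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Count FISH particles per ROI
#'
#' Applies a Gaussian blur, thresholds, and counts 8-connected
#' suprathreshold components inside each ROI (a component is attributed to
#' an ROI when it touches it). The threshold is meant to be calibrated once
#' per hybridization batch against negative controls (at most ~3 particles
#' per cell) and held constant.
#'
#' @param img a [channel_image].
#' @param roi_masks list of logical matrices (disjoint ROIs), same shape as
#'   the image.
#' @param blur_sigma Gaussian sigma in pixels (>= 0).
#' @param threshold intensity threshold applied after blurring.
#' @return Integer vector of particle counts, one per ROI (empty for an
#'   empty ROI list).
#' @export
count_fish_particles <- function(img, roi_masks, blur_sigma = 2,
                                 threshold) {
  stopifnot(inherits(img, "channel_image"), blur_sigma >= 0)
  if (length(roi_masks) == 0) return(integer(0))
  sm <- gaussian_blur(img$pixels, blur_sigma)
  labs <- .label_components_cpp(sm >= threshold)
  vapply(roi_masks, function(roi) {
    stopifnot(identical(dim(roi), dim(img$pixels)))
    length(setdiff(unique(labs[roi]), 0L))
  }, integer(1))
}
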