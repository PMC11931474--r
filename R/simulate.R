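#' Generate a ground-truthed synthetic synapse field
#'
#' Draws Poisson-distributed presynaptic, postsynaptic and receptor point
#' populations inside the configured FOV. A configurable fraction of
#' presynaptic puncta receive a postsynaptic partner at a radial offset drawn
#' from a gamma distribution matched to the configured median/IQR; each such
#' pair is a synapse. Synapses are gated to VGLUT1/VGLUT2 input types with
#' the configured fractions (VGLUT masks are discs around the presynaptic
#' position: numerous small VGLUT1 terminals, sparse large VGLUT2 terminals)
#' and carry postsynaptic / presynaptic receptor puncta with the configured
#' probabilities; receptor puncta not attached to a synapse are placed
#' uniformly (extrasynaptic). Deterministic given the config (seed included).
#'
#' @param config a [synth_config()].
#' @return An object of class `ground_truth`: per-channel point tables
#'   (`$points$pre`, `$points$post`, `$points$receptor` with columns
#'   `id, x_nm, y_nm, amplitude`), `$pairing` (`synapse_id, pre_id, post_id,
#'   offset_nm`), `$receptor_assignment` (`receptor_id, synapse_id,
#'   compartment, offset_nm`), `$input_labels` (`synapse_id, label`),
#'   `$vglut_masks` (logical pixel grids) and the resolved `$config`.
#' @export
generate_synapse_field <- function(config) {
  config <- validate_synth_config(unclass(config))
  set.seed(config$seed)
  px <- config$pixel_size
  h_nm <- config$fov_shape[1] * px
  w_nm <- config$fov_shape[2] * px
  area_um2 <- (w_nm / 1000) * (h_nm / 1000)
  fov <- fov_rect(w_nm, h_nm)

  amp <- function(n) {
    if (n == 0) return(numeric(0))
    pmax(config$amplitude_mean *
           (1 + config$amplitude_cv * rnorm(n)), config$amplitude_mean * 0.05)
  }
  # radial displacement at a gamma-distributed distance, resampled until the
  # displaced point stays inside the FOV
  displace <- function(xy, gpar) {
    out <- matrix(NA_real_, nrow(xy), 2)
    off <- numeric(nrow(xy))
    for (i in seq_len(nrow(xy))) {
      repeat {
        r <- rgamma(1, shape = gpar$shape, scale = gpar$scale)
        th <- runif(1, 0, 2 * pi)
        p <- xy[i, ] + r * c(cos(th), sin(th))
        if (p[1] >= 0 && p[1] <= w_nm && p[2] >= 0 && p[2] <= h_nm) {
          out[i, ] <- p
          off[i] <- r
          break
        }
      }
    }
    list(xy = out, offset = off)
  }

  # presynaptic channel
  n_pre <- rpois(1, config$density_pre * area_um2)
  pre_xy <- runif_fov(n_pre, fov)
  paired <- if (n_pre > 0)
    which(runif(n_pre) < config$paired_fraction_pre) else integer(0)

  # paired postsynaptic partners + independent unpaired post puncta
  gpost <- gamma_from_median_iqr(config$offset_median, config$offset_iqr)
  dp <- if (length(paired) > 0)
    displace(pre_xy[paired, , drop = FALSE], gpost)
  else list(xy = matrix(numeric(0), 0, 2), offset = numeric(0))
  n_post_total <- rpois(1, config$density_post * area_um2)
  n_post_free <- max(0L, n_post_total - length(paired))
  post_xy <- rbind(dp$xy, runif_fov(n_post_free, fov))
  n_post <- nrow(post_xy)

  pairing <- data.frame(
    synapse_id = seq_along(paired),
    pre_id = paired,
    post_id = seq_along(paired),
    offset_nm = dp$offset
  )
  n_syn <- nrow(pairing)

  # input-type gating
  u <- runif(n_syn)
  label <- rep("none", n_syn)
  label[u < config$vglut2_fraction] <- "VGLUT2"
  label[u >= config$vglut2_fraction &
          u < config$vglut2_fraction + config$vglut1_fraction] <- "VGLUT1"
  input_labels <- data.frame(synapse_id = pairing$synapse_id, label = label)

  vglut_masks <- list(
    vglut1 = disc_mask(pre_xy[pairing$pre_id[label == "VGLUT1"], , drop = FALSE],
                       config$vglut1_terminal_radius, config$fov_shape, px),
    vglut2 = disc_mask(pre_xy[pairing$pre_id[label == "VGLUT2"], , drop = FALSE],
                       config$vglut2_terminal_radius, config$fov_shape, px)
  )

  # receptor channel: synapse-attached then extrasynaptic
  grec <- gamma_from_median_iqr(config$receptor_offset_median,
                                config$receptor_offset_iqr)
  rec_xy <- matrix(numeric(0), 0, 2)
  rec_assign <- data.frame(receptor_id = integer(0), synapse_id = integer(0),
                           compartment = character(0), offset_nm = numeric(0))
  add_attached <- function(anchor_xy, syn_ids, compartment) {
    if (nrow(anchor_xy) == 0) return()
    d <- displace(anchor_xy, grec)
    ids <- nrow(rec_xy) + seq_len(nrow(anchor_xy))
    rec_xy <<- rbind(rec_xy, d$xy)
    rec_assign <<- rbind(rec_assign, data.frame(
      receptor_id = ids, synapse_id = syn_ids,
      compartment = compartment, offset_nm = d$offset))
  }
  has_post_rec <- which(runif(n_syn) < config$receptor_post_prob)
  add_attached(post_xy[pairing$post_id[has_post_rec], , drop = FALSE],
               pairing$synapse_id[has_post_rec], "post")
  has_pre_rec <- which(runif(n_syn) < config$receptor_pre_prob)
  add_attached(pre_xy[pairing$pre_id[has_pre_rec], , drop = FALSE],
               pairing$synapse_id[has_pre_rec], "pre")
  n_rec_total <- rpois(1, config$density_receptor * area_um2)
  n_extra <- max(0L, n_rec_total - nrow(rec_xy))
  if (n_extra > 0) {
    ids <- nrow(rec_xy) + seq_len(n_extra)
    rec_xy <- rbind(rec_xy, runif_fov(n_extra, fov))
    rec_assign <- rbind(rec_assign, data.frame(
      receptor_id = ids, synapse_id = NA_integer_,
      compartment = "none", offset_nm = NA_real_))
  }

  pt_df <- function(xy) {
    n <- nrow(xy)
    data.frame(id = seq_len(n),
               x_nm = if (n) xy[, 1] else numeric(0),
               y_nm = if (n) xy[, 2] else numeric(0),
               amplitude = amp(n))
  }
  structure(list(
    points = list(pre = pt_df(pre_xy), post = pt_df(post_xy),
                  receptor = pt_df(rec_xy)),
    pairing = pairing,
    receptor_assignment = rec_assign,
    input_labels = input_labels,
    vglut_masks = vglut_masks,
    fov = fov,
    config = config
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d pre, %d post, %d receptor puncta; %d synapses (%d VGLUT1, %d VGLUT2)\n",
    nrow(x$points$pre), nrow(x$points$post), nrow(x$points$receptor),
    nrow(x$pairing), sum(x$input_labels$label == "VGLUT1"),
    sum(x$input_labels$label == "VGLUT2")))
  invisible(x)
}

# logical pixel grid with discs of given radius (nm) around centres (nm)
disc_mask <- function(centres, radius_nm, fov_shape, pixel_size) {
  m <- matrix(FALSE, fov_shape[1], fov_shape[2])
  if (nrow(centres) == 0) return(m)
  rpx <- ceiling(radius_nm / pixel_size)
  for (i in seq_len(nrow(centres))) {
    c0 <- centres[i, 1] / pixel_size + 0.5 # fractional col of centre
    r0 <- centres[i, 2] / pixel_size + 0.5
    cols <- max(1, floor(c0 - rpx)):min(fov_shape[2], ceiling(c0 + rpx))
    rows <- max(1, floor(r0 - rpx)):min(fov_shape[1], ceiling(r0 + rpx))
    dx2 <- ((cols - c0) * pixel_size)^2
    dy2 <- ((rows - r0) * pixel_size)^2
    m[rows, cols] <- m[rows, cols] | outer(dy2, dx2, `+`) <= radius_nm^2
  }
  m
}

#' Render a point list as a fluorescence channel image
#'
#' Forward imaging model: constant background plus one isotropic Gaussian of
#' the configured PSF sigma per point, scaled by its amplitude, plus i.i.d.
#' Gaussian read noise; pixel values are clipped at zero. Each Gaussian is
#' evaluated on a window of +/- 5 sigma around the point.
#'
#' @param points data frame with `x_nm`, `y_nm`, `amplitude` columns (or an
#'   n x 2 coordinate matrix, in which case the configured mean amplitude is
#'   used), coordinates inside the FOV.
#' @param config a [synth_config()].
#' @param channel label for the returned image.
#' @param noise if `FALSE`, the read-noise term is omitted regardless of
#'   `config$noise_sd` (useful for truth-recovery tests).
#' @param seed optional seed for the noise draw; `NULL` uses the current RNG
#'   stream.
#' @return A [channel_image].
#' @export
render_channel <- function(points, config, channel = "", noise = TRUE,
                           seed = NULL) {
  config <- validate_synth_config(unclass(config))
  px <- config$pixel_size
  if (config$psf_sigma < px / 4)
    warning("psf_sigma < pixel_size / 4: the PSF is undersampled")
  nr <- config$fov_shape[1]
  nc <- config$fov_shape[2]
  if (is.matrix(points))
    points <- data.frame(x_nm = points[, 1], y_nm = points[, 2],
                         amplitude = config$amplitude_mean)
  if (nrow(points) > 0) {
    if (any(points$x_nm < 0 | points$x_nm > nc * px |
            points$y_nm < 0 | points$y_nm > nr * px))
      stop("point coordinates outside the FOV")
  }
  img <- matrix(config$background, nr, nc)
  s_px <- config$psf_sigma / px
  w <- ceiling(5 * s_px)
  for (i in seq_len(nrow(points))) {
    c0 <- points$x_nm[i] / px + 0.5 # fractional pixel coords of the point
    r0 <- points$y_nm[i] / px + 0.5
    cols <- max(1, floor(c0 - w)):min(nc, ceiling(c0 + w))
    rows <- max(1, floor(r0 - w)):min(nr, ceiling(r0 + w))
    gx <- exp(-((cols - c0)^2) / (2 * s_px^2))
    gy <- exp(-((rows - r0)^2) / (2 * s_px^2))
    img[rows, cols] <- img[rows, cols] + points$amplitude[i] * outer(gy, gx)
  }
  if (noise && config$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  }
  img[img < 0] <- 0
  channel_image(img, pixel_size_nm = px, channel = channel)
}

#' Render every channel of a ground-truth field
#'
#' @param gt a [generate_synapse_field()] result.
#' @param noise as in [render_channel()]; noise seeds are derived from the
#'   config seed per channel, so rendering is deterministic.
#' @return Named list of [channel_image]s (`pre`, `post`, `receptor`), plus
#'   `vglut1`/`vglut2` intensity images rendered from the truth masks
#'   (mask x mean amplitude + background + noise).
#' @export
render_ground_truth <- function(gt, noise = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  cfg <- gt$config
  out <- list(
    pre = render_channel(gt$points$pre, cfg, "pre", noise, cfg$seed + 101L),
    post = render_channel(gt$points$post, cfg, "post", noise, cfg$seed + 102L),
    receptor = render_channel(gt$points$receptor, cfg, "receptor", noise,
                              cfg$seed + 103L)
  )
  for (k in c("vglut1", "vglut2")) {
    img <- cfg$background + cfg$amplitude_mean * gt$vglut_masks[[k]]
    if (noise && cfg$noise_sd > 0) {
      set.seed(cfg$seed + if (k == "vglut1") 104L else 105L)
      img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd), nrow(img))
    }
    img[img < 0] <- 0
    out[[k]] <- channel_image(img, cfg$pixel_size, k)
  }
  out
}

#' Rotate a channel image or point set by quarter turns about the FOV centre
#'
#' The rotated-signal control: a rigid 90-degree rotation destroys any
#' cross-channel pairing while preserving each channel's internal geometry.
#' One quarter turn maps a point `(x, y)` in a `W x W` FOV to `(y, W - x)`.
#'
#' @param x a [channel_image], or an n x 2 matrix / data frame of `x_nm`,
#'   `y_nm` coordinates (then `width_nm` is required).
#' @param quarter_turns integer number of 90-degree turns.
#' @param width_nm FOV side length in nm (points input only).
#' @param on_nonsquare `"error"` (default) refuses odd quarter-turns of a
#'   non-square FOV; `"crop"` first crops the image to its central square.
#' @return The rotated object of the same kind.
#' @export
rotate_channel_control <- function(x, quarter_turns = 1L, width_nm = NULL,
                                   on_nonsquare = c("error", "crop")) {
  on_nonsquare <- match.arg(on_nonsquare)
  k <- ((as.integer(quarter_turns) %% 4L) + 4L) %% 4L
  if (inherits(x, "channel_image")) {
    m <- x$pixels
    if (nrow(m) != ncol(m) && k %% 2L == 1L) {
      if (on_nonsquare == "error")
        stop("odd quarter-turn of a non-square FOV; use on_nonsquare = \"crop\"")
      side <- min(dim(m))
      r0 <- floor((nrow(m) - side) / 2)
      c0 <- floor((ncol(m) - side) / 2)
      m <- m[r0 + seq_len(side), c0 + seq_len(side)]
    }
    for (i in seq_len(k)) m <- t(m[, ncol(m):1, drop = FALSE])
    return(channel_image(m, x$pixel_size_nm, x$channel))
  }
  if (is.data.frame(x)) {
    xy <- cbind(x$x_nm, x$y_nm)
  } else xy <- as.matrix(x)
  if (is.null(width_nm)) stop("width_nm is required to rotate point sets")
  for (i in seq_len(k)) xy <- cbind(xy[, 2], width_nm - xy[, 1])
  if (is.data.frame(x)) {
    x$x_nm <- xy[, 1]
    x$y_nm <- xy[, 2]
    x
  } else {
    colnames(xy) <- c("x", "y")
    xy
  }
}

#' Write a simulated field to disk
#'
#' Writes one 16-bit grayscale TIFF per channel plus plain-text truth tables:
#' `points.csv` (channel, id, x_nm, y_nm, amplitude), `pairing.csv`,
#' `receptor_assignment.csv`, `input_labels.csv`, and the resolved config as
#' `config.yaml`.
#'
#' @param gt a [generate_synapse_field()] result.
#' @param dir output directory (created if missing).
#' @param noise passed to [render_ground_truth()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(gt, dir, noise = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- render_ground_truth(gt, noise = noise)
  for (ch in names(imgs))
    write_channel_tiff(imgs[[ch]], file.path(dir, paste0(ch, ".tif")))
  pts <- do.call(rbind, lapply(names(gt$points), function(ch)
    cbind(channel = ch, gt$points[[ch]])))
  write.csv(pts, file.path(dir, "points.csv"), row.names = FALSE)
  write.csv(gt$pairing, file.path(dir, "pairing.csv"), row.names = FALSE)
  write.csv(gt$receptor_assignment,
            file.path(dir, "receptor_assignment.csv"), row.names = FALSE)
  write.csv(gt$input_labels, file.path(dir, "input_labels.csv"),
            row.names = FALSE)
  yaml::write_yaml(unclass(gt$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
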