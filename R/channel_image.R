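#' Single-channel image with physical pixel size
#'
#' The unit of all detection: a 2D non-negative intensity grid together with
#' its physical pixel size in nanometres and a channel label. The matrix is
#' indexed `[row, col]` with the origin at the top-left pixel; a point at
#' physical position `(x_nm, y_nm)` falls in column `ceiling(x_nm / pixel_size)`
#' and row `ceiling(y_nm / pixel_size)` (pixel centres at `(i - 0.5) * pixel_size`).
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_nm physical size of one pixel in nm (default 27, typical
#'   of 4x optical-reassignment spinning-disk acquisition).
#' @param channel free-text channel label (e.g. `"bassoon"`, `"homer"`).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_nm = 27, channel = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must contain only finite intensities")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel = as.character(channel)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px, %.1f nm/px, range [%.4g, %.4g]\n",
              if (nzchar(x$channel)) x$channel else "(unlabeled)",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Read a single-plane grayscale TIFF as a channel image
#'
#' 8- or 16-bit TIFFs are rescaled back to their integer intensity range
#' (the `tiff` package reads into `[0, 1]`).
#'
#' @param path path to a TIFF file.
#' @inheritParams channel_image
#' @return A [channel_image].
#' @export
read_channel_tiff <- function(path, pixel_size_nm = 27, channel = "") {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] != 1)
      stop("expected a single-plane grayscale TIFF: ", path)
    raw <- raw[, , 1]
  }
  channel_image(raw * 1.0, pixel_size_nm = pixel_size_nm, channel = channel)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Intensities are clipped to `[0, 65535]` and rounded.
#'
#' @param img a [channel_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  px <- round(pmin(pmax(img$pixels, 0), 65535))
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' FOV geometry helper
#'
#' Rectangular or disc field-of-view descriptions used by the point-pattern
#' operations. Sizes are in nm.
#'
#' @param width,height extents of a rectangular FOV in nm.
#' @param radius radius of a disc FOV in nm.
#' @return A list with class `fov_geometry`.
#' @export
fov_rect <- function(width, height = width) {
  stopifnot(width > 0, height > 0)
  structure(list(shape = "rect", width = width, height = height,
                 area = width * height),
            class = "fov_geometry")
}

#' @rdname fov_rect
#' @export
fov_disc <- function(radius) {
  stopifnot(radius > 0)
  structure(list(shape = "disc", radius = radius, area = pi * radius^2),
            class = "fov_geometry")
}

#' Draw uniform points inside an FOV
#' @param n number of points.
#' @param fov a [fov_rect()] or [fov_disc()].
#' @return n x 2 matrix of (x, y) nm coordinates.
#' @keywords internal
runif_fov <- function(n, fov) {
  if (fov$shape == "rect") {
    cbind(x = runif(n, 0, fov$width), y = runif(n, 0, fov$height))
  } else {
    r <- fov$radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  }
}

#' Regular grid of points covering an FOV
#' @param spacing grid spacing in nm.
#' @inheritParams runif_fov
#' @keywords internal
grid_fov <- function(fov, spacing) {
  if (fov$shape == "rect") {
    gx <- seq(spacing / 2, fov$width, by = spacing)
    gy <- seq(spacing / 2, fov$height, by = spacing)
    as.matrix(expand.grid(x = gx, y = gy))
  } else {
    g <- seq(-fov$radius + spacing / 2, fov$radius, by = spacing)
    pts <- as.matrix(expand.grid(x = g, y = g))
    pts[pts[, 1]^2 + pts[, 2]^2 <= fov$radius^2, , drop = FALSE]
  }
}
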