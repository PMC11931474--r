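#' Write a puncta set as CSV plus a label-mask TIFF
#'
#' Writes `<prefix>_puncta.csv` (id, x_px, y_px, x_nm, y_nm, area_um2, peak,
#' eq_diam_nm; pixel coordinates 0-based, origin top-left) and
#' `<prefix>_labels.tif`, a 16-bit image whose pixel values are punctum ids
#' (0 = background).
#'
#' @param ps a `puncta_set`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_puncta_set <- function(ps, prefix) {
  stopifnot(inherits(ps, "puncta_set"))
  tab <- data.frame(
    id = ps$table$id,
    x_px = ps$table$col - 1, y_px = ps$table$row - 1,
    x_nm = ps$table$x_nm, y_nm = ps$table$y_nm,
    area_um2 = ps$table$area_um2, peak = ps$table$peak,
    eq_diam_nm = ps$table$eq_diam_nm
  )
  write.csv(tab, paste0(prefix, "_puncta.csv"), row.names = FALSE)
  if (max(ps$labels) > 65535)
    stop("more than 65535 puncta cannot be stored in a 16-bit label mask")
  tiff::writeTIFF(ps$labels / 65535, paste0(prefix, "_labels.tif"),
                  bits.per.sample = 16L)
  invisible(prefix)
}

#' Read a puncta set written by [write_puncta_set()]
#'
#' @param prefix the path prefix used when writing.
#' @param pixel_size_nm physical pixel size of the source image.
#' @param channel channel label.
#' @return A `puncta_set` (without detection parameters).
#' @export
read_puncta_set <- function(prefix, pixel_size_nm = 27, channel = "") {
  tab <- read.csv(paste0(prefix, "_puncta.csv"))
  labels <- round(tiff::readTIFF(paste0(prefix, "_labels.tif")) * 65535)
  storage.mode(labels) <- "integer"
  n_px <- tabulate(labels[labels > 0], nbins = max(tab$id, 0))
  structure(list(
    table = data.frame(id = tab$id, row = tab$y_px + 1, col = tab$x_px + 1,
                       x_nm = tab$x_nm, y_nm = tab$y_nm, peak = tab$peak,
                       n_px = n_px[tab$id], area_um2 = tab$area_um2,
                       eq_diam_nm = tab$eq_diam_nm),
    labels = labels, pixel_size_nm = pixel_size_nm, channel = channel,
    params = NULL, fov_shape = dim(labels)
  ), class = "puncta_set")
}

#' Read a point set from CSV
#'
#' Accepts the `id, x_nm, y_nm` layout emitted by the simulator and pipeline.
#'
#' @param path CSV path.
#' @return An n x 2 matrix of (x, y) nm coordinates.
#' @export
read_point_csv <- function(path) {
  tab <- read.csv(path)
  if (!all(c("x_nm", "y_nm") %in% names(tab)))
    stop("point CSV must have x_nm and y_nm columns: ", path)
  cbind(x = tab$x_nm, y = tab$y_nm)
}
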