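#' Configuration for the synthetic synapse-field generator
#'
#' Defaults emulate punctate immunolabeling of glutamatergic synapses in
#' thalamus imaged at 27 nm pixels with ~120 nm lateral resolution: a
#' presynaptic marker channel, a postsynaptic marker channel whose paired
#' puncta sit at sub-resolution offsets from their presynaptic partners
#' (median 193 nm, IQR 31), a receptor channel attached to synapses with
#' input-specific probabilities, and sparse large VGLUT2 versus numerous
#' small VGLUT1 terminal masks.
#'
#' @param fov_shape integer vector (rows, cols) in pixels.
#' @param pixel_size nm per pixel.
#' @param density_pre,density_post,density_receptor puncta per um^2. The
#'   post density is the total (paired + unpaired) postsynaptic density.
#' @param paired_fraction_pre probability that a presynaptic punctum has a
#'   postsynaptic partner (calibrated so ~42% of presynaptic and ~33% of
#'   postsynaptic puncta are synaptic).
#' @param offset_median,offset_iqr median and IQR (nm) of the radial
#'   pre-to-post maxima offset, realized as a right-skewed gamma.
#' @param receptor_post_prob,receptor_pre_prob probability a synapse carries
#'   a postsynaptic / presynaptic receptor punctum.
#' @param receptor_offset_median,receptor_offset_iqr median and IQR (nm) of
#'   the radial offset between a receptor punctum and the marker it is
#'   attached to.
#' @param vglut1_fraction,vglut2_fraction fraction of synapses gated to each
#'   input type (their sum must be <= 1).
#' @param vglut1_terminal_radius,vglut2_terminal_radius disc radii (nm) of
#'   the terminal masks drawn around gated synapses.
#' @param psf_sigma Gaussian PSF sigma in nm (120 nm FWHM / 2.355 ~ 51 nm).
#' @param amplitude_mean,amplitude_cv mean and coefficient of variation of
#'   per-punctum peak amplitude (arbitrary intensity units).
#' @param background constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian read noise.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   config (seed included).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(fov_shape = c(512L, 512L),
                         pixel_size = 27,
                         density_pre = 0.5,
                         density_post = 0.64,
                         density_receptor = 0.6,
                         paired_fraction_pre = 0.42,
                         offset_median = 193,
                         offset_iqr = 31,
                         receptor_post_prob = 0.51,
                         receptor_pre_prob = 0.07,
                         receptor_offset_median = 120,
                         receptor_offset_iqr = 60,
                         vglut1_fraction = 0.49,
                         vglut2_fraction = 0.06,
                         vglut1_terminal_radius = 250,
                         vglut2_terminal_radius = 1000,
                         psf_sigma = 51,
                         amplitude_mean = 1500,
                         amplitude_cv = 0.2,
                         background = 20,
                         noise_sd = 10,
                         seed = 1L) {
  cfg <- list(
    fov_shape = as.integer(fov_shape), pixel_size = pixel_size,
    density_pre = density_pre, density_post = density_post,
    density_receptor = density_receptor,
    paired_fraction_pre = paired_fraction_pre,
    offset_median = offset_median, offset_iqr = offset_iqr,
    receptor_post_prob = receptor_post_prob,
    receptor_pre_prob = receptor_pre_prob,
    receptor_offset_median = receptor_offset_median,
    receptor_offset_iqr = receptor_offset_iqr,
    vglut1_fraction = vglut1_fraction, vglut2_fraction = vglut2_fraction,
    vglut1_terminal_radius = vglut1_terminal_radius,
    vglut2_terminal_radius = vglut2_terminal_radius,
    psf_sigma = psf_sigma, amplitude_mean = amplitude_mean,
    amplitude_cv = amplitude_cv, background = background,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  chk <- function(field, ok) {
    v <- cfg[[field]]
    if (is.null(v) || any(!is.finite(v)) || !ok(v))
      stop("invalid synth_config field: ", field, call. = FALSE)
  }
  chk("fov_shape", function(v) length(v) == 2 && all(v >= 8))
  chk("pixel_size", function(v) v > 0)
  for (f in c("density_pre", "density_post", "density_receptor"))
    chk(f, function(v) v > 0)
  for (f in c("paired_fraction_pre", "receptor_post_prob",
              "receptor_pre_prob", "vglut1_fraction", "vglut2_fraction"))
    chk(f, function(v) v >= 0 && v <= 1)
  if (cfg$vglut1_fraction + cfg$vglut2_fraction > 1)
    stop("invalid synth_config: vglut1_fraction + vglut2_fraction > 1",
         call. = FALSE)
  for (f in c("offset_median", "offset_iqr", "receptor_offset_median",
              "receptor_offset_iqr", "vglut1_terminal_radius",
              "vglut2_terminal_radius", "psf_sigma", "amplitude_mean"))
    chk(f, function(v) v > 0)
  chk("amplitude_cv", function(v) v >= 0)
  chk("background", function(v) v >= 0)
  chk("noise_sd", function(v) v >= 0)
  chk("seed", function(v) length(v) == 1)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (f in names(x))
    cat(sprintf("  %-24s %s\n", f, paste(format(x[[f]]), collapse = " x ")))
  invisible(x)
}

#' Gamma distribution matched to a (median, IQR) pair
#'
#' Solves for the gamma shape whose IQR-to-median ratio matches the target
#' (the scale cancels in that ratio), then sets the scale from the median.
#' Used for the right-skewed radial offset distributions, which are printed
#' only as median (IQR) summaries.
#'
#' @param median_nm,iqr_nm target median and interquartile range.
#' @return list with `shape` and `scale`.
#' @export
gamma_from_median_iqr <- function(median_nm, iqr_nm) {
  stopifnot(median_nm > 0, iqr_nm > 0)
  target <- iqr_nm / median_nm
  ratio <- function(logk) {
    k <- exp(logk)
    (qgamma(0.75, k) - qgamma(0.25, k)) / qgamma(0.5, k) - target
  }
  k <- exp(uniroot(ratio, c(log(1e-2), log(1e6)), tol = 1e-10)$root)
  list(shape = k, scale = median_nm / qgamma(0.5, k))
}
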