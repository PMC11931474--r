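# Shared fixtures built in code at test time.

# small fast field for structural tests
small_config <- function(seed = 1L, ...) {
  synth_config(fov_shape = c(128L, 128L), seed = seed, ...)
}

# sparse, low-variance field on which geometric overlap coincides with the
# truth tables (no incidental cross-channel adjacency at this density), used
# for exact truth-recovery checks
exact_config <- function(seed = 1L) {
  synth_config(density_pre = 0.05, density_post = 0.064,
               density_receptor = 0.06,
               receptor_pre_prob = 0,
               receptor_offset_median = 80, receptor_offset_iqr = 30,
               amplitude_cv = 0.05, seed = seed)
}

# expected metric values computed purely from the ground-truth tables
truth_metrics <- function(gt) {
  pr <- gt$pairing
  asn <- gt$receptor_assignment
  lab <- gt$input_labels$label
  n_pairs <- nrow(pr)
  area <- prod(gt$config$fov_shape) * (gt$config$pixel_size / 1000)^2
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  syn_post_rec <- unique(asn$synapse_id[asn$compartment == "post"])
  syn_pre_rec <- unique(asn$synapse_id[asn$compartment == "pre"])
  v1 <- pr$synapse_id[lab == "VGLUT1"]
  v2 <- pr$synapse_id[lab == "VGLUT2"]
  c(
    pct_pre_synaptic = pct(length(unique(pr$pre_id)), nrow(gt$points$pre)),
    pct_post_synaptic = pct(length(unique(pr$post_id)), nrow(gt$points$post)),
    pct_synapses_vglut1 = pct(length(v1), n_pairs),
    pct_synapses_vglut2 = pct(length(v2), n_pairs),
    pct_synaptic_post_multi_pre = if (n_pairs == 0) NA_real_ else 0,
    pre_puncta_per_25um2 = 25 * nrow(gt$points$pre) / area,
    post_puncta_per_25um2 = 25 * nrow(gt$points$post) / area,
    pct_receptor_postsynaptic = pct(sum(asn$compartment == "post"),
                                    nrow(gt$points$receptor)),
    pct_receptor_presynaptic = pct(sum(asn$compartment == "pre"),
                                   nrow(gt$points$receptor)),
    pct_synapses_receptor_post = pct(length(syn_post_rec), n_pairs),
    pct_synapses_receptor_pre = pct(length(syn_pre_rec), n_pairs),
    pct_vglut1_synapses_receptor_post = pct(sum(v1 %in% syn_post_rec),
                                            length(v1)),
    pct_vglut2_synapses_receptor_post = pct(sum(v2 %in% syn_post_rec),
                                            length(v2)),
    pct_vglut1_post_receptor = pct(sum(v1 %in% syn_post_rec), length(v1)),
    pct_vglut2_post_receptor = pct(sum(v2 %in% syn_post_rec), length(v2)),
    receptor_puncta_per_25um2 = 25 * nrow(gt$points$receptor) / area
  )
}

# Score detected receptor compartments against truth, restricted to
# receptors for which the truth label is recoverable at all:
#  - the parent synapse was itself recovered as an overlapping pair
#    (compartments are only defined relative to detected synapses),
#  - the receptor punctum was individually resolved (a maximum within 2 px),
#  - the truth-attached marker is strictly nearer (by > 1 px) than the
#    synapse's other marker, since the shortest-distance rule resolves a
#    receptor lying between the two maxima toward the nearer one regardless
#    of which marker it was attached to.
score_compartments <- function(gt, d, tab, asn) {
  truth <- gt$receptor_assignment
  att <- truth[truth$compartment %in% c("post", "pre") &
                 truth$offset_nm < 200, ]
  paired_post <- d$post$table[d$post$table$id %in% tab$pairs$post_id, ]
  ok <- 0L
  n <- 0L
  for (k in seq_len(nrow(att))) {
    syn <- gt$pairing[gt$pairing$synapse_id == att$synapse_id[k], ]
    tpost <- gt$points$post[gt$points$post$id == syn$post_id, ]
    tpre <- gt$points$pre[gt$points$pre$id == syn$pre_id, ]
    if (nrow(paired_post) == 0 ||
        min(sqrt((paired_post$x_nm - tpost$x_nm)^2 +
                   (paired_post$y_nm - tpost$y_nm)^2)) > 54) next
    p <- gt$points$receptor[gt$points$receptor$id == att$receptor_id[k], ]
    d_post <- sqrt((p$x_nm - tpost$x_nm)^2 + (p$y_nm - tpost$y_nm)^2)
    d_pre <- sqrt((p$x_nm - tpre$x_nm)^2 + (p$y_nm - tpre$y_nm)^2)
    d_own <- if (att$compartment[k] == "post") d_post else d_pre
    d_other <- if (att$compartment[k] == "post") d_pre else d_post
    if (d_other < d_own + 27) next # ambiguous under the distance rule
    dd <- sqrt((d$receptor$table$x_nm - p$x_nm)^2 +
                 (d$receptor$table$y_nm - p$y_nm)^2)
    if (min(dd) > 54) next
    det_id <- d$receptor$table$id[which.min(dd)]
    got <- asn$compartment[asn$receptor_id == det_id]
    want <- if (att$compartment[k] == "post") "postsynaptic" else "presynaptic"
    n <- n + 1L
    if (got == want) ok <- ok + 1L
  }
  c(ok = ok, n = n)
}

runif_fov_test <- function(n, fov) {
  cbind(runif(n, 0, fov$width), runif(n, 0, fov$height))
}

# a single rendered Gaussian spot on a small canvas
spot_image <- function(positions_nm, amplitudes = 1000, shape = c(64L, 64L),
                       psf_sigma = 51, background = 0, pixel_size = 27) {
  cfg <- synth_config(fov_shape = shape, pixel_size = pixel_size,
                      psf_sigma = psf_sigma, background = background,
                      amplitude_mean = 1000, amplitude_cv = 0,
                      noise_sd = 0, seed = 1L)
  pts <- data.frame(x_nm = positions_nm[, 1], y_nm = positions_nm[, 2],
                    amplitude = amplitudes)
  render_channel(pts, cfg, noise = FALSE)
}
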