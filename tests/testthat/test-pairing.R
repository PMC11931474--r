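# detect the three channels of a rendered field with the default settings
detect_field <- function(gt, noise = FALSE) {
  imgs <- render_ground_truth(gt, noise = noise)
  cfg <- default_pipeline_config()
  suppressMessages(list(
    imgs = imgs,
    pre = detect_puncta(imgs$pre, cfg$channels$pre),
    post = detect_puncta(imgs$post, cfg$channels$post),
    receptor = detect_puncta(imgs$receptor, cfg$channels$receptor)
  ))
}

test_that("disjoint masks give no pairs; identical channels pair at distance 0", {
  prm <- detection_params(min_intensity = 100, noise_tolerance = 20,
                          min_area = 0, max_area = 50)
  far <- spot_image(matrix(c(300, 300), 1))
  far2 <- spot_image(matrix(c(1300, 1300), 1))
  ps_a <- segment_puncta(far, find_maxima(far, prm), prm)
  ps_b <- segment_puncta(far2, find_maxima(far2, prm), prm)
  expect_identical(nrow(pair_synapses(ps_a, ps_b)$pairs), 0L)
  tab <- pair_synapses(ps_a, ps_a)
  expect_identical(nrow(tab$pairs), 1L)
  expect_identical(tab$pairs$distance_nm, 0)
})

test_that("pairing equals the brute-force all-pairs mask intersection", {
  gt <- generate_synapse_field(synth_config(density_pre = 0.15,
                                            density_post = 0.2,
                                            noise_sd = 0, seed = 9))
  d <- detect_field(gt)
  tab <- pair_synapses(d$pre, d$post)
  expected <- oracle_pairs(d$pre$labels, d$post$labels)
  got <- as.matrix(tab$pairs[order(tab$pairs$pre_id, tab$pairs$post_id),
                             c("pre_id", "post_id")])
  expect_equal(unname(got), unname(expected))
  # distances are maxima-to-maxima
  i <- match(tab$pairs$pre_id, d$pre$table$id)
  j <- match(tab$pairs$post_id, d$post$table$id)
  expect_equal(tab$pairs$distance_nm,
               sqrt((d$pre$table$x_nm[i] - d$post$table$x_nm[j])^2 +
                      (d$pre$table$y_nm[i] - d$post$table$y_nm[j])^2))
})

test_that("pairing is symmetric under swapping the channels", {
  gt <- generate_synapse_field(small_config(seed = 4))
  d <- detect_field(gt)
  ab <- pair_synapses(d$pre, d$post)$pairs
  ba <- pair_synapses(d$post, d$pre)$pairs
  key_ab <- paste(ab$pre_id, ab$post_id)
  key_ba <- paste(ba$post_id, ba$pre_id)
  expect_setequal(key_ab, key_ba)
  expect_equal(sort(ab$distance_nm), sort(ba$distance_nm))
})

test_that("mismatched pixel sizes are refused", {
  prm <- detection_params(min_intensity = 100, noise_tolerance = 20,
                          min_area = 0, max_area = 50)
  img <- spot_image(matrix(c(300, 300), 1))
  ps <- segment_puncta(img, find_maxima(img, prm), prm)
  ps2 <- ps
  ps2$pixel_size_nm <- 30
  expect_error(pair_synapses(ps, ps2), "pixel size")
})

test_that("VGLUT gating follows single-pixel suprathreshold overlap", {
  gt <- generate_synapse_field(small_config(seed = 6))
  d <- detect_field(gt)
  tab <- pair_synapses(d$pre, d$post)
  # an all-zero VGLUT image labels nothing
  zero <- channel_image(matrix(0, 128, 128), 27, "vglut1")
  expect_true(all(gate_synapses_by_vglut(tab, zero, 100,
                                         "VGLUT1")$pairs$input_label == "none"))
  # a full-field suprathreshold image labels every pair
  full <- channel_image(matrix(200, 128, 128), 27, "vglut1")
  expect_true(all(gate_synapses_by_vglut(tab, full, 100,
                                         "VGLUT1")$pairs$input_label == "VGLUT1"))
  if (nrow(tab$pairs) > 0) {
    # a single shared pixel at exactly the threshold labels the pair;
    # one intensity unit below does not (brute-force pixel check)
    pid <- tab$pairs$pre_id[1]
    px1 <- which(tab$pre_labels == pid)[1]
    v <- matrix(0, 128, 128)
    v[px1] <- 100
    lab_at <- gate_synapses_by_vglut(tab, channel_image(v, 27), 100, "VGLUT1")
    expect_identical(lab_at$pairs$input_label[1], "VGLUT1")
    v[px1] <- 99.9
    lab_below <- gate_synapses_by_vglut(tab, channel_image(v, 27), 100,
                                        "VGLUT1")
    expect_identical(lab_below$pairs$input_label[1], "none")
  }
})

test_that("raising the VGLUT threshold never labels more synapses", {
  gt <- generate_synapse_field(synth_config(seed = 8))
  d <- detect_field(gt)
  tab <- pair_synapses(d$pre, d$post)
  n_labeled <- vapply(c(100, 300, 700, 1200, 1600), function(thr) {
    sum(gate_synapses_by_vglut(tab, d$imgs$vglut1, thr,
                               "VGLUT1")$pairs$input_label == "VGLUT1")
  }, numeric(1))
  expect_true(all(diff(n_labeled) <= 0))
})

test_that("receptor compartments follow overlap and the shortest-distance tie-break", {
  prm <- detection_params(min_intensity = 100, noise_tolerance = 20,
                          min_area = 0, max_area = 50)
  seg <- function(img) segment_puncta(img, find_maxima(img, prm), prm)
  # pre at x=700, post at x=880: overlapping pair
  pre <- seg(spot_image(matrix(c(700, 864), 1)))
  post <- seg(spot_image(matrix(c(880, 864), 1)))
  tab <- pair_synapses(pre, post)
  expect_identical(nrow(tab$pairs), 1L)
  # receptor overlapping only the post punctum
  rec_post <- seg(spot_image(matrix(c(980, 864), 1)))
  a1 <- assign_receptor_puncta(rec_post, tab, pre, post)
  expect_identical(a1$compartment, "postsynaptic")
  expect_equal(a1$distance_to_marker, 100, tolerance = 30)
  # receptor overlapping only the pre punctum
  rec_pre <- seg(spot_image(matrix(c(600, 864), 1)))
  expect_identical(assign_receptor_puncta(rec_pre, tab, pre,
                                          post)$compartment, "presynaptic")
  # receptor overlapping both: 100 nm from post maximum, 280 from pre
  rec_mid <- seg(spot_image(matrix(c(980, 864), 1)))
  tab_wide <- pair_synapses(seg(spot_image(matrix(c(864, 864), 1),
                                           amplitudes = 2500)), post)
  a3 <- assign_receptor_puncta(rec_mid, tab_wide,
                               seg(spot_image(matrix(c(864, 864), 1),
                                              amplitudes = 2500)), post)
  expect_identical(a3$compartment, "postsynaptic")
  # receptor overlapping nothing
  rec_far <- seg(spot_image(matrix(c(300, 300), 1)))
  expect_identical(assign_receptor_puncta(rec_far, tab, pre,
                                          post)$compartment, "unassigned")
})

test_that("every receptor punctum lands in exactly one compartment", {
  gt <- generate_synapse_field(synth_config(seed = 12))
  d <- detect_field(gt)
  tab <- pair_synapses(d$pre, d$post)
  asn <- assign_receptor_puncta(d$receptor, tab, d$pre, d$post)
  expect_identical(nrow(asn), nrow(d$receptor$table))
  expect_true(all(asn$compartment %in%
                    c("postsynaptic", "presynaptic", "unassigned")))
  expect_false(any(duplicated(asn$receptor_id)))
})

test_that("postsynaptic receptor distances respect the overlap geometry bound", {
  gt <- generate_synapse_field(synth_config(seed = 13))
  d <- detect_field(gt)
  tab <- pair_synapses(d$pre, d$post)
  asn <- assign_receptor_puncta(d$receptor, tab, d$pre, d$post)
  dd <- asn$distance_to_marker[asn$compartment == "postsynaptic"]
  expect_gt(length(dd), 5)
  expect_true(all(dd <= 400))
})

test_that("receptor compartment recovery matches truth on noiseless fields", {
  # A receptor attached to the presynaptic marker but lying between the two
  # maxima is intrinsically ambiguous under the shortest-distance rule (it
  # resolves postsynaptic); the >= 99% recovery check therefore uses fields
  # without presynaptic receptors, and the default field is held to the
  # looser bound the ambiguity allows.
  correct <- 0L
  total <- 0L
  for (s in 1:4) {
    gt <- generate_synapse_field(synth_config(seed = s, noise_sd = 0,
                                              receptor_pre_prob = 0))
    d <- detect_field(gt)
    tab <- pair_synapses(d$pre, d$post)
    asn <- assign_receptor_puncta(d$receptor, tab, d$pre, d$post)
    sc <- score_compartments(gt, d, tab, asn)
    correct <- correct + sc["ok"]
    total <- total + sc["n"]
  }
  expect_gt(total, 40)
  expect_gte(correct / total, 0.99)
})

test_that("default fields with presynaptic receptors recover unambiguous labels", {
  ok <- 0L
  n <- 0L
  for (s in 31:33) {
    gt <- generate_synapse_field(synth_config(seed = s, noise_sd = 0))
    d <- detect_field(gt)
    tab <- pair_synapses(d$pre, d$post)
    asn <- assign_receptor_puncta(d$receptor, tab, d$pre, d$post)
    sc <- score_compartments(gt, d, tab, asn)
    ok <- ok + sc["ok"]
    n <- n + sc["n"]
  }
  expect_gt(n, 40)
  expect_gte(ok / n, 0.95)
})

test_that("distance histograms normalize and summarize raw values", {
  h <- distance_histogram(c(100, 100, 100), 20)
  expect_identical(sum(h$freq > 0), 1L)
  expect_identical(h$median, 100)
  expect_identical(h$iqr, 0)
  expect_equal(sum(h$freq), 1)
  set.seed(1)
  v <- rgamma(500, 30, scale = 6)
  h2 <- distance_histogram(v, 25)
  expect_equal(sum(h2$freq), 1)
  expect_identical(h2$median, unname(quantile(v, 0.5)))
  expect_error(distance_histogram(numeric(0), 20), "empty")
})

test_that("recovered pair distances match the configured offset calibration", {
  dists <- unlist(lapply(1:3, function(s) {
    gt <- generate_synapse_field(synth_config(seed = s, noise_sd = 0))
    d <- detect_field(gt)
    pair_synapses(d$pre, d$post)$pairs$distance_nm
  }))
  h <- distance_histogram(dists, 20)
  se_med <- 1.2533 * (31 / 1.349) / sqrt(length(dists))
  expect_lt(abs(h$median - 193), 3 * se_med + 8) # + pixel quantization slack
})

test_that("three-channel and four-channel input-specific estimates agree", {
  d4 <- d3 <- numeric(6)
  for (s in 1:6) {
    gt <- generate_synapse_field(synth_config(seed = 20 + s, noise_sd = 0))
    d <- detect_field(gt)
    tab <- pair_synapses(d$pre, d$post)
    tab <- gate_synapses_by_vglut(tab, d$imgs$vglut1, 500, "VGLUT1")
    m4 <- summarize_synapse_metrics(tab, d$pre, d$post, d$receptor)
    d4[s] <- m4$value[m4$metric == "pct_vglut1_post_receptor"]
    m3 <- homer_only_vglut_analysis(d$post, d$imgs$vglut1, d$receptor, 500)
    d3[s] <- m3$value[m3$metric == "pct_vglut_post_receptor"]
  }
  se <- sd(d4 - d3) / sqrt(length(d4))
  expect_lt(abs(mean(d4) - mean(d3)), 3 * se + 5)
})

test_that("homer-only analysis handles blank and saturated designs", {
  gt <- generate_synapse_field(small_config(seed = 2))
  d <- detect_field(gt)
  blank <- channel_image(matrix(0, 128, 128), 27)
  m <- homer_only_vglut_analysis(d$post, blank, d$receptor, 100)
  expect_true(is.na(m$value[m$metric == "pct_vglut_post_receptor"]))
  # every synapse VGLUT2-gated and receptor-positive -> 100%
  cfg <- synth_config(vglut1_fraction = 0, vglut2_fraction = 1,
                      receptor_post_prob = 1, receptor_pre_prob = 0,
                      receptor_offset_median = 60, receptor_offset_iqr = 20,
                      density_pre = 0.1, density_post = 0.05,
                      paired_fraction_pre = 1, noise_sd = 0, seed = 5)
  gt2 <- generate_synapse_field(cfg)
  d2 <- detect_field(gt2)
  m2 <- homer_only_vglut_analysis(d2$post, d2$imgs$vglut2, d2$receptor, 500)
  expect_equal(m2$value[m2$metric == "pct_vglut_post_receptor"], 100)
})
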