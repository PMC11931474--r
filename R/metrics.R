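metric_row <- function(metric, num, den, scale = 100) {
  data.frame(metric = metric,
             value = if (is.na(den) || den == 0) NA_real_ else scale * num / den,
             numerator = num, denominator = den)
}

#' Summarize colocalization metrics for one FOV
#'
#' Computes the per-FOV percentages and densities reported by the pipeline:
#' fraction of pre/post puncta that are synaptic, input-type composition of
#' synapses, receptor compartment fractions (per unique receptor punctum),
#' fraction of synapses carrying a postsynaptic / presynaptic receptor
#' (overall and per input label; a synapse counts as presynaptic-receptor
#' positive when a receptor overlaps its presynaptic but not its
#' postsynaptic punctum), fraction of VGLUT-positive postsynaptic puncta
#' overlapping receptor, puncta densities per 25 um^2, and the fraction of
#' synaptic post puncta overlapping more than one pre punctum. Every metric
#' carries its numerator and denominator; zero-denominator metrics are
#' reported as `NA`, never as 0.
#'
#' @param table a `synapse_table` (optionally VGLUT-gated).
#' @param pre,post the `puncta_set`s the table was built from.
#' @param receptors receptor `puncta_set`, or `NULL` if no receptor channel.
#' @return Data frame with columns `metric`, `value` (percent or count per
#'   25 um^2), `numerator`, `denominator`.
#' @export
summarize_synapse_metrics <- function(table, pre, post, receptors = NULL) {
  stopifnot(inherits(table, "synapse_table"))
  pairs <- table$pairs
  n_pairs <- nrow(pairs)
  area_um2 <- prod(table$fov_shape) * (table$pixel_size_nm / 1000)^2
  lab1 <- pairs$input_label == "VGLUT1"
  lab2 <- pairs$input_label == "VGLUT2"

  out <- rbind(
    metric_row("pct_pre_synaptic", length(unique(pairs$pre_id)), table$n_pre),
    metric_row("pct_post_synaptic", length(unique(pairs$post_id)), table$n_post),
    metric_row("pct_synapses_vglut1", sum(lab1), n_pairs),
    metric_row("pct_synapses_vglut2", sum(lab2), n_pairs),
    metric_row("pct_synaptic_post_multi_pre",
               length(unique(pairs$post_id[pairs$post_multi])),
               length(unique(pairs$post_id))),
    metric_row("pre_puncta_per_25um2", table$n_pre, area_um2, scale = 25),
    metric_row("post_puncta_per_25um2", table$n_post, area_um2, scale = 25)
  )
  if (!is.null(receptors)) {
    stopifnot(inherits(receptors, "puncta_set"))
    n_rec <- nrow(receptors$table)
    asn <- assign_receptor_puncta(receptors, table, pre, post)
    ov_post <- overlap_pairs(receptors$labels, post$labels)
    ov_pre <- overlap_pairs(receptors$labels, pre$labels)
    post_hit <- unique(ov_post$b) # post puncta overlapping any receptor
    # synapse-level receptor positivity
    syn_post_pos <- pairs$post_id %in% post_hit
    pre_rec <- split(ov_pre$a, ov_pre$b) # receptors per pre punctum
    post_rec <- split(ov_post$a, ov_post$b)
    syn_pre_pos <- vapply(seq_len(n_pairs), function(i) {
      rs <- pre_rec[[as.character(pairs$pre_id[i])]]
      if (is.null(rs)) return(FALSE)
      any(!(rs %in% post_rec[[as.character(pairs$post_id[i])]]))
    }, logical(1))
    out <- rbind(
      out,
      metric_row("pct_receptor_postsynaptic",
                 sum(asn$compartment == "postsynaptic"), n_rec),
      metric_row("pct_receptor_presynaptic",
                 sum(asn$compartment == "presynaptic"), n_rec),
      metric_row("pct_synapses_receptor_post", sum(syn_post_pos), n_pairs),
      metric_row("pct_synapses_receptor_pre", sum(syn_pre_pos), n_pairs),
      metric_row("pct_vglut1_synapses_receptor_post",
                 sum(syn_post_pos & lab1), sum(lab1)),
      metric_row("pct_vglut2_synapses_receptor_post",
                 sum(syn_post_pos & lab2), sum(lab2)),
      metric_row("pct_vglut1_post_receptor",
                 length(unique(pairs$post_id[lab1][
                   pairs$post_id[lab1] %in% post_hit])),
                 length(unique(pairs$post_id[lab1]))),
      metric_row("pct_vglut2_post_receptor",
                 length(unique(pairs$post_id[lab2][
                   pairs$post_id[lab2] %in% post_hit])),
                 length(unique(pairs$post_id[lab2]))),
      metric_row("receptor_puncta_per_25um2", n_rec, area_um2, scale = 25)
    )
  }
  rownames(out) <- NULL
  out
}

#' Three-channel input-specific receptor analysis (no presynaptic marker)
#'
#' The reduced design used when four-channel labeling is not available:
#' postsynaptic puncta overlapping the suprathreshold VGLUT region are
#' labeled as input-positive, and the fraction of labeled postsynaptic
#' puncta overlapping a receptor punctum is reported. Designed to agree with
#' the four-channel pipeline on the same field.
#'
#' @param post postsynaptic `puncta_set`.
#' @param vglut VGLUT [channel_image].
#' @param receptors receptor `puncta_set`.
#' @param vglut_threshold intensity threshold (> 0).
#' @return Data frame in the [summarize_synapse_metrics()] format with
#'   metrics `pct_post_vglut` (labeled fraction of all post puncta) and
#'   `pct_vglut_post_receptor` (receptor-positive fraction of labeled post
#'   puncta; `NA` when no post punctum is labeled).
#' @export
homer_only_vglut_analysis <- function(post, vglut, receptors,
                                      vglut_threshold) {
  stopifnot(inherits(post, "puncta_set"), inherits(vglut, "channel_image"),
            inherits(receptors, "puncta_set"), vglut_threshold > 0)
  supra <- vglut$pixels >= vglut_threshold
  labeled <- unique(post$labels[post$labels > 0L & supra])
  ov <- overlap_pairs(receptors$labels, post$labels)
  hit <- sum(labeled %in% ov$b)
  rbind(
    metric_row("pct_post_vglut", length(labeled), nrow(post$table)),
    metric_row("pct_vglut_post_receptor", hit, length(labeled))
  )
}
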