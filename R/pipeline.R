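#' Default analysis configuration for one imaging batch
#'
#' Per-channel detection parameters (synaptic-marker size window 0.02-5
#' um^2 for pre/post, receptor window 0.05-5 um^2), empirical VGLUT
#' thresholds, and interaction-analysis settings. All thresholds are held
#' constant across the images of a batch.
#'
#' @param marker_min_intensity,receptor_min_intensity segmentation support
#'   thresholds for the synaptic-marker and receptor channels (the receptor
#'   threshold is lower so that receptor masks clear the stricter 0.05 um^2
#'   size floor).
#' @param noise_tolerance minimum maxima prominence, all channels.
#' @param vglut1_threshold,vglut2_threshold VGLUT gating thresholds.
#' @param interaction_runs,interaction_alpha Monte Carlo settings.
#' @param seed analysis seed (context sampling and randomization test).
#' @return A nested list consumed by [run_fov_analysis()].
#' @export
default_pipeline_config <- function(marker_min_intensity = 75,
                                    receptor_min_intensity = 40,
                                    noise_tolerance = 50,
                                    vglut1_threshold = 500,
                                    vglut2_threshold = 500,
                                    interaction_runs = 1000,
                                    interaction_alpha = 0.05,
                                    seed = 1L) {
  marker <- detection_params(min_intensity = marker_min_intensity,
                             noise_tolerance = noise_tolerance,
                             median_radius = 2L,
                             min_area = 0.02, max_area = 5)
  receptor <- detection_params(min_intensity = receptor_min_intensity,
                               noise_tolerance = noise_tolerance,
                               median_radius = 2L,
                               min_area = 0.05, max_area = 5)
  list(
    channels = list(pre = marker, post = marker, receptor = receptor),
    vglut = list(vglut1 = vglut1_threshold, vglut2 = vglut2_threshold),
    interaction = list(enabled = TRUE, mc_test = TRUE,
                       n_runs = interaction_runs,
                       alpha = interaction_alpha,
                       pairs = list(c(ref = "pre", target = "post"))),
    histogram_bin_nm = 20,
    seed = as.integer(seed)
  )
}

#' Run the full single-FOV analysis
#'
#' Detect -> size-filter -> pair -> VGLUT-gate -> receptor-assign ->
#' summarize -> interaction, per the configuration. Channels `pre` and
#' `post` are required; `receptor`, `vglut1` and `vglut2` are optional.
#' Deterministic given images + config (the config seed drives context
#' sampling and the randomization test).
#'
#' @param images named list of [channel_image]s with consistent pixel size.
#' @param config a [default_pipeline_config()]-style list.
#' @param fov_id,mouse_id identifiers carried into the result.
#' @param rotated_control mark the interaction fits as coming from a
#'   rotated-signal control.
#' @return An `fov_result`: `metrics` (data frame), `pairs`
#'   (`synapse_table`), `assignments`, `puncta` (per-channel sets),
#'   `interaction` (list of `interaction_fit`), `distance_histogram`,
#'   ids and the resolved config.
#' @export
run_fov_analysis <- function(images, config = default_pipeline_config(),
                             fov_id = "fov1", mouse_id = "mouse1",
                             rotated_control = FALSE) {
  for (ch in c("pre", "post"))
    if (is.null(images[[ch]]))
      stop("missing required channel: ", ch)
  px <- unique(vapply(images, function(im) im$pixel_size_nm, numeric(1)))
  if (length(px) != 1)
    stop("channels have inconsistent pixel sizes")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  puncta <- list()
  for (ch in intersect(names(config$channels), names(images)))
    puncta[[ch]] <- stage(paste0("detect:", ch),
                          detect_puncta(images[[ch]], config$channels[[ch]]))
  tab <- stage("pair", pair_synapses(puncta$pre, puncta$post))
  for (v in c("vglut1", "vglut2"))
    if (!is.null(images[[v]]))
      tab <- stage(paste0("gate:", v),
                   gate_synapses_by_vglut(tab, images[[v]], config$vglut[[v]],
                                          toupper(v)))
  assignments <- NULL
  if (!is.null(puncta$receptor))
    assignments <- stage("assign",
                         assign_receptor_puncta(puncta$receptor, tab,
                                                puncta$pre, puncta$post))
  metrics <- stage("summarize",
                   summarize_synapse_metrics(tab, puncta$pre, puncta$post,
                                             puncta$receptor))
  dist_hist <- if (nrow(tab$pairs) > 0)
    distance_histogram(tab$pairs$distance_nm, config$histogram_bin_nm)
  else NULL
  interaction <- list()
  if (isTRUE(config$interaction$enabled)) {
    for (pair in config$interaction$pairs) {
      ref <- pair[["ref"]]
      tgt <- pair[["target"]]
      if (is.null(puncta[[ref]]) || is.null(puncta[[tgt]])) next
      if (nrow(puncta[[ref]]$table) < 10 || nrow(puncta[[tgt]]$table) < 10) {
        message("skipping interaction fit ", ref, "~", tgt,
                ": fewer than 10 puncta in a channel")
        next
      }
      key <- paste0(ref, "~", tgt)
      interaction[[key]] <- stage(
        paste0("interact:", key),
        interaction_strength_for_channels(
          puncta[[ref]], puncta[[tgt]],
          mc_test = !isFALSE(config$interaction$mc_test),
          n_runs = config$interaction$n_runs,
          alpha = config$interaction$alpha,
          seed = config$seed))
      interaction[[key]]$rotated_control <- rotated_control
    }
  }
  structure(list(
    fov_id = fov_id, mouse_id = mouse_id,
    metrics = metrics, pairs = tab, assignments = assignments,
    puncta = puncta, interaction = interaction,
    distance_histogram = dist_hist,
    rotated_control = rotated_control, config = config
  ), class = "fov_result")
}

#' @export
print.fov_result <- function(x, ...) {
  cat(sprintf("<fov_result> %s (%s): %d synapses\n", x$fov_id, x$mouse_id,
              nrow(x$pairs$pairs)))
  invisible(x)
}

#' Average per-FOV metrics within each mouse
#'
#' The mouse, not the FOV, is the unit of analysis: each metric is the
#' unweighted mean over that mouse's FOVs (typically three), and the FOV
#' count is recorded even when it differs from three. `NA` metric values
#' (undefined denominators) are dropped from the mean.
#'
#' @param results list of `fov_result`s (each carrying a `mouse_id`).
#' @return Data frame with columns `mouse_id`, `metric`, `value`,
#'   `n_fov`.
#' @export
aggregate_by_mouse <- function(results) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(mouse_id = r$mouse_id, fov_id = r$fov_id,
               metric = r$metrics$metric, value = r$metrics$value)
  }))
  agg <- aggregate(value ~ mouse_id + metric, data = rows, FUN = mean,
                   na.rm = TRUE, na.action = stats::na.pass)
  counts <- aggregate(fov_id ~ mouse_id, data = unique(rows[c("mouse_id", "fov_id")]),
                      FUN = length)
  names(counts)[2] <- "n_fov"
  out <- merge(agg, counts, by = "mouse_id", sort = TRUE)
  out[order(out$mouse_id, out$metric), c("mouse_id", "metric", "value", "n_fov")]
}

#' Welch two-sample comparison of per-mouse values
#'
#' Welch's unequal-variance t-test with the Welch-Satterthwaite degrees of
#' freedom and the 95% CI of the mean difference. Groups with zero variance
#' and equal means are reported as degenerate (t = 0, df undefined) rather
#' than an error.
#'
#' @param a,b numeric vectors of per-mouse values (n >= 2 each).
#' @param labels length-2 character vector of group labels.
#' @param conf confidence level for the mean-difference CI.
#' @return A `group_comparison` list: per-group `mean`, `sd`, `n`, plus
#'   `t`, `df`, `p_value`, `mean_diff`, `conf_int`, `degenerate`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b"), conf = 0.95) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    return(structure(list(
      labels = labels, mean = c(mean(a), mean(b)), sd = c(0, 0),
      n = c(length(a), length(b)),
      t = 0, df = NA_real_, p_value = NA_real_,
      mean_diff = mean(a) - mean(b), conf_int = c(NA_real_, NA_real_),
      degenerate = TRUE), class = "group_comparison"))
  }
  tt <- t.test(a, b, var.equal = FALSE, conf.level = conf)
  structure(list(
    labels = labels, mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
    n = c(length(a), length(b)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_diff = mean(a) - mean(b), conf_int = unname(tt$conf.int),
    degenerate = FALSE), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  means %.4g vs %.4g; Welch t = %.4g, df = %.4g, p = %.4g\n",
              x$mean[1], x$mean[2], x$t, x$df, x$p_value))
  cat(sprintf("  mean difference %.4g, 95%% CI [%.4g, %.4g]\n",
              x$mean_diff, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Write per-FOV result tables to disk
#'
#' Emits `metrics.csv`, `pairs.csv`, `assignments.csv` (when present), the
#' interaction fits as JSON, and the resolved configuration as YAML.
#'
#' @param result an `fov_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fov_result <- function(result, dir) {
  stopifnot(inherits(result, "fov_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(result$pairs$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  if (!is.null(result$assignments))
    write.csv(result$assignments, file.path(dir, "assignments.csv"),
              row.names = FALSE)
  fits <- lapply(result$interaction, function(f)
    list(epsilon = f$epsilon, sigma = f$sigma, residual = f$residual,
         p_value = f$p_value, n_runs = f$n_mc_runs, alpha = f$alpha,
         reject = f$reject, rotated_control = isTRUE(f$rotated_control)))
  jsonlite::write_json(fits, file.path(dir, "interaction.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- result$config
  cfg$channels <- lapply(cfg$channels, unclass)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
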