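# unique (a, b) label pairs co-occurring at the same pixel, with pixel counts
overlap_pairs <- function(lab_a, lab_b) {
  idx <- which(lab_a > 0L & lab_b > 0L)
  if (length(idx) == 0)
    return(data.frame(a = integer(0), b = integer(0), n_px = integer(0)))
  a <- lab_a[idx]
  b <- lab_b[idx]
  key <- paste(a, b)
  tt <- table(key)
  first <- !duplicated(key)
  ord <- order(a[first], b[first])
  data.frame(a = a[first][ord], b = b[first][ord],
             n_px = as.integer(tt[key[first][ord]]))
}

#' Pair overlapping pre- and postsynaptic puncta into synapses
#'
#' A synapse is every (pre, post) punctum pair whose masks share at least one
#' pixel; no dilation is applied beyond the upstream median filter. The pair
#' distance is the Euclidean distance between the two intensity maxima, and
#' multiplicity flags record post puncta overlapping more than one pre
#' punctum (and vice versa).
#'
#' @param pre,post `puncta_set`s from the same FOV (pixel size and shape
#'   must match).
#' @return A `synapse_table`: `$pairs` (one row per pair: `synapse_id`,
#'   `pre_id`, `post_id`, `distance_nm`, `n_overlap_px`, `input_label`,
#'   `vglut_overlap_px`, `pre_multi`, `post_multi`), channel totals, and the
#'   pre/post label images needed by downstream gating and assignment.
#' @export
pair_synapses <- function(pre, post) {
  stopifnot(inherits(pre, "puncta_set"), inherits(post, "puncta_set"))
  if (pre$pixel_size_nm != post$pixel_size_nm)
    stop("pre and post puncta sets have different pixel sizes")
  if (!identical(pre$fov_shape, post$fov_shape))
    stop("pre and post puncta sets have different FOV shapes")
  ov <- overlap_pairs(pre$labels, post$labels)
  pre_i <- match(ov$a, pre$table$id)
  post_i <- match(ov$b, post$table$id)
  d <- sqrt((pre$table$x_nm[pre_i] - post$table$x_nm[post_i])^2 +
              (pre$table$y_nm[pre_i] - post$table$y_nm[post_i])^2)
  pairs <- data.frame(
    synapse_id = seq_len(nrow(ov)),
    pre_id = ov$a, post_id = ov$b,
    distance_nm = if (nrow(ov)) d else numeric(0),
    n_overlap_px = ov$n_px,
    input_label = rep("none", nrow(ov)),
    vglut_overlap_px = rep(0L, nrow(ov))
  )
  pairs$pre_multi <- pairs$pre_id %in% pairs$pre_id[duplicated(pairs$pre_id)]
  pairs$post_multi <- pairs$post_id %in% pairs$post_id[duplicated(pairs$post_id)]
  structure(list(
    pairs = pairs,
    n_pre = nrow(pre$table), n_post = nrow(post$table),
    pre_labels = pre$labels, post_labels = post$labels,
    pixel_size_nm = pre$pixel_size_nm, fov_shape = pre$fov_shape
  ), class = "synapse_table")
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> %d pairs from %d pre / %d post puncta (%s)\n",
              nrow(x$pairs), x$n_pre, x$n_post,
              paste(names(table(x$pairs$input_label)),
                    table(x$pairs$input_label), collapse = ", ")))
  invisible(x)
}

#' Gate synapses by VGLUT input type
#'
#' Pairs whose presynaptic mask shares at least one pixel with the
#' suprathreshold VGLUT region receive the given input label. A pair already
#' carrying a different label (dual-VGLUT conflict, an artifact since the
#' two transporters label non-overlapping terminal populations) keeps the
#' label with the larger pixel overlap; conflicts are reported with a
#' message.
#'
#' @param table a `synapse_table`.
#' @param vglut the VGLUT [channel_image] (same FOV).
#' @param vglut_threshold intensity threshold (> 0), set empirically per
#'   staining batch.
#' @param label input label to apply (e.g. `"VGLUT1"`).
#' @return The updated `synapse_table`.
#' @export
gate_synapses_by_vglut <- function(table, vglut, vglut_threshold, label) {
  stopifnot(inherits(table, "synapse_table"), inherits(vglut, "channel_image"),
            vglut_threshold > 0)
  if (!identical(dim(vglut$pixels), as.integer(table$fov_shape)))
    stop("VGLUT image shape does not match the synapse table FOV")
  supra <- vglut$pixels >= vglut_threshold
  ids <- table$pre_labels[table$pre_labels > 0L & supra]
  if (length(ids) == 0) return(table)
  cnt <- tabulate(ids, nbins = max(table$pairs$pre_id, ids))
  hit <- which(table$pairs$pre_id <= length(cnt) &
                 cnt[table$pairs$pre_id] > 0)
  conflicts <- 0L
  for (i in hit) {
    n_ov <- cnt[table$pairs$pre_id[i]]
    cur <- table$pairs$input_label[i]
    if (cur != "none" && cur != label) {
      conflicts <- conflicts + 1L
      if (n_ov <= table$pairs$vglut_overlap_px[i]) next
    }
    table$pairs$input_label[i] <- label
    table$pairs$vglut_overlap_px[i] <- n_ov
  }
  if (conflicts > 0)
    message(conflicts, " dual-VGLUT conflicts resolved by larger overlap")
  table
}

#' Classify receptor puncta as post- or presynaptic
#'
#' A receptor punctum overlapping only the postsynaptic punctum of a synapse
#' is postsynaptic; one overlapping only the presynaptic punctum of a
#' synapse is presynaptic; one overlapping both is assigned to the
#' compartment whose punctum maximum is nearer to the receptor maximum (on
#' tissue this resolves postsynaptic in the large majority of cases); one
#' overlapping neither is unassigned. When several puncta of the chosen
#' compartment overlap the receptor, the nearest maximum wins.
#'
#' @param receptors receptor `puncta_set`.
#' @param table a `synapse_table` (defines which pre/post puncta are
#'   synaptic).
#' @param pre,post the `puncta_set`s the table was built from.
#' @return Data frame with one row per receptor punctum: `receptor_id`,
#'   `compartment` (postsynaptic / presynaptic / unassigned), `synapse_ref`
#'   (a `synapse_id`, NA if unassigned) and `distance_to_marker` (nm).
#' @export
assign_receptor_puncta <- function(receptors, table, pre, post) {
  stopifnot(inherits(receptors, "puncta_set"), inherits(table, "synapse_table"))
  pairs <- table$pairs
  syn_pre <- unique(pairs$pre_id)
  syn_post <- unique(pairs$post_id)
  ov_post <- overlap_pairs(receptors$labels, post$labels)
  ov_post <- ov_post[ov_post$b %in% syn_post, , drop = FALSE]
  ov_pre <- overlap_pairs(receptors$labels, pre$labels)
  ov_pre <- ov_pre[ov_pre$b %in% syn_pre, , drop = FALSE]

  rt <- receptors$table
  nearest <- function(rid, ov, marker_tab) {
    cand <- ov$b[ov$a == rid]
    if (length(cand) == 0) return(NULL)
    mi <- match(cand, marker_tab$id)
    ri <- match(rid, rt$id)
    d <- sqrt((rt$x_nm[ri] - marker_tab$x_nm[mi])^2 +
                (rt$y_nm[ri] - marker_tab$y_nm[mi])^2)
    j <- which.min(d)
    list(id = cand[j], dist = d[j])
  }
  out <- data.frame(receptor_id = rt$id,
                    compartment = rep("unassigned", nrow(rt)),
                    synapse_ref = rep(NA_integer_, nrow(rt)),
                    distance_to_marker = rep(NA_real_, nrow(rt)))
  for (k in seq_len(nrow(rt))) {
    rid <- rt$id[k]
    np <- nearest(rid, ov_post, post$table)
    nb <- nearest(rid, ov_pre, pre$table)
    if (is.null(np) && is.null(nb)) next
    use_post <- !is.null(np) && (is.null(nb) || np$dist <= nb$dist)
    if (use_post) {
      cand <- pairs$synapse_id[pairs$post_id == np$id]
      out$compartment[k] <- "postsynaptic"
      out$synapse_ref[k] <- min(cand)
      out$distance_to_marker[k] <- np$dist
    } else {
      cand <- pairs$synapse_id[pairs$pre_id == nb$id]
      out$compartment[k] <- "presynaptic"
      out$synapse_ref[k] <- min(cand)
      out$distance_to_marker[k] <- nb$dist
    }
  }
  out
}

#' Normalized distance histogram with median and IQR
#'
#' Bins cover `[0, max(values)]` in steps of `bin_width`; frequencies sum to
#' one. The median and IQR are computed from the raw values, not the bins.
#'
#' @param values distances in nm (non-empty).
#' @param bin_width bin width in nm (> 0).
#' @return list with `breaks`, `mids`, `freq`, `median`, `iqr`, `n`.
#' @export
distance_histogram <- function(values, bin_width) {
  if (length(values) == 0) stop("distance_histogram: empty input")
  stopifnot(bin_width > 0, all(values >= 0))
  top <- max(values, bin_width)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
       freq = counts / length(values),
       median = q[2], iqr = q[3] - q[1], n = length(values))
}
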