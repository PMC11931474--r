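# Independent brute-force oracles. These deliberately re-derive results from
# first principles (double loops, flood fills, closed forms) and must stay
# independent of the package internals they check.

# disc median filter with reflect padding, explicit double loop
oracle_median_filter <- function(img, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  reflect <- function(i, n) {
    period <- 2 * n - 2
    i <- ((i - 1) %% period + period) %% period
    ifelse(i < n, i + 1, period - i + 1)
  }
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- img
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rr <- reflect(r + offs$dr, nr)
      cc <- reflect(c + offs$dc, nc)
      out[r, c] <- median(img[cbind(rr, cc)])
    }
  }
  out
}

# vectorized 8-connected flood fill; returns logical membership matrix
oracle_flood <- function(mask, start_r, start_c) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  visited <- matrix(FALSE, nr, nc)
  if (!mask[start_r, start_c]) return(visited)
  visited[start_r, start_c] <- TRUE
  frontier <- (start_c - 1L) * nr + start_r
  while (length(frontier) > 0) {
    cand <- unlist(lapply(c(-1L, 0L, 1L), function(dc) {
      lapply(c(-1L, 0L, 1L), function(dr) {
        if (dr == 0L && dc == 0L) return(integer(0))
        rr <- (frontier - 1L) %% nr + 1L + dr
        cc <- (frontier - 1L) %/% nr + 1L + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        (cc[ok] - 1L) * nr + rr[ok]
      })
    }))
    cand <- unique(cand)
    cand <- cand[mask[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# 8-connected component count of a mask, BFS from scratch
oracle_component_count <- function(mask) {
  remaining <- mask
  count <- 0L
  while (any(remaining)) {
    idx <- which(remaining)[1]
    r <- (idx - 1L) %% nrow(mask) + 1L
    c <- (idx - 1L) %/% nrow(mask) + 1L
    comp <- oracle_flood(remaining, r, c)
    remaining[comp] <- FALSE
    count <- count + 1L
  }
  count
}

# strict local maxima (8-neighborhood) of an image without ties
oracle_local_maxima <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      nb <- img[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      if (sum(nb >= img[r, c]) == 1)
        out <- rbind(out, c(r, c))
    }
  }
  out
}

# topographic prominence of the maximum at (r, c): h minus the highest pixel
# level L whose >= L component containing (r, c) holds a strictly higher
# pixel; the predicate is monotone in L, so binary search over levels
oracle_prominence <- function(img, r, c) {
  h <- img[r, c]
  levels <- sort(unique(img[img < h]), decreasing = TRUE)
  contains_higher <- function(L) {
    comp <- oracle_flood(img >= L, r, c)
    any(img[comp] > h)
  }
  if (length(levels) == 0 || !contains_higher(min(levels)))
    return(h - min(img)) # global maximum convention
  lo <- 1L
  hi <- length(levels)
  while (lo < hi) { # find first (highest) level with the predicate TRUE
    mid <- (lo + hi) %/% 2L
    if (contains_higher(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  h - levels[lo]
}

oracle_all_maxima <- function(img) {
  lm <- oracle_local_maxima(img)
  data.frame(
    row = lm[, 1], col = lm[, 2],
    peak = img[lm],
    prominence = vapply(seq_len(nrow(lm)), function(i)
      oracle_prominence(img, lm[i, 1], lm[i, 2]), numeric(1))
  )
}

# Welch t statistic, Welch-Satterthwaite df, hand evaluation
oracle_welch <- function(a, b) {
  v1 <- var(a) / length(a)
  v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# nearest-neighbor distances, explicit double loop
oracle_nn <- function(ref, target) {
  vapply(seq_len(nrow(ref)), function(i) {
    min(sqrt((ref[i, 1] - target[, 1])^2 + (ref[i, 2] - target[, 2])^2))
  }, numeric(1))
}

# all-pairs mask intersection between two label images
oracle_pairs <- function(lab_pre, lab_post) {
  out <- NULL
  for (i in sort(unique(lab_pre[lab_pre > 0]))) {
    mi <- lab_pre == i
    for (j in sort(unique(lab_post[lab_post > 0]))) {
      if (any(mi & lab_post == j)) out <- rbind(out, c(i, j))
    }
  }
  out
}
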