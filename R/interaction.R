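#' Nearest-neighbor distances from a reference to a target point set
#'
#' One distance per reference point: the minimum Euclidean distance to any
#' target point. A reference point coincident with a target yields 0.
#'
#' @param reference,target n x 2 coordinate matrices (nm), or data frames
#'   with `x_nm`/`y_nm` (or `x`/`y`) columns. `target` must be non-empty.
#' @return Numeric vector of distances, one per reference point.
#' @export
nearest_neighbor_distances <- function(reference, target) {
  reference <- as_xy(reference)
  target <- as_xy(target)
  if (nrow(target) == 0) stop("target point set is empty")
  if (nrow(reference) == 0) return(numeric(0))
  nn_distances_xy(reference, target)
}

nn_distances_xy <- function(reference, target) {
  .nn_dist_cpp(reference, target)
}

as_xy <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("x_nm", "y_nm") %in% names(x))) {
      return(cbind(x$x_nm, x$y_nm))
    }
    return(cbind(x$x, x$y))
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# regular distance grid shared by q and p
make_grid <- function(d_max, spacing, kernel_width) {
  d <- seq(0, ceiling(d_max / spacing) * spacing, by = spacing)
  structure(list(d = d, spacing = spacing, kernel_width = kernel_width),
            class = "distance_grid")
}

smooth_on_grid <- function(distances, grid) {
  dens <- density(distances, bw = grid$kernel_width, from = 0,
                  to = max(grid$d), n = length(grid$d))$y
  dens[dens < 0] <- 0
  dens / trapz(grid$d, dens)
}

#' Kernel-smoothed nearest-neighbor distance distribution
#'
#' The observed NN-distance density q(d) on a regular grid, Gaussian-kernel
#' smoothed and renormalized to integrate to one (trapezoid rule).
#'
#' @param distances raw NN distances in nm (from
#'   [nearest_neighbor_distances()]).
#' @param grid optional grid from a matching context distribution; by
#'   default one is built covering the data.
#' @param spacing grid spacing in nm (default 27, one pixel).
#' @param kernel_width Gaussian kernel sd in nm (default 2 x spacing).
#' @return An `nn_distribution`: list with `raw`, `grid`, `density`.
#' @export
nn_distribution <- function(distances, grid = NULL, spacing = 27,
                            kernel_width = 2 * spacing) {
  if (length(distances) == 0) stop("no distances supplied")
  if (is.null(grid))
    grid <- make_grid(max(distances) + 5 * kernel_width, spacing, kernel_width)
  structure(list(raw = distances, grid = grid,
                 density = smooth_on_grid(distances, grid)),
            class = "nn_distribution")
}

#' Estimate the context distribution p(d) of a target point set
#'
#' The no-interaction baseline given the target geometry: the density of
#' nearest-neighbor distances from uniformly random FOV locations (or an
#' exhaustive regular grid) to the target set, kernel-smoothed on the same
#' kind of grid as [nn_distribution()].
#'
#' @param target target point set (matrix or data frame, nm).
#' @param fov a [fov_rect()] or [fov_disc()].
#' @param n_samples number of uniform sample locations (>= 1e4) for
#'   `method = "random"`.
#' @param method `"random"` Monte Carlo sampling or `"grid"` exhaustive
#'   regular grid (deterministic).
#' @param grid_spacing sample spacing (nm) for `method = "grid"`.
#' @inheritParams nn_distribution
#' @return A `context_distribution`: list with `grid`, `density`,
#'   `n_samples`, `d_max`.
#' @export
estimate_context_distribution <- function(target, fov, n_samples = 2e4,
                                          method = c("random", "grid"),
                                          grid_spacing = NULL,
                                          spacing = 27,
                                          kernel_width = 2 * spacing) {
  method <- match.arg(method)
  target <- as_xy(target)
  if (nrow(target) == 0) stop("target point set is empty")
  stopifnot(inherits(fov, "fov_geometry"))
  if (method == "random") {
    if (n_samples < 1e4) stop("n_samples must be at least 1e4")
    samples <- runif_fov(n_samples, fov)
  } else {
    if (is.null(grid_spacing))
      grid_spacing <- sqrt(fov$area / 4e4)
    samples <- grid_fov(fov, grid_spacing)
  }
  d <- nn_distances_xy(samples, target)
  grid <- make_grid(max(d) + 5 * kernel_width, spacing, kernel_width)
  structure(list(grid = grid, density = smooth_on_grid(d, grid),
                 n_samples = nrow(samples), d_max = max(d)),
            class = "context_distribution")
}

# model NN density under the Hernquist potential on a grid
model_density <- function(p, d, epsilon, sigma) {
  f <- p * exp(epsilon * sigma / (d + sigma))
  Z <- trapz(d, f)
  list(q = f / Z, Z = Z)
}

#' Fit the Hernquist interaction potential to an observed NN distribution
#'
#' Finds `(epsilon, sigma)` minimizing the L2 distance between the observed
#' density `q_obs(d)` and the model `p(d) exp(-phi(d; epsilon, sigma)) / Z`,
#' by bounded quasi-Newton optimization from a small set of starting points
#' spread over log-spaced sigma values. `epsilon` is the reported
#' interaction strength: 0 for independence, positive for attraction, with
#' no imposed upper bound below the box constraint. Ties between starts are
#' broken by smaller residual, then smaller `|epsilon|`.
#'
#' @param q_obs an [nn_distribution()].
#' @param p_ctx an [estimate_context_distribution()] result. Its grid is
#'   used; the observed distances are re-smoothed onto it if the grids
#'   differ.
#' @param eps_bounds,sigma_bounds box constraints for the optimizer
#'   (defaults `[-5, 10]` and `[10, 2000]` nm).
#' @param fast use a reduced start set (for Monte Carlo null fits).
#' @return An `interaction_fit`: `epsilon`, `sigma`, `residual` (L2),
#'   `Z`, `grid`, plus `p_value`/`n_mc_runs`/`alpha`/`reject` slots filled
#'   by [monte_carlo_interaction_test()].
#' @export
fit_interaction_potential <- function(q_obs, p_ctx,
                                      eps_bounds = c(-5, 10),
                                      sigma_bounds = c(10, 2000),
                                      fast = FALSE) {
  stopifnot(inherits(q_obs, "nn_distribution"),
            inherits(p_ctx, "context_distribution"))
  grid <- p_ctx$grid
  qv <- if (identical(q_obs$grid$d, grid$d)) q_obs$density
        else smooth_on_grid(q_obs$raw, grid)
  d <- grid$d
  p <- p_ctx$density
  dx <- grid$spacing
  wt <- c(dx / 2, rep(dx, length(d) - 2), dx / 2) # trapezoid weights
  obj <- function(par) {
    f <- p * exp(par[1] * par[2] / (d + par[2]))
    Z <- sum(wt * f)
    sum(wt * (qv - f / Z)^2)
  }
  starts <- if (fast) {
    rbind(c(0, 60), c(0, 300), c(1.5, 150))
  } else {
    as.matrix(expand.grid(eps = c(0, 1, 3), sigma = c(40, 150, 600)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = c(eps_bounds[1], sigma_bounds[1]),
                     upper = c(eps_bounds[2], sigma_bounds[2])),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-14 ||
        (abs(fit$value - best$value) <= 1e-14 &&
           abs(fit$par[1]) < abs(best$par[1])))
      best <- fit
  }
  if (is.null(best))
    stop("interaction fit did not converge from any start")
  md <- model_density(p, d, best$par[1], best$par[2])
  structure(list(
    epsilon = unname(best$par[1]), sigma = unname(best$par[2]),
    residual = sqrt(best$value), Z = md$Z,
    grid = grid, q_obs = qv, p_ctx = p, q_model = md$q,
    p_value = NA_real_, n_mc_runs = NA_integer_, alpha = NA_real_,
    reject = NA
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> epsilon = %.3f, sigma = %.1f nm, residual = %.3g\n",
              x$epsilon, x$sigma, x$residual))
  if (!is.na(x$p_value))
    cat(sprintf("  Monte Carlo: p = %.4g (%d runs, alpha = %g) -> %s\n",
                x$p_value, x$n_mc_runs, x$alpha,
                if (isTRUE(x$reject)) "reject independence" else "independent"))
  invisible(x)
}

#' Monte Carlo randomization test of the interaction strength
#'
#' Fits the interaction strength on the observed pattern, then refits it on
#' `n_runs` null patterns in which the reference coordinates are redrawn
#' uniformly in the FOV (counts fixed, targets fixed, so the context p(d)
#' is preserved; optionally both sets are redrawn). The one-sided add-one
#' p-value is `p = (1 + #[eps_null >= eps_obs]) / (n_runs + 1)`, and
#' independence is rejected when `p < alpha`.
#'
#' @param reference,target point sets (matrices or data frames, nm).
#' @param fov a [fov_rect()] or [fov_disc()].
#' @param n_runs null randomizations (>= 99; classic choice 1000).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed; the test is deterministic given it.
#' @param redraw `"reference"` (default) or `"both"`.
#' @param n_ctx_samples samples for the context estimate.
#' @param fast_fits use the reduced optimizer start set. Whatever the
#'   choice, observed and null statistics are computed with identical
#'   settings, so the randomization test stays exchangeable.
#' @inheritParams nn_distribution
#' @return An `interaction_fit` with `p_value`, `n_mc_runs`, `alpha`,
#'   `reject` and the vector of `null_epsilons` filled in.
#' @export
monte_carlo_interaction_test <- function(reference, target, fov,
                                         n_runs = 1000, alpha = 0.05,
                                         seed = 1L,
                                         redraw = c("reference", "both"),
                                         n_ctx_samples = 2e4,
                                         spacing = 27,
                                         kernel_width = 2 * spacing,
                                         fast_fits = FALSE) {
  redraw <- match.arg(redraw)
  if (n_runs < 99) stop("n_runs must be at least 99")
  reference <- as_xy(reference)
  target <- as_xy(target)
  set.seed(as.integer(seed))
  p_ctx <- estimate_context_distribution(target, fov, n_samples = n_ctx_samples,
                                         spacing = spacing,
                                         kernel_width = kernel_width)
  q_obs <- nn_distribution(nn_distances_xy(reference, target),
                           grid = p_ctx$grid)
  fit <- fit_interaction_potential(q_obs, p_ctx, fast = fast_fits)
  n_ref <- nrow(reference)
  null_eps <- rep(NA_real_, n_runs)
  failures <- 0L
  for (i in seq_len(n_runs)) {
    ref_i <- runif_fov(n_ref, fov)
    if (redraw == "both") {
      tgt_i <- runif_fov(nrow(target), fov)
      p_i <- estimate_context_distribution(tgt_i, fov,
                                           n_samples = n_ctx_samples,
                                           spacing = spacing,
                                           kernel_width = kernel_width)
    } else {
      tgt_i <- target
      p_i <- p_ctx
    }
    q_i <- try(nn_distribution(nn_distances_xy(ref_i, tgt_i), grid = p_i$grid),
               silent = TRUE)
    f_i <- if (inherits(q_i, "try-error")) q_i else
      try(fit_interaction_potential(q_i, p_i, fast = fast_fits),
          silent = TRUE)
    if (inherits(f_i, "try-error")) failures <- failures + 1L
    else null_eps[i] <- f_i$epsilon
  }
  if (failures > 0.1 * n_runs)
    stop("interaction fit failed in more than 10% of null runs (",
         failures, "/", n_runs, ")")
  ok <- !is.na(null_eps)
  p_value <- (1 + sum(null_eps[ok] >= fit$epsilon)) / (sum(ok) + 1)
  fit$p_value <- p_value
  fit$n_mc_runs <- sum(ok)
  fit$alpha <- alpha
  fit$reject <- p_value < alpha
  fit$null_epsilons <- null_eps[ok]
  fit
}

#' Interaction strength between two detected puncta channels
#'
#' Convenience composition for images: punctum maxima are the point
#' coordinates, the FOV is taken from the puncta set geometry, and the
#' reference-set direction is the explicit first argument (presynaptic
#' marker as reference for synapse-marker comparisons; postsynaptic marker
#' as reference for receptor comparisons).
#'
#' @param ref_puncta,target_puncta `puncta_set`s from one FOV, each with at
#'   least 10 puncta.
#' @param mc_test run the Monte Carlo randomization test (default `TRUE`).
#' @param ... passed on to [monte_carlo_interaction_test()] (or, with
#'   `mc_test = FALSE`, to [estimate_context_distribution()]).
#' @inheritParams monte_carlo_interaction_test
#' @return An `interaction_fit`.
#' @export
interaction_strength_for_channels <- function(ref_puncta, target_puncta,
                                              mc_test = TRUE,
                                              n_runs = 1000, alpha = 0.05,
                                              seed = 1L, ...) {
  stopifnot(inherits(ref_puncta, "puncta_set"),
            inherits(target_puncta, "puncta_set"))
  if (nrow(ref_puncta$table) < 10 || nrow(target_puncta$table) < 10)
    stop("need at least 10 puncta in each channel for a stable fit")
  px <- ref_puncta$pixel_size_nm
  if (px != target_puncta$pixel_size_nm ||
      !identical(ref_puncta$fov_shape, target_puncta$fov_shape))
    stop("reference and target puncta sets come from different FOVs")
  fov <- fov_rect(ref_puncta$fov_shape[2] * px, ref_puncta$fov_shape[1] * px)
  ref_xy <- cbind(ref_puncta$table$x_nm, ref_puncta$table$y_nm)
  tgt_xy <- cbind(target_puncta$table$x_nm, target_puncta$table$y_nm)
  if (mc_test) {
    monte_carlo_interaction_test(ref_xy, tgt_xy, fov, n_runs = n_runs,
                                 alpha = alpha, seed = seed,
                                 spacing = px, kernel_width = 2 * px, ...)
  } else {
    set.seed(as.integer(seed))
    p_ctx <- estimate_context_distribution(tgt_xy, fov, spacing = px,
                                           kernel_width = 2 * px, ...)
    q_obs <- nn_distribution(nn_distances_xy(ref_xy, tgt_xy),
                             grid = p_ctx$grid)
    fit_interaction_potential(q_obs, p_ctx)
  }
}
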