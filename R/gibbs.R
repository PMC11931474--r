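#' Hernquist pairwise interaction potential
#'
#' `phi(d; epsilon, sigma) = -epsilon * sigma / (d + sigma)`: a smooth
#' -1/(d + sigma) profile that tends to 0 as d grows and equals `-epsilon`
#' at contact. Positive `epsilon` is attraction (the nearest-neighbor
#' distance density is tilted toward short distances by `exp(-phi)`),
#' negative `epsilon` is repulsion. `epsilon` is the dimensionless
#' interaction strength reported by the fit; `sigma` is its length scale
#' in nm.
#'
#' @param d distances (nm).
#' @param epsilon dimensionless interaction strength.
#' @param sigma length scale in nm (> 0).
#' @return Potential values, same length as `d`.
#' @export
hernquist_potential <- function(d, epsilon, sigma) {
  stopifnot(sigma > 0)
  -epsilon * sigma / (d + sigma)
}

#' Generate a Gibbs pair pattern with a known Hernquist interaction
#'
#' Target points are uniform in the FOV. Reference points are drawn by
#' rejection sampling with acceptance weight
#' `exp(-phi(d_NN(x); epsilon, sigma))` normalized by its supremum over the
#' FOV, so the reference nearest-neighbor-distance density equals
#' `q(d) \propto p(d) exp(-phi(d))` where `p(d)` is the context density of
#' the realized target set. This is exactly the forward model fitted by
#' [fit_interaction_potential()], so recovery can be scored against truth.
#'
#' @param n_ref,n_target point counts (> 0).
#' @param epsilon,sigma Hernquist parameters (see [hernquist_potential()]).
#' @param fov a [fov_rect()] or [fov_disc()].
#' @param seed integer seed; the draw is deterministic given it.
#' @param max_tries rejection-sampling budget per accepted point, on average.
#' @return list with `reference` and `target` n x 2 coordinate matrices (nm)
#'   and the generating parameters.
#' @export
generate_gibbs_pair_pattern <- function(n_ref, n_target, epsilon, sigma, fov,
                                        seed = 1L, max_tries = 1e4) {
  stopifnot(n_ref > 0, n_target > 0, sigma > 0, inherits(fov, "fov_geometry"))
  set.seed(as.integer(seed))
  target <- runif_fov(n_target, fov)
  # sup of exp(-phi) = exp(epsilon * sigma / (d + sigma)): at d = 0 for
  # attraction, approached as d -> Inf (value 1) for repulsion
  log_sup <- max(epsilon, 0)
  reference <- matrix(NA_real_, n_ref, 2)
  accepted <- 0L
  proposed <- 0L
  batch <- max(256L, n_ref)
  while (accepted < n_ref) {
    if (proposed > max_tries * n_ref)
      stop("rejection acceptance rate < ", format(1 / max_tries),
           "; use a smaller |epsilon|")
    prop <- runif_fov(batch, fov)
    d <- nn_distances_xy(prop, target)
    logw <- epsilon * sigma / (d + sigma) - log_sup
    keep <- which(log(runif(batch)) < logw)
    proposed <- proposed + batch
    if (length(keep) > 0) {
      take <- keep[seq_len(min(length(keep), n_ref - accepted))]
      reference[accepted + seq_along(take), ] <- prop[take, , drop = FALSE]
      accepted <- accepted + length(take)
    }
  }
  colnames(reference) <- colnames(target) <- c("x", "y")
  list(reference = reference, target = target,
       epsilon = epsilon, sigma = sigma, fov = fov, seed = as.integer(seed))
}
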