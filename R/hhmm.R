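#' Inner-HMM parameters
#'
#' The inner HMM explains samples within one base block: states `prev`, `curr`
#' and `next` emit Gaussians centred on the neighbouring k-mer baselines (the
#' jiggling excursions), and `noise` emits uniformly over `noise_bounds`.
#'
#' @param transition 4x4 row-stochastic matrix over (prev, curr, next, noise).
#' @param initial initial distribution over the four states.
#' @param sigma_inner shared emission std for prev/curr/next (pA).
#' @param noise_bounds pA interval of the uniform noise state; `NULL` means
#'   derive from the signal at use time (range widened by 5 pA).
#' @return An `inner_params` list.
#' @export
inner_params <- function(transition = NULL, initial = NULL, sigma_inner = 2.5,
                         noise_bounds = NULL) {
  if (is.null(transition))
    transition <- matrix(rep(c(0.05, 0.88, 0.05, 0.02), 4), 4, byrow = TRUE)
  if (is.null(initial))
    initial <- c(0.05, 0.88, 0.05, 0.02)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    ps_validation_error("inner transition matrix rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9)
    ps_validation_error("inner initial distribution must sum to 1")
  if (sigma_inner <= 0)
    ps_validation_error("sigma_inner must be > 0")
  structure(list(transition = transition, initial = initial,
                 sigma_inner = sigma_inner, noise_bounds = noise_bounds),
            class = "inner_params")
}

#' Outer-HMM parameters
#'
#' The outer HMM arranges the read into alternating base (B) and transition
#' (T) blocks; its per-sample transition probabilities penalize block changes.
#'
#' @param T_outer 2x2 row-stochastic matrix over (B, T).
#' @param pi_outer initial distribution over (B, T).
#' @param min_base_len minimum base-block length (samples).
#' @param max_base_len maximum base-block length considered between
#'   non-adjacent lattice candidates (caps the dynamic program's work; blocks
#'   between adjacent candidates are always admissible, so degenerate flat
#'   signals still segment into one block).
#' @param max_trans_len maximum transition-block length (samples).
#' @return An `outer_params` list.
#' @export
outer_params <- function(T_outer = matrix(c(0.995, 0.005, 0.15, 0.85), 2,
                                          byrow = TRUE),
                         pi_outer = c(0.99, 0.01),
                         min_base_len = 3L, max_base_len = 150L,
                         max_trans_len = 10L) {
  if (any(abs(rowSums(T_outer) - 1) > 1e-9))
    ps_validation_error("outer transition matrix rows must sum to 1")
  structure(list(T_outer = T_outer, pi_outer = pi_outer,
                 min_base_len = as.integer(min_base_len),
                 max_base_len = as.integer(max_base_len),
                 max_trans_len = as.integer(max_trans_len)),
            class = "outer_params")
}

#' Transition-block (linear ramp) model parameters
#'
#' @param min_abs_slope minimum |slope| (pA per sample) for a stretch to be
#'   admissible as a transition block.
#' @param residual_sigma Gaussian residual std around the fitted line (pA).
#' @return A `trans_params` list.
#' @export
trans_params <- function(min_abs_slope = 0.5, residual_sigma = 1.0) {
  if (min_abs_slope <= 0)
    ps_validation_error("min_abs_slope must be > 0")
  structure(list(min_abs_slope = min_abs_slope,
                 residual_sigma = residual_sigma), class = "trans_params")
}

resolve_noise_bounds <- function(params, samples) {
  if (!is.null(params$noise_bounds)) {
    nb <- params$noise_bounds
    if (nb[2] <= nb[1])
      ps_validation_error("noise_bounds must be a non-degenerate interval")
    return(nb)
  }
  range(samples) + c(-5, 5)
}

#' Inner-HMM marginal log-likelihood of a base block
#'
#' Forward-algorithm marginal over all hidden-state paths, with Gaussian
#' emissions `N(mu_prev/curr/next, sigma_inner)` and the uniform noise state,
#' computed with per-step scaling (stable for long blocks). An `NA` mean
#' disables the corresponding state (its transition and initial probabilities
#' are zeroed and renormalized).
#'
#' @param samples numeric vector of current samples (>= 1).
#' @param mu_prev,mu_curr,mu_next state means (pA); `NA` disables prev/next.
#' @param params an [inner_params()].
#' @return Log marginal likelihood; `-Inf` when the data have zero probability
#'   under the model.
#' @export
inner_block_loglik <- function(samples, mu_prev, mu_curr, mu_next, params) {
  if (length(samples) < 1)
    ps_validation_error("inner_block_loglik() needs at least one sample")
  nb <- resolve_noise_bounds(params, samples)
  .inner_forward_cpp(samples, c(mu_prev, mu_curr, mu_next), params$transition,
                     params$initial, params$sigma_inner, nb[1], nb[2])
}

#' Per-sample inner-HMM state posteriors
#'
#' Forward-backward posteriors over (prev, curr, next, noise) for each sample
#' of a base block.
#'
#' @inheritParams inner_block_loglik
#' @return Matrix `length(samples)` x 4 with columns `prev`, `curr`, `next`,
#'   `noise`; rows sum to 1.
#' @export
inner_posteriors <- function(samples, mu_prev, mu_curr, mu_next, params) {
  if (length(samples) < 1)
    ps_validation_error("inner_posteriors() needs at least one sample")
  nb <- resolve_noise_bounds(params, samples)
  post <- .inner_posteriors_cpp(samples, c(mu_prev, mu_curr, mu_next),
                                params$transition, params$initial,
                                params$sigma_inner, nb[1], nb[2])
  colnames(post) <- c("prev", "curr", "next", "noise")
  post
}

#' Transition-block log-likelihood
#'
#' Ordinary least-squares line fit to the samples; the log-likelihood is the
#' Gaussian density of the residuals. A fitted |slope| below `min_abs_slope`
#' makes the stretch inadmissible as a transition block (`-Inf`), as the model
#' requires a steep ramp between consecutive k-mer baselines.
#'
#' @param samples numeric vector (>= 2 samples, otherwise `-Inf`).
#' @param params a [trans_params()].
#' @return Log-likelihood or `-Inf`.
#' @export
transition_block_loglik <- function(samples, params) {
  .transition_loglik_cpp(samples, params$min_abs_slope, params$residual_sigma)
}

#' Candidate changepoints from multiscale mean shifts
#'
#' At each window size `w`, computes the difference between the mean of the
#' next `w` samples and the mean of the previous `w` samples, standardized by
#' a robust noise estimate (median absolute first difference). Local peaks of
#' the |z| profile above `z_thr` mark probable boundaries; a dense cluster of
#' candidates (`peak - spread .. peak + spread`) is emitted around each so the
#' segmentation dynamic program can place the exact boundary. Recall-oriented:
#' the lattice should be a superset of the true boundaries, with precision
#' left to the DP. Always includes 0 and `length(signal)`.
#'
#' @param signal numeric current samples.
#' @param windows integer window sizes.
#' @param z_thr peak threshold in robust z units.
#' @param spread half-width of the candidate cluster around each peak.
#' @return Strictly increasing integer vector of 0-based boundary candidates.
#' @export
propose_changepoints <- function(signal, windows = c(4L, 6L, 10L), z_thr = 3,
                                 spread = 3L) {
  n <- length(signal)
  out <- c(0L, n)
  if (n < 4) return(sort(unique(out)))
  # robust per-sample noise: for N(0, sigma), median|diff| = 0.6745 * sigma * sqrt(2)
  sigma_hat <- median(abs(diff(signal))) / (0.6745 * sqrt(2))
  if (!is.finite(sigma_hat) || sigma_hat <= 0)
    return(sort(unique(out)))          # constant (or near-constant) signal
  cs <- cumsum(c(0, signal))
  for (w in windows) {
    if (n < 2 * w + 2) next
    t <- seq(w, n - w)                 # 0-based boundary positions
    right <- (cs[t + w + 1] - cs[t + 1]) / w
    left <- (cs[t + 1] - cs[t - w + 1]) / w
    z <- abs(right - left) / (sigma_hat * sqrt(2 / w))
    m <- length(z)
    is_peak <- z > z_thr &
      z >= c(-Inf, z[-m]) & z > c(z[-1], -Inf)
    for (p in which(is_peak))
      out <- c(out, t[p] + seq(-spread, spread))
  }
  sort(unique(pmin(pmax(out, 0L), n)))
}

#' Segment a standardized signal into base and transition blocks
#'
#' Maximizes the hierarchical-HMM joint objective — inner-HMM marginals for
#' base blocks, gated linear-ramp likelihoods for transition blocks, and the
#' outer HMM's per-sample transition probabilities — exactly over the
#' candidate-changepoint lattice, by dynamic programming. The segmentation
#' alternates B, T, ..., B (2K+1 blocks). During segmentation no reference is
#' available, so the prev/next baselines of a candidate base block are the
#' trimmed means of the nearest base-length elementary candidate segments on
#' either side; at the read ends the corresponding state is disabled.
#'
#' Per-base-block mean and std are computed from samples whose posterior
#' probability of the noise state is <= 0.5.
#'
#' @param signal standardized transcript-region samples.
#' @param outer an [outer_params()].
#' @param inner an [inner_params()].
#' @param trans a [trans_params()].
#' @param candidates optional candidate boundary vector; defaults to
#'   [propose_changepoints()].
#' @param read_id identifier stored in the result.
#' @return A `segmentation`: list with `read_id`, `blocks` (data.frame `start`,
#'   `end`, `label`, `mean`, `std`, `n`; 0-based half-open, relative to
#'   `signal`) and `total_loglik`. Attribute `degenerate` is `TRUE` when the
#'   signal was too short to segment and a single block was returned.
#' @export
segment_signal <- function(signal, outer = outer_params(),
                           inner = inner_params(), trans = trans_params(),
                           candidates = NULL, read_id = NA_character_) {
  n <- length(signal)
  single_block <- function(warn) {
    blocks <- data.frame(start = 0L, end = n, label = "B",
                         mean = mean(signal), std = if (n > 1) sd(signal) else 0,
                         n = n, stringsAsFactors = FALSE)
    res <- structure(list(read_id = read_id, blocks = blocks,
                          total_loglik = NA_real_),
                     class = "segmentation")
    attr(res, "degenerate") <- warn
    res
  }
  if (n < max(outer$min_base_len, 2L)) {
    warning("signal shorter than min_base_len; returning a single block")
    return(single_block(TRUE))
  }
  if (is.null(candidates))
    candidates <- propose_changepoints(signal)
  candidates <- sort(unique(as.integer(c(0L, candidates, n))))
  nb <- resolve_noise_bounds(inner, signal)
  dp <- .segment_dp_cpp(signal, candidates, outer$min_base_len,
                        outer$max_base_len,
                        outer$max_trans_len, trans$min_abs_slope,
                        trans$residual_sigma, inner$transition, inner$initial,
                        inner$sigma_inner, nb[1], nb[2],
                        log(outer$T_outer), log(outer$pi_outer[1]), 0.1)
  if (!isTRUE(dp$ok))
    return(single_block(TRUE))
  nblk <- length(dp$start)
  means <- stds <- ns <- numeric(nblk)
  for (b in seq_len(nblk)) {
    seg <- signal[(dp$start[b] + 1):dp$end[b]]
    if (dp$label[b] == "B") {
      mu_curr <- mean(seg, trim = 0.1)
      post <- inner_posteriors(seg, dp$mu_prev[b], mu_curr, dp$mu_next[b],
                               inner_params(inner$transition, inner$initial,
                                            inner$sigma_inner, nb))
      # mask structured noise: keep samples the inner HMM attributes to the
      # current k-mer (this also excludes noise-state samples); the block mean
      # additionally trims 15% per tail, since excursions whose baseline sits
      # within ~2 sigma of the current level evade per-sample attribution
      keep <- seg[post[, "curr"] >= 0.5]
      if (length(keep) < 2) keep <- seg[post[, "noise"] <= 0.5]
      if (length(keep) == 0) keep <- seg
      means[b] <- mean(keep, trim = 0.15)
      stds[b] <- if (length(keep) > 1) sd(keep) else 0
      ns[b] <- length(keep)
    } else {
      means[b] <- mean(seg)
      stds[b] <- if (length(seg) > 1) sd(seg) else 0
      ns[b] <- length(seg)
    }
  }
  blocks <- data.frame(start = dp$start, end = dp$end, label = dp$label,
                       mean = means, std = stds, n = ns,
                       stringsAsFactors = FALSE)
  structure(list(read_id = read_id, blocks = blocks,
                 total_loglik = dp$loglik),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  nB <- sum(x$blocks$label == "B")
  cat(sprintf("segmentation of %s: %d blocks (%d base, %d transition), loglik %.2f\n",
              x$read_id, nrow(x$blocks), nB, nrow(x$blocks) - nB,
              x$total_loglik))
  invisible(x)
}

#' Segment the transcript region of a read
#'
#' Convenience wrapper: extracts the read's transcript-region samples, runs
#' [segment_signal()], and reports block coordinates in whole-read sample
#' indices.
#'
#' @param read a [read_record()].
#' @inheritParams segment_signal
#' @return A `segmentation` with absolute sample coordinates.
#' @export
segment_read <- function(read, outer = outer_params(), inner = inner_params(),
                         trans = trans_params()) {
  iv <- read$transcript_interval
  seg <- segment_signal(read$signal[(iv[1] + 1):iv[2]], outer, inner, trans,
                        read_id = read$read_id)
  seg$blocks$start <- seg$blocks$start + iv[1]
  seg$blocks$end <- seg$blocks$end + iv[1]
  seg
}

#' Export a segmentation as a data.frame
#'
#' @param segs list of `segmentation` objects.
#' @return data.frame `read_id`, `block_index`, `label`, `start`, `end`,
#'   `mean`, `std`.
#' @export
segmentation_table <- function(segs) {
  do.call(rbind, lapply(segs, function(s)
    data.frame(read_id = s$read_id, block_index = seq_len(nrow(s$blocks)) - 1L,
               label = s$blocks$label, start = s$blocks$start,
               end = s$blocks$end, mean = s$blocks$mean, std = s$blocks$std,
               stringsAsFactors = FALSE)))
}
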