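#' Two-component Gaussian mixture with a fixed first mean
#'
#' EM fit of `w1 * N(mu_fixed, sigma1) + w2 * N(mu2, sigma2)` where the first
#' (unmodified) component's mean stays pinned to the pore-model baseline at
#' every M step; only its std and weight are re-estimated. Pinning removes the
#' label-swapping ambiguity and anchors the mixture to the unmodified state.
#'
#' Initialization: component 1 at `(mu_fixed, sd(values))`; component 2 at the
#' mean of the points beyond one sample-std of `mu_fixed` on the heavier side
#' (same std), weights (0.7, 0.3). Three restarts with seed-derived jitter on
#' the second mean; the best log-likelihood is kept, so the fit is
#' deterministic given `seed`.
#'
#' @param values event means pooled for one k-mer (pA).
#' @param mu_fixed pinned mean of the unmodified component (pA).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed for the restart jitter.
#' @param min_points minimum number of values (coverage floor).
#' @return A `gmm_fit`: list with `mu1`, `sigma1`, `w1`, `mu2`, `sigma2`,
#'   `w2`, `n_points`, `n_iter`, `converged`, `loglik`, and `clamped` (TRUE if
#'   a std hit the 0.05 pA floor).
#' @export
fit_gmm_fixed_mean <- function(values, mu_fixed, tol = 1e-6, max_iter = 500L,
                               seed = 1L, min_points = 50L) {
  n <- length(values)
  if (n < min_points)
    ps_coverage_error(sprintf(
      "insufficient coverage for GMM fit: %d points < floor %d", n, min_points))
  set.seed(seed)
  s0 <- sd(values)
  if (!is.finite(s0) || s0 <= 0) s0 <- 0.05
  lo <- values[values < mu_fixed - s0]
  hi <- values[values > mu_fixed + s0]
  heavier <- if (length(hi) >= length(lo)) hi else lo
  mu2_0 <- if (length(heavier) > 0) mean(heavier)
           else mu_fixed + s0

  best <- NULL
  for (r in 1:3) {
    mu2 <- mu2_0 + (r - 1) * 0.5 * s0 * rnorm(1)
    fit <- em_fixed_mean(values, mu_fixed, mu2, s0, c(0.7, 0.3), tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$n_points <- n
  structure(best, class = "gmm_fit")
}

em_fixed_mean <- function(x, mu1, mu2, s0, w, tol, max_iter) {
  sigma1 <- sigma2 <- s0
  w1 <- w[1]; w2 <- w[2]
  clamped <- FALSE
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w1 * dnorm(x, mu1, sigma1)
    d2 <- w2 * dnorm(x, mu2, sigma2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    # mu1 stays fixed; only its spread and weight are updated
    sigma1 <- sqrt(sum(r1 * (x - mu1)^2) / max(n1, 1e-12))
    mu2 <- sum(r2 * x) / max(n2, 1e-12)
    sigma2 <- sqrt(sum(r2 * (x - mu2)^2) / max(n2, 1e-12))
    if (sigma1 < 0.05) { sigma1 <- 0.05; clamped <- TRUE }
    if (sigma2 < 0.05) { sigma2 <- 0.05; clamped <- TRUE }
    w1 <- n1 / length(x); w2 <- n2 / length(x)
  }
  list(mu1 = mu1, sigma1 = sigma1, w1 = w1, mu2 = mu2, sigma2 = sigma2,
       w2 = w2, n_iter = it, converged = converged, loglik = ll_old,
       clamped = clamped)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "fixed-mean GMM (n = %d): comp1 N(%.2f, %.2f) w = %.3f | comp2 N(%.2f, %.2f) w = %.3f\n",
    x$n_points, x$mu1, x$sigma1, x$w1, x$mu2, x$sigma2, x$w2))
  cat(sprintf("loglik %.2f after %d iterations (%sconverged)\n", x$loglik,
              x$n_iter, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Classify one event against a k-mer's two-state model
#'
#' The hard state call compares the unweighted Gaussian densities of the event
#' mean under the modified and unmodified baselines (modified wins when its
#' density is larger). The reported probability is the weight-aware posterior
#' `w_mod phi_mod / (w_un phi_un + w_mod phi_mod)`.
#'
#' @param event_mean event mean (pA); vectorized.
#' @param kmer_params one-row parameter data.frame (see [lookup_kmer()]) with
#'   `mod_enabled = TRUE`.
#' @return data.frame with `prob_mod` and `state`
#'   (`"modified"`/`"unmodified"`).
#' @export
classify_read <- function(event_mean, kmer_params) {
  if (!isTRUE(kmer_params$mod_enabled))
    ps_validation_error(paste0("k-mer not callable (no modification parameters): ",
                               kmer_params$kmer))
  d_un <- dnorm(event_mean, kmer_params$mu_un, kmer_params$sigma_un)
  d_mod <- dnorm(event_mean, kmer_params$mu_mod, kmer_params$sigma_mod)
  num <- kmer_params$omega_mod * d_mod
  den <- kmer_params$omega_un * d_un + num
  prob <- ifelse(den > 0, num / den, 0.5)
  data.frame(prob_mod = prob,
             state = ifelse(d_mod > d_un, "modified", "unmodified"),
             stringsAsFactors = FALSE)
}

#' Site-level modification rate
#'
#' @param read_calls data.frame of per-read calls at one site (`state` column,
#'   plus `reference_id`, `position`, `kmer` taken from the first row).
#' @param min_site_coverage minimum read count; below it the site is skipped
#'   (an error of class `poreseg_coverage_error`).
#' @return One-row data.frame `reference_id`, `position`, `kmer`, `coverage`,
#'   `mod_rate`.
#' @export
site_mod_rate <- function(read_calls, min_site_coverage = 20L) {
  cov <- nrow(read_calls)
  if (cov < min_site_coverage)
    ps_coverage_error(sprintf("site coverage %d below minimum %d",
                              cov, min_site_coverage))
  data.frame(reference_id = read_calls$reference_id[1],
             position = read_calls$position[1],
             kmer = read_calls$kmer[1],
             coverage = cov,
             mod_rate = mean(read_calls$state == "modified"),
             stringsAsFactors = FALSE)
}

#' Call modification states from events
#'
#' Applies [classify_read()] to every event whose k-mer has modification
#' parameters, and aggregates per-site rates.
#'
#' @param events events data.frame (possibly many reads).
#' @param table a [kmer_table()].
#' @param min_site_coverage per-site coverage floor for the site summary.
#' @return List with `read_calls` (read_id, reference_id, position, kmer,
#'   prob_mod, state) and `site_calls` (sites meeting the coverage floor;
#'   skipped sites are listed in `skipped` with the reason).
#' @export
call_modifications <- function(events, table, min_site_coverage = 20L) {
  callable <- events$model_kmer %in% rownames(table)[table$mod_enabled]
  ev <- events[callable, , drop = FALSE]
  if (nrow(ev) == 0)
    return(list(read_calls = NULL, site_calls = NULL, skipped = NULL))
  calls <- do.call(rbind, lapply(unique(ev$model_kmer), function(km) {
    p <- lookup_kmer(table, km)
    e <- ev[ev$model_kmer == km, , drop = FALSE]
    cbind(data.frame(read_id = e$read_name, reference_id = e$contig,
                     position = e$position, kmer = km,
                     stringsAsFactors = FALSE),
          classify_read(e$event_level_mean, p))
  }))
  site_calls <- NULL
  skipped <- NULL
  for (key in unique(paste(calls$reference_id, calls$position))) {
    rc <- calls[paste(calls$reference_id, calls$position) == key, , drop = FALSE]
    res <- tryCatch(site_mod_rate(rc, min_site_coverage),
                    poreseg_coverage_error = function(e) conditionMessage(e))
    if (is.character(res))
      skipped <- rbind(skipped, data.frame(
        reference_id = rc$reference_id[1], position = rc$position[1],
        reason = res, stringsAsFactors = FALSE))
    else site_calls <- rbind(site_calls, res)
  }
  list(read_calls = calls, site_calls = site_calls, skipped = skipped)
}

#' Re-estimate the k-mer parameter table from pooled events
#'
#' For every k-mer whose pooled coverage (event means across reads and sites)
#' reaches `min_coverage`, fits [fit_gmm_fixed_mean()] with the first mean
#' pinned to the current unmodified baseline, then updates `sigma_un`,
#' `omega_un`, `mu_mod`, `sigma_mod`, `omega_mod`. A k-mer is flagged
#' `mod_enabled` only when the component separation exceeds `min_sep` pA, the
#' modified weight is at least `min_weight`, and the modified std lies in a
#' plausible 0.5-10 pA band (it is clamped into the band otherwise); k-mers
#' failing the gates keep their previous parameters with
#' `mod_enabled = FALSE` recomputed from the gates.
#'
#' @param events pooled events data.frame.
#' @param table current [kmer_table()].
#' @param min_coverage pooled coverage gate (defaults to 1500; simulations use
#'   lower values via configuration).
#' @param min_sep separation gate (pA).
#' @param min_weight minimum modified-component weight.
#' @param seed seed for the GMM restarts.
#' @return List with `table` (updated `kmer_table`) and `report` (one row per
#'   fitted k-mer: coverage, separation, weight, gates passed).
#' @export
reestimate_table <- function(events, table, min_coverage = 1500L, min_sep = 5,
                             min_weight = 0.05, seed = 1L) {
  df <- as.data.frame(table)
  report <- NULL
  counts <- table(events$model_kmer)
  for (km in names(counts)[counts >= min_coverage]) {
    if (!km %in% rownames(df)) next
    vals <- events$event_level_mean[events$model_kmer == km]
    p <- df[km, ]
    fit <- fit_gmm_fixed_mean(vals, p$mu_un,
                              seed = derive_seed(seed, which(rownames(df) == km)),
                              min_points = min(50L, min_coverage))
    sep <- abs(fit$mu2 - fit$mu1)
    sigma2 <- min(max(fit$sigma2, 0.5), 10)
    pass <- sep > min_sep && fit$w2 >= min_weight
    report <- rbind(report, data.frame(
      kmer = km, coverage = length(vals), mu_mod = fit$mu2,
      sigma_mod = sigma2, omega_mod = fit$w2, separation = sep,
      mod_enabled = pass, stringsAsFactors = FALSE))
    df[km, "sigma_un"] <- max(fit$sigma1, 0.05)
    if (pass) {
      df[km, c("mu_mod", "sigma_mod")] <- c(fit$mu2, sigma2)
      df[km, c("omega_un", "omega_mod")] <- c(fit$w1, fit$w2) / (fit$w1 + fit$w2)
      df[km, "mod_enabled"] <- TRUE
    } else {
      df[km, c("mu_mod", "sigma_mod")] <- NA_real_
      df[km, c("omega_un", "omega_mod")] <- c(1, 0)
      df[km, "mod_enabled"] <- FALSE
    }
  }
  list(table = kmer_table(df), report = report)
}

#' Iterate alignment and table re-estimation to stability
#'
#' Runs \{align -> assemble events -> re-estimate table\} starting from
#' `table0` until the mean absolute change of the k-mer mean values (both
#' components where defined) drops below `tol` or `max_rounds` is reached.
#' Segmentation does not depend on the table and is computed once.
#'
#' @param reads list of standardized [read_record()]s.
#' @param references named character vector of reference sequences.
#' @param table0 initial [kmer_table()].
#' @param max_rounds maximum refinement rounds.
#' @param tol stop when the mean |change of mean values| is below this (pA).
#' @param segmentations optional precomputed list of segmentations (parallel
#'   to `reads`).
#' @param min_coverage,min_sep,seed passed to [reestimate_table()].
#' @param outer,inner,trans segmentation parameters (used only when
#'   `segmentations` is not supplied).
#' @return List with `table`, `converged`, `rounds` (data.frame of per-round
#'   mean |delta mu|), and the final `events`.
#' @export
iterate_workflow <- function(reads, references, table0, max_rounds = 5L,
                             tol = 5e-3, segmentations = NULL,
                             min_coverage = 1500L, min_sep = 5, seed = 1L,
                             outer = outer_params(), inner = inner_params(),
                             trans = trans_params()) {
  if (is.null(segmentations))
    segmentations <- lapply(reads, segment_read, outer = outer, inner = inner,
                            trans = trans)
  table <- table0
  rounds <- NULL
  converged <- FALSE
  events <- NULL
  for (round in seq_len(max_rounds)) {
    events <- do.call(rbind, lapply(seq_along(reads), function(i) {
      r <- reads[[i]]
      ref <- ref_kmer_seq(references[[r$reference_id]], table_k(table),
                          r$reference_id)
      seg <- segmentations[[i]]
      mu <- seg$blocks$mean[seg$blocks$label == "B"]
      al <- align_full(mu, ref, table)
      assemble_events(al, seg, read_id = r$read_id)
    }))
    upd <- reestimate_table(events, table, min_coverage = min_coverage,
                            min_sep = min_sep, seed = derive_seed(seed, round))
    change <- table_mean_change(table, upd$table)
    rounds <- rbind(rounds, data.frame(round = round, mean_abs_dmu = change))
    table <- upd$table
    if (change < tol) { converged <- TRUE; break }
  }
  list(table = table, converged = converged, rounds = rounds, events = events)
}

# mean over k-mers of |change in mean values|, both components where defined
# in either table (a component appearing/disappearing contributes its shift
# relative to the unmodified baseline it collapsed to).
table_mean_change <- function(old, new) {
  deltas <- abs(new$mu_un - old$mu_un)           # pinned, normally zero
  both <- old$mod_enabled & new$mod_enabled
  deltas <- c(deltas, abs(new$mu_mod[both] - old$mu_mod[both]))
  gained <- !old$mod_enabled & new$mod_enabled
  lost <- old$mod_enabled & !new$mod_enabled
  deltas <- c(deltas, abs(new$mu_mod[gained] - new$mu_un[gained]),
              abs(old$mu_mod[lost] - old$mu_un[lost]))
  mean(deltas)
}
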