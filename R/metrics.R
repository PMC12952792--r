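#' Segmentation benchmark metrics
#'
#' Two summary metrics over events: the average standard deviation of the
#' event samples (lower = less structured noise left inside events) and the
#' average log-likelihood of the event mean under the pore-model baseline of
#' its k-mer (higher = event means closer to the table, natural log). Events
#' produced by pipelines that keep boundary samples inside events are
#' conventionally trimmed by `trim` samples at each end before the statistics
#' are recomputed (use `trim = 0` for events whose transition samples were
#' already excluded, `trim = 3` for equal-width style events).
#'
#' @param events events data.frame carrying per-event raw samples (the
#'   `samples` attribute set by [assemble_events()] / [equal_width_baseline()],
#'   or a `samples` list passed explicitly).
#' @param table a [kmer_table()] providing `(mu_un, sigma_un)` per k-mer.
#' @param trim samples dropped from each end of every event.
#' @param samples optional list of per-event sample vectors overriding the
#'   attribute.
#' @return A `metrics_report`: list with `avg_std` (pA), `avg_logp`,
#'   `n_events`, `n_excluded` (events shorter than `2 * trim + 1`), and
#'   `per_kmer` (macro breakdown data.frame with per-k-mer means).
#' @export
segment_metrics <- function(events, table, trim = 0L, samples = NULL) {
  if (is.null(samples))
    samples <- attr(events, "samples")
  if (is.null(samples))
    ps_validation_error("segment_metrics() needs per-event samples")
  if (length(samples) != nrow(events))
    ps_validation_error("samples list and events disagree in length")
  stds <- logps <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    x <- samples[[i]]
    if (trim > 0) {
      if (length(x) < 2 * trim + 1) next        # excluded, counted below
      x <- x[(trim + 1):(length(x) - trim)]
    }
    p <- lookup_kmer(table, events$model_kmer[i])
    stds[i] <- if (length(x) > 1) sd(x) else 0
    logps[i] <- dnorm(mean(x), p$mu_un, p$sigma_un, log = TRUE)
  }
  keep <- !is.na(stds)
  per_kmer <- NULL
  if (any(keep)) {
    km <- events$model_kmer[keep]
    per_kmer <- data.frame(
      kmer = sort(unique(km)),
      avg_std = tapply(stds[keep], km, mean)[sort(unique(km))],
      avg_logp = tapply(logps[keep], km, mean)[sort(unique(km))],
      n_events = as.integer(table(km)[sort(unique(km))]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(avg_std = mean(stds[keep]), avg_logp = mean(logps[keep]),
                 n_events = sum(keep), n_excluded = sum(!keep),
                 per_kmer = per_kmer),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("segmentation metrics over %d events (%d excluded):\n",
              x$n_events, x$n_excluded))
  cat(sprintf("  avg std  : %.3f pA\n  avg log p: %.3f\n",
              x$avg_std, x$avg_logp))
  invisible(x)
}

#' Equal-width baseline events
#'
#' Control condition for the benchmark: the transcript-region signal is split
#' into as many equal-width contiguous segments as there are reference k-mers,
#' one per k-mer in pore order, with no model at all.
#'
#' @param signal transcript-region samples.
#' @param ref a [ref_kmer_seq()].
#' @param read_id read identifier.
#' @return Events data.frame (with the `samples` attribute), comparable to
#'   [assemble_events()] output.
#' @export
equal_width_baseline <- function(signal, ref, read_id = "read_1") {
  n <- length(ref$kmers)
  N <- length(signal)
  if (n < 1 || N < n)
    ps_validation_error("signal shorter than the number of reference k-mers")
  edges <- round(seq(0, N, length.out = n + 1))
  out <- vector("list", n)
  samples <- vector("list", n)
  for (j in seq_len(n)) {
    x <- signal[(edges[j] + 1):edges[j + 1]]
    out[[j]] <- data.frame(
      contig = ref$reference_id, position = ref$positions[j],
      reference_kmer = ref$kmers[j], read_name = read_id,
      event_level_mean = mean(x),
      event_stdv = if (length(x) > 1) sd(x) else 0,
      event_length = length(x), start_idx = edges[j], end_idx = edges[j + 1],
      model_kmer = ref$kmers[j], stringsAsFactors = FALSE)
    samples[[j]] <- x
  }
  ev <- do.call(rbind, out)
  ord <- order(ev$position)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "samples") <- samples[ord]
  ev
}
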