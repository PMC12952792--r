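#' Run the segmentation-and-alignment pipeline over a read set
#'
#' Standardize (poly(A)-anchored), segment, align, and assemble events for a
#' list of reads, using the full alignment variant against each read's
#' reference. This is the programmatic equivalent of the `segment` + `align` +
#' `eventalign` CLI steps.
#'
#' @param reads list of [read_record()]s (simulated or loaded from a
#'   container).
#' @param references named character vector of reference sequences.
#' @param table a [kmer_table()].
#' @param standardized set `TRUE` when the signals are already standardized.
#' @param attach_samples attach per-event raw samples (needed by
#'   [segment_metrics()]).
#' @param outer,inner,trans segmentation parameters.
#' @return List with `events` (one data.frame across reads; `samples`
#'   attribute when requested), `segmentations`, and the (standardized)
#'   `reads`.
#' @export
pipeline_events <- function(reads, references, table, standardized = FALSE,
                            attach_samples = FALSE, outer = outer_params(),
                            inner = inner_params(), trans = trans_params()) {
  if (!standardized) {
    tg <- default_targets(table)
    reads <- lapply(reads, standardize_read, target_mu = tg[1],
                    target_sigma = tg[2])
  }
  segs <- lapply(reads, segment_read, outer = outer, inner = inner,
                 trans = trans)
  evs <- vector("list", length(reads))
  samp <- list()
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    ref <- ref_kmer_seq(references[[r$reference_id]], table_k(table),
                        r$reference_id)
    mu <- segs[[i]]$blocks$mean[segs[[i]]$blocks$label == "B"]
    al <- align_full(mu, ref, table)
    ev <- assemble_events(al, segs[[i]],
                          signal = if (attach_samples) r$signal,
                          read_id = r$read_id)
    if (attach_samples) samp <- c(samp, attr(ev, "samples"))
    evs[[i]] <- ev
  }
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  if (attach_samples) attr(events, "samples") <- samp
  list(events = events, segmentations = segs, reads = reads)
}
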