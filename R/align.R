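#' Reference k-mer list in pore-traversal order
#'
#' Direct RNA is sequenced 3'->5': the 3'-most k-mer enters the pore first, so
#' the time order of the signal corresponds to the reverse of the 5'->3'
#' positional order. `ref_kmer_seq()` stores the k-mer strings in pore order
#' together with their 0-based start positions in reference coordinates.
#'
#' @param reference reference sequence (5'->3'; U allowed).
#' @param k k-mer length.
#' @param reference_id identifier carried into events.
#' @return A `ref_kmer_seq`: list with `kmers`, `positions`, `reference_id`,
#'   `k`.
#' @export
ref_kmer_seq <- function(reference, k, reference_id = "ref_1") {
  reference <- normalize_reference(reference)
  po <- pore_order_kmers(reference, k)
  structure(list(kmers = po$kmers, positions = po$positions,
                 reference_id = reference_id, k = k),
            class = "ref_kmer_seq")
}

#' Match score of a block mean against a k-mer
#'
#' Log-density of the mean under the k-mer's Gaussian baseline; when the k-mer
#' has modification parameters, the larger of the unmodified and modified
#' log-densities is used, so a modified block is not penalized during
#' alignment.
#'
#' @param mu block mean(s), pA.
#' @param kmer k-mer string.
#' @param table a [kmer_table()].
#' @return Log-density score (vectorized over `mu`).
#' @export
kmer_score <- function(mu, kmer, table) {
  p <- lookup_kmer(table, kmer)
  s <- dnorm(mu, p$mu_un, p$sigma_un, log = TRUE)
  if (p$mod_enabled)
    s <- pmax(s, dnorm(mu, p$mu_mod, p$sigma_mod, log = TRUE))
  s
}

#' Indel score
#'
#' Insertions (a block mean aligned to `-`) and deletions (`0.0` aligned to a
#' k-mer) are scored as noise: the log-density of a fixed uniform distribution
#' whose range defaults to the spread of the table's baselines widened by three
#' times the largest std on each side.
#'
#' @param table a [kmer_table()].
#' @param range optional explicit range (pA).
#' @return A single negative constant, `log(1/range)`.
#' @export
indel_score <- function(table, range = NULL) {
  if (is.null(range)) {
    sig <- c(table$sigma_un, table$sigma_mod[table$mod_enabled])
    mus <- c(table$mu_un, table$mu_mod[table$mod_enabled])
    range <- (max(mus) - min(mus)) + 6 * max(sig)
  }
  if (range <= 0)
    ps_validation_error("indel score range must be positive")
  -log(range)
}

resolve_ref <- function(kmers, table) {
  if (inherits(kmers, "ref_kmer_seq")) return(kmers)
  structure(list(kmers = normalize_kmer(kmers),
                 positions = rep(NA_integer_, length(kmers)),
                 reference_id = NA_character_, k = table_k(table)),
            class = "ref_kmer_seq")
}

# Shared DP core for both variants. Moves (and fill-time tie-break priority):
# stay (mu_i joins s_j below mu_{i-1}) > diagonal match > del > ins.
align_dp <- function(means, ref, table, variant, keep_matrix) {
  m <- length(means)
  n <- length(ref$kmers)
  if (m < 1 || n < 1)
    ps_validation_error("alignment requires at least one mean and one k-mer")
  f <- vapply(ref$kmers, function(s) kmer_score(means, s, table),
              numeric(m))
  f <- matrix(f, nrow = m)               # f[i, j]
  gap <- indel_score(table)
  M <- matrix(-Inf, m + 1, n + 1)
  op <- matrix(NA_integer_, m + 1, n + 1)  # 1 stay, 2 diag, 3 del, 4 ins
  M[1, 1] <- 0
  if (variant == "full") {
    M[1, 1 + seq_len(n)] <- seq_len(n) * gap
    M[1 + seq_len(m), 1] <- seq_len(m) * gap
    op[1, 1 + seq_len(n)] <- 3L
    op[1 + seq_len(m), 1] <- 4L
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- c(stay = M[i, j + 1] + f[i, j],
              diag = M[i, j] + f[i, j],
              del = if (variant == "full") M[i + 1, j] + gap else -Inf,
              ins = if (variant == "full") M[i, j + 1] + gap else -Inf)
      best <- which.max(sc)              # first max wins: priority order
      M[i + 1, j + 1] <- sc[best]
      op[i + 1, j + 1] <- best
    }
  }
  if (variant == "full") {
    end <- c(m + 1, n + 1)
    score <- M[m + 1, n + 1]
  } else {
    j_end <- which.max(M[m + 1, ])
    end <- c(m + 1, j_end)
    score <- M[m + 1, j_end]
  }
  # traceback
  steps <- list()
  i <- end[1]; j <- end[2]
  while (!(i == 1 && j == 1)) {
    o <- op[i, j]
    if (is.na(o))
      ps_validation_error("alignment traceback failed (no admissible path)")
    steps[[length(steps) + 1]] <- switch(o,
      data.frame(op = "stay", i = i - 1L, j = j - 1L),
      data.frame(op = "match", i = i - 1L, j = j - 1L),
      data.frame(op = "del", i = NA_integer_, j = j - 1L),
      data.frame(op = "ins", i = i - 1L, j = NA_integer_))
    if (o == 1L) i <- i - 1L
    else if (o == 2L) { i <- i - 1L; j <- j - 1L }
    else if (o == 3L) j <- j - 1L
    else i <- i - 1L
  }
  path <- do.call(rbind, rev(steps))
  rownames(path) <- NULL
  structure(list(path = path, score = score, variant = variant,
                 M = if (keep_matrix) M, ref = ref),
            class = "alignment")
}

#' Full (global) alignment of block means to the reference k-mer list
#'
#' Dynamic program over the (m+1) x (n+1) score matrix with four moves:
#' diagonal match, k-mer skip (deletion), mean skip (insertion), and a
#' vertical "stay" that aligns another mean to the current k-mer — the
#' many-to-one behaviour by which several base blocks (sub-states) merge into
#' one event. Matches are scored by [kmer_score()], indels by [indel_score()].
#' Traceback starts at (m+1, n+1) and consumes all means and all k-mers.
#'
#' @param means ordered base-block means (pore time order).
#' @param kmers a [ref_kmer_seq()] or character vector of k-mers in pore
#'   order.
#' @param table a [kmer_table()].
#' @param keep_matrix retain the score matrix for diagnostics.
#' @return An `alignment`: list with `path` (data.frame `op`, `i`, `j`),
#'   `score`, `variant`, optional `M`, and the `ref` used.
#' @export
align_full <- function(means, kmers, table, keep_matrix = FALSE) {
  align_dp(means, resolve_ref(kmers, table), table, "full", keep_matrix)
}

#' Partial (prefix) alignment
#'
#' Aligns all means to a prefix of the k-mer list using only diagonal and stay
#' moves (no indels); the traceback starts from the maximum of the last row,
#' which selects the best prefix length.
#'
#' @inheritParams align_full
#' @return An `alignment` with `variant = "partial"`.
#' @export
align_partial <- function(means, kmers, table, keep_matrix = FALSE) {
  align_dp(means, resolve_ref(kmers, table), table, "partial", keep_matrix)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %d steps, score %.3f\n", x$variant,
              nrow(x$path), x$score))
  invisible(x)
}

#' Assemble per-k-mer events from an alignment
#'
#' All base blocks aligned to the same k-mer are merged into one event. The
#' event mean is the length-weighted mean of the member blocks; the event std
#' is pooled over member blocks by the combined-moments identity (equivalent
#' to the std of the concatenated member samples). Samples inside intervening
#' transition blocks are excluded; k-mers hit only by deletion steps yield no
#' event. Event dwell is the total number of contributing samples.
#'
#' @param alignment an [align_full()] / [align_partial()] result.
#' @param segmentation the [segment_signal()] result whose base-block means
#'   were aligned.
#' @param signal optional raw samples of the read (whole-read coordinates);
#'   when supplied, each event carries its member samples for benchmarking.
#' @param read_id read identifier.
#' @return data.frame with columns `contig`, `position`, `reference_kmer`,
#'   `read_name`, `event_level_mean`, `event_stdv`, `event_length` (dwell,
#'   samples), `start_idx`, `end_idx`, `model_kmer`, ordered by reference
#'   position; attribute `samples` holds the per-event sample list when
#'   `signal` is given.
#' @export
assemble_events <- function(alignment, segmentation, signal = NULL,
                            read_id = segmentation$read_id) {
  blocks <- segmentation$blocks
  b <- blocks[blocks$label == "B", , drop = FALSE]
  m <- nrow(b)
  path <- alignment$path
  used <- path[path$op %in% c("match", "stay"), , drop = FALSE]
  if (nrow(used) > 0 && max(used$i) > m)
    ps_stop("alignment refers to more means than the segmentation has base blocks",
            "poreseg_internal_error")
  ref <- alignment$ref
  out <- list()
  samples_list <- list()
  for (j in sort(unique(used$j))) {
    ii <- used$i[used$j == j]
    nb <- b[ii, , drop = FALSE]
    N <- sum(nb$n)
    gm <- sum(nb$n * nb$mean) / N
    ss <- sum((nb$n - 1) * nb$std^2 + nb$n * nb$mean^2)
    v <- if (N > 1) (ss - N * gm^2) / (N - 1) else 0
    out[[length(out) + 1]] <- data.frame(
      contig = ref$reference_id, position = ref$positions[j],
      reference_kmer = ref$kmers[j], read_name = read_id,
      event_level_mean = gm, event_stdv = sqrt(max(v, 0)),
      event_length = N, start_idx = min(nb$start), end_idx = max(nb$end),
      model_kmer = ref$kmers[j], stringsAsFactors = FALSE)
    if (!is.null(signal))
      samples_list[[length(samples_list) + 1]] <-
        unlist(lapply(seq_len(nrow(nb)), function(r)
          signal[(nb$start[r] + 1):nb$end[r]]), use.names = FALSE)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(contig = character(0), position = integer(0),
                     reference_kmer = character(0), read_name = character(0),
                     event_level_mean = numeric(0), event_stdv = numeric(0),
                     event_length = integer(0), start_idx = integer(0),
                     end_idx = integer(0), model_kmer = character(0))
  ord <- order(ev$position)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  if (!is.null(signal) && length(samples_list) > 0)
    attr(ev, "samples") <- samples_list[ord]
  ev
}

#' Per-position 9-component feature vector
#'
#' For one read's events, returns the feature vector
#' (mu, sigma, dwell) of the events at positions `position - 1`, `position`,
#' `position + 1`, in that order — the inputs downstream neural m6A callers
#' consume. A missing flanking event makes the feature unavailable.
#'
#' @param events one read's events (from [assemble_events()]).
#' @param position central reference position (k-mer start, 0-based).
#' @return Named numeric vector of length 9 with attribute
#'   `available = TRUE`, or a vector of `NA`s with `available = FALSE`.
#' @export
m6anet_features <- function(events, position) {
  idx <- match(position + c(-1L, 0L, 1L), events$position)
  if (anyNA(idx)) {
    out <- rep(NA_real_, 9)
    names(out) <- feature_names()
    attr(out, "available") <- FALSE
    return(out)
  }
  out <- as.vector(rbind(events$event_level_mean[idx],
                         events$event_stdv[idx],
                         events$event_length[idx]))
  names(out) <- feature_names()
  attr(out, "available") <- TRUE
  out
}

feature_names <- function() {
  as.vector(outer(c("mu", "sigma", "dwell"), c("m1", "0", "p1"),
                  function(a, b) paste0(a, "_", b)))
}

#' Feature matrix across reads at one position
#'
#' @param events events of many reads (one data.frame).
#' @param position central reference position.
#' @return Numeric matrix, one row per read having all three events, with
#'   `read_name` rownames.
#' @export
m6anet_feature_matrix <- function(events, position) {
  rows <- list()
  for (rn in unique(events$read_name)) {
    e <- events[events$read_name == rn, , drop = FALSE]
    v <- m6anet_features(e, position)
    if (isTRUE(attr(v, "available")))
      rows[[rn]] <- v
  }
  if (length(rows) == 0)
    return(matrix(numeric(0), 0, 9, dimnames = list(NULL, feature_names())))
  do.call(rbind, rows)
}

#' Write / read eventalign-style TSV
#'
#' Tab-separated with columns `contig`, `position`, `reference_kmer`,
#' `read_name`, `event_level_mean`, `event_stdv`, `event_length`,
#' `start_idx`, `end_idx`, `model_kmer`. Floats carry six decimals, so a
#' write/read round trip is the identity at that precision. `event_length` is
#' a dwell in raw samples (not seconds).
#'
#' @param events events data.frame.
#' @param path file path.
#' @return `write_eventalign()` returns `path` invisibly; `read_eventalign()`
#'   the events data.frame.
#' @export
write_eventalign <- function(events, path) {
  df <- events[, c("contig", "position", "reference_kmer", "read_name",
                   "event_level_mean", "event_stdv", "event_length",
                   "start_idx", "end_idx", "model_kmer")]
  df$event_level_mean <- sprintf("%.6f", df$event_level_mean)
  df$event_stdv <- sprintf("%.6f", df$event_stdv)
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e)
      ps_io_error(paste0("cannot write eventalign TSV to ", path, ": ",
                         conditionMessage(e))))
  invisible(path)
}

#' @rdname write_eventalign
#' @export
read_eventalign <- function(path) {
  if (!file.exists(path))
    ps_io_error(paste0("eventalign file not found: ", path))
  read.delim(path, stringsAsFactors = FALSE)
}
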