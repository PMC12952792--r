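#' Construct a read record
#'
#' A `read_record` holds one read's raw current samples plus the sample-index
#' intervals of its poly(A) tail and transcript region (0-based, half-open,
#' poly(A) preceding the transcript region in sample order).
#'
#' @param read_id read identifier.
#' @param signal numeric vector of current samples (pA).
#' @param polya_interval length-2 integer vector `c(start, end)` or `NULL`.
#' @param transcript_interval length-2 integer vector; defaults to everything
#'   after the poly(A) tail.
#' @param reference_id optional reference identifier.
#' @return A `read_record`.
#' @export
read_record <- function(read_id, signal, polya_interval = NULL,
                        transcript_interval = NULL, reference_id = NA) {
  n <- length(signal)
  if (!is.null(polya_interval)) {
    if (polya_interval[1] < 0 || polya_interval[2] > n ||
        polya_interval[1] >= polya_interval[2])
      ps_validation_error("polya_interval out of range")
  }
  if (is.null(transcript_interval))
    transcript_interval <- c(if (is.null(polya_interval)) 0L
                             else polya_interval[2], n)
  if (transcript_interval[1] < 0 || transcript_interval[2] > n)
    ps_validation_error("transcript_interval out of range")
  if (!is.null(polya_interval) &&
      polya_interval[2] > transcript_interval[1])
    ps_validation_error("poly(A) interval must precede the transcript region")
  structure(list(read_id = read_id, signal = signal,
                 reference_id = reference_id,
                 polya_interval = polya_interval,
                 transcript_interval = transcript_interval),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("read %s: %d samples, poly(A) [%s), transcript [%d, %d)\n",
              x$read_id, length(x$signal),
              if (is.null(x$polya_interval)) "absent"
              else paste(x$polya_interval, collapse = ", "),
              x$transcript_interval[1], x$transcript_interval[2]))
  invisible(x)
}

#' Poly(A)-anchored signal standardization
#'
#' Pore-to-pore variability shifts and scales the current baseline between
#' reads. The poly(A) tail is a homopolymer stretch present on every mRNA read,
#' so its signal gives a per-read anchor: the whole read is transformed
#' affinely (`a * y + b`, `a > 0`) so that the poly(A) segment attains the
#' target mean and standard deviation. After standardization, k-mer baselines
#' are comparable across reads and to the pore-model table.
#'
#' @param read a [read_record()] with a poly(A) interval of at least 30
#'   samples.
#' @param target_mu,target_sigma target mean/std (pA) of the transformed
#'   poly(A) segment; see [default_targets()].
#' @return The read with transformed `signal`; attributes `scale` and `offset`
#'   record the applied map.
#' @export
standardize_read <- function(read, target_mu, target_sigma) {
  if (is.null(read$polya_interval))
    ps_validation_error(paste0("unstandardizable read (no poly(A) interval): ",
                               read$read_id))
  iv <- read$polya_interval
  if (iv[2] - iv[1] < 30)
    ps_validation_error(paste0("poly(A) interval has fewer than 30 samples: ",
                               read$read_id))
  pa <- read$signal[(iv[1] + 1):iv[2]]
  s <- sd(pa)
  if (!is.finite(s) || s <= 0)
    ps_validation_error(paste0("zero poly(A) variance, cannot standardize: ",
                               read$read_id))
  a <- target_sigma / s
  b <- target_mu - a * mean(pa)
  read$signal <- a * read$signal + b
  attr(read, "scale") <- a
  attr(read, "offset") <- b
  read
}

#' Default standardization targets from a pore-model table
#'
#' The poly(A) segment is, to the pore, a run of the all-A k-mer; its tabulated
#' baseline is therefore the natural standardization target, which puts reads
#' on the same pA scale as the table.
#'
#' @param table a [kmer_table()] containing the all-A k-mer.
#' @return `c(target_mu, target_sigma)`.
#' @export
default_targets <- function(table) {
  km <- strrep("A", table_k(table))
  if (!km %in% rownames(table))
    ps_validation_error(paste0("table lacks the all-A k-mer ", km,
                               " needed for standardization targets"))
  p <- lookup_kmer(table, km)
  c(target_mu = p$mu_un, target_sigma = p$sigma_un)
}

#' Heuristic poly(A) detector (fallback)
#'
#' Marked heuristic: finds the longest run (>= `min_len` samples) whose rolling
#' standard deviation stays below `sd_max`, scanning from the start of the
#' read. Intended only for inputs lacking an external poly(A) annotation; the
#' principled route is to supply annotated intervals.
#'
#' @param signal numeric current samples.
#' @param min_len minimum run length in samples.
#' @param sd_max rolling-std ceiling (pA).
#' @param window rolling window size.
#' @return `c(start, end)` 0-based half-open, or `NULL` if nothing qualifies.
#' @export
detect_polya <- function(signal, min_len = 200L, sd_max = 4, window = 25L) {
  n <- length(signal)
  if (n < min_len) return(NULL)
  nw <- n - window + 1L
  cs <- cumsum(c(0, signal))
  cs2 <- cumsum(c(0, signal^2))
  m <- (cs[(window + 1):(n + 1)] - cs[1:nw]) / window
  v <- (cs2[(window + 1):(n + 1)] - cs2[1:nw]) / window - m^2
  flat <- sqrt(pmax(v, 0)) < sd_max
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (i in which(r$values)) {
    len <- r$lengths[i] + window - 1L
    if (len >= min_len && (is.null(best) || len > best[2] - best[1]))
      best <- c(starts[i] - 1L, starts[i] - 1L + len)
  }
  best
}
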