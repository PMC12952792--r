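#' Simulation configuration
#'
#' Configures the jiggling-translocation signal generator. Within a base block
#' each raw sample is independently emitted from the current k-mer's baseline,
#' the previous or next k-mer's baseline (transient back/forward translocation
#' by about one nucleotide), or a uniform noise floor. Consecutive base blocks
#' are joined by short, steep linear transition ramps. A poly(A) tail segment
#' precedes the transcript region.
#'
#' @param table a [kmer_table()] providing per-k-mer baselines (and
#'   modification parameters when `mod_rate > 0`).
#' @param p_prev,p_next per-sample probability of an excursion to the
#'   previous/next k-mer baseline.
#' @param p_noise per-sample probability of a uniform noise sample.
#' @param dwell_mean expected number of samples per base block (>= 3).
#' @param n_blocks_per_kmer_max a k-mer may emit up to this many base blocks
#'   (sub-states); the number is uniform on `1..n_blocks_per_kmer_max`.
#' @param trans_len_range integer range of transition-block lengths, within
#'   \[1, 20\].
#' @param trans_residual_sd Gaussian residual std around transition ramps (pA).
#' @param noise_range pA interval for uniform noise samples; defaults to the
#'   table's level range widened by 5 pA on each side.
#' @param run_excursions if `TRUE`, excursions occur in geometric runs
#'   (expected length 2) instead of i.i.d. per sample.
#' @param polya_len number of poly(A)-tail samples prepended to each read.
#'   Tails of a few thousand samples are typical of real reads; short tails
#'   inflate the per-read standardization error.
#' @param drift_sd,offset_sd per-read affine pore drift: the whole read is
#'   multiplied by `N(1, drift_sd)` and shifted by `N(0, offset_sd)` pA
#'   (removed downstream by poly(A) standardization).
#' @param mod_rate probability that a DRACH centre A is modified (per read and
#'   site).
#' @param seed master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(table,
                       p_prev = 0.05, p_next = 0.05, p_noise = 0.01,
                       dwell_mean = 30, n_blocks_per_kmer_max = 1,
                       trans_len_range = c(4, 8), trans_residual_sd = 1,
                       noise_range = NULL, run_excursions = FALSE,
                       polya_len = 2000, drift_sd = 0.02, offset_sd = 2,
                       mod_rate = 0, seed = 1L) {
  if (!inherits(table, "kmer_table"))
    ps_validation_error("sim_config(): `table` must be a kmer_table")
  if (p_prev < 0 || p_next < 0 || p_noise < 0 ||
      p_prev + p_next + p_noise >= 1)
    ps_validation_error("excursion probabilities must be >= 0 and sum to < 1")
  if (dwell_mean < 3)
    ps_validation_error("dwell_mean must be >= 3")
  trans_len_range <- as.integer(round(trans_len_range))
  if (length(trans_len_range) != 2 || trans_len_range[1] > trans_len_range[2] ||
      trans_len_range[1] < 1 || trans_len_range[2] > 20)
    ps_validation_error("trans_len_range must be an increasing interval within [1, 20]")
  if (n_blocks_per_kmer_max < 1)
    ps_validation_error("n_blocks_per_kmer_max must be >= 1")
  if (mod_rate < 0 || mod_rate > 1)
    ps_validation_error("mod_rate must lie in [0, 1]")
  if (is.null(noise_range))
    noise_range <- c(min(table$mu_un) - 5, max(table$mu_un) + 5)
  structure(list(
    table = table, p_prev = p_prev, p_next = p_next, p_noise = p_noise,
    dwell_mean = dwell_mean, n_blocks_per_kmer_max = n_blocks_per_kmer_max,
    trans_len_range = trans_len_range, trans_residual_sd = trans_residual_sd,
    noise_range = noise_range, run_excursions = run_excursions,
    polya_len = as.integer(polya_len), drift_sd = drift_sd,
    offset_sd = offset_sd, mod_rate = mod_rate,
    seed = as.integer(seed)), class = "sim_config")
}

normalize_reference <- function(reference) {
  reference <- toupper(reference)
  reference <- gsub("U", "T", reference, fixed = TRUE)
  if (grepl("[^ACGT]", reference))
    ps_validation_error("reference contains symbols outside {A,C,G,T,U}")
  reference
}

# k-mer strings of `reference` in pore-traversal order (3'->5'): the 3'-most
# k-mer enters the pore first, so the time order is the reverse of the 5'->3'
# positional order. `positions` are 0-based starts in reference coordinates.
pore_order_kmers <- function(reference, k) {
  L <- nchar(reference)
  if (L < k)
    ps_validation_error("reference shorter than k")
  starts <- seq(L - k + 1, 1)            # 1-based, 3' -> 5'
  list(kmers = substring(reference, starts, starts + k - 1),
       positions = starts - 1L)
}

#' Simulate one direct-RNA read
#'
#' Generates the raw current trace of one read under the jiggling translocation
#' model together with complete ground truth: block boundaries, per-sample
#' hidden states, and per-site modification labels.
#'
#' @param reference reference transcript sequence (5'->3'; U allowed).
#' @param config a [sim_config()].
#' @param read_id identifier stored in the output.
#' @param reference_id identifier of the reference.
#' @param seed per-read seed; defaults to `config$seed`.
#' @return A `sim_read` (also a `read_record`): list with `read_id`, `signal`,
#'   `reference_id`, `truth_blocks` (data.frame `start`, `end`, `label`,
#'   `kmer_index`, `kmer`; 0-based half-open sample intervals), `truth_states`
#'   (per-sample labels), `truth_mods` (per-reference-position logical),
#'   `polya_interval` and `transcript_interval` (0-based half-open).
#' @export
simulate_read <- function(reference, config, read_id = "read_1",
                          reference_id = "ref_1", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  table <- config$table
  k <- table_k(table)
  reference <- normalize_reference(reference)
  po <- pore_order_kmers(reference, k)
  missing <- setdiff(unique(po$kmers), rownames(table))
  if (length(missing) > 0)
    ps_validation_error(paste0("k-mer(s) of the reference missing from table: ",
                               paste(missing, collapse = ", ")))
  set.seed(if (is.null(seed)) config$seed else seed)

  L <- nchar(reference)
  centre_off <- (k - 1L) %/% 2L          # centre base offset inside a k-mer
  # per-site modification truth: DRACH centres only (k = 5)
  truth_mods <- rep(FALSE, L)
  if (config$mod_rate > 0) {
    if (k != 5)
      ps_validation_error("modification simulation requires k = 5 (DRACH)")
    drach <- is_drach(po$kmers)
    centres <- po$positions + centre_off          # 0-based centre positions
    for (t in which(drach)) {
      km <- lookup_kmer(table, po$kmers[t])
      if (!km$mod_enabled)
        ps_validation_error(paste0(
          "mod_rate > 0 but DRACH k-mer lacks modification parameters: ",
          po$kmers[t]))
      truth_mods[centres[t] + 1L] <- runif(1) < config$mod_rate
    }
  }

  n_kmers <- length(po$kmers)
  params <- table[po$kmers, , drop = FALSE]
  centres1 <- po$positions + centre_off + 1L      # 1-based centre positions
  use_mod <- params$mod_enabled & truth_mods[centres1]
  mu_eff <- ifelse(use_mod, params$mu_mod, params$mu_un)
  sd_eff <- ifelse(use_mod, params$sigma_mod, params$sigma_un)

  p_curr <- 1 - config$p_prev - config$p_next - config$p_noise
  states4 <- c("prev", "curr", "next", "noise")

  polya <- numeric(0)
  if (config$polya_len > 0) {
    aa <- lookup_kmer(table, strrep("A", k))
    polya <- rnorm(config$polya_len, aa$mu_un, aa$sigma_un)
  }

  sig_parts <- list(polya)
  state_parts <- list(rep("polyA", length(polya)))
  blk <- list()
  prev_block_mu <- NA_real_
  cursor <- length(polya)

  draw_states <- function(n, probs) {
    if (!config$run_excursions)
      return(sample(states4, n, replace = TRUE, prob = probs))
    # geometric runs (expected length 2) for excursion states
    out <- character(0)
    while (length(out) < n) {
      s <- sample(states4, 1, prob = probs)
      len <- if (s %in% c("prev", "next")) rgeom_run() else 1L
      out <- c(out, rep(s, len))
    }
    out[seq_len(n)]
  }

  for (t in seq_len(n_kmers)) {
    probs <- c(config$p_prev, p_curr, config$p_next, config$p_noise)
    if (t == 1) { probs[2] <- probs[2] + probs[1]; probs[1] <- 0 }
    if (t == n_kmers) { probs[2] <- probs[2] + probs[3]; probs[3] <- 0 }
    n_blocks <- sample.int(config$n_blocks_per_kmer_max, 1)
    for (b in seq_len(n_blocks)) {
      # transition ramp joining the previous base block to this one
      if (!is.na(prev_block_mu)) {
        tl <- sample(seq(config$trans_len_range[1], config$trans_len_range[2]), 1)
        ramp <- seq(prev_block_mu, mu_eff[t], length.out = tl + 2)[2:(tl + 1)]
        tr <- ramp + rnorm(tl, 0, config$trans_residual_sd)
        sig_parts[[length(sig_parts) + 1]] <- tr
        state_parts[[length(state_parts) + 1]] <- rep("transition", tl)
        blk[[length(blk) + 1]] <- list(start = cursor, end = cursor + tl,
                                       label = "T", kmer_index = NA_integer_,
                                       kmer = NA_character_)
        cursor <- cursor + tl
      }
      dwell <- 3L + rpois(1, config$dwell_mean - 3)
      st <- draw_states(dwell, probs)
      vals <- numeric(dwell)
      for (s in states4) {
        idx <- which(st == s)
        if (length(idx) == 0) next
        vals[idx] <- switch(s,
          prev  = rnorm(length(idx), mu_eff[t - 1], sd_eff[t - 1]),
          curr  = rnorm(length(idx), mu_eff[t], sd_eff[t]),
          "next" = rnorm(length(idx), mu_eff[t + 1], sd_eff[t + 1]),
          noise = runif(length(idx), config$noise_range[1], config$noise_range[2]))
      }
      sig_parts[[length(sig_parts) + 1]] <- vals
      state_parts[[length(state_parts) + 1]] <- st
      blk[[length(blk) + 1]] <- list(start = cursor, end = cursor + dwell,
                                     label = "B", kmer_index = t,
                                     kmer = po$kmers[t])
      cursor <- cursor + dwell
      prev_block_mu <- mu_eff[t]
    }
  }

  signal <- unlist(sig_parts, use.names = FALSE)
  # per-read pore drift, removed later by poly(A) standardization
  drift <- max(rnorm(1, 1, config$drift_sd), 0.5)
  signal <- drift * signal + rnorm(1, 0, config$offset_sd)
  truth_blocks <- do.call(rbind, lapply(blk, function(b)
    data.frame(start = b$start, end = b$end, label = b$label,
               kmer_index = b$kmer_index, kmer = b$kmer,
               stringsAsFactors = FALSE)))
  structure(list(
    read_id = read_id, signal = signal, reference_id = reference_id,
    truth_blocks = truth_blocks,
    truth_states = unlist(state_parts, use.names = FALSE),
    truth_mods = truth_mods,
    polya_interval = c(0L, length(polya)),
    transcript_interval = c(length(polya), length(signal))),
    class = c("sim_read", "read_record"))
}

rgeom_run <- function() 1L + rgeom(1, 0.5)

#' @importFrom stats rgeom
NULL

#' @export
print.sim_read <- function(x, ...) {
  cat(sprintf("simulated read %s on %s: %d samples (%d poly(A)), %d blocks, %d modified site(s)\n",
              x$read_id, x$reference_id, length(x$signal),
              diff(x$polya_interval), nrow(x$truth_blocks), sum(x$truth_mods)))
  invisible(x)
}

#' Simulate a read set with ground truth
#'
#' @param references named character vector of reference sequences, or the path
#'   to a FASTA file.
#' @param n_reads number of reads; references are assigned round-robin.
#' @param config a [sim_config()]; per-read seeds are derived deterministically
#'   from `config$seed`.
#' @param dir optional output directory; when given, the signal container and
#'   ground-truth TSVs are written there (see [write_signal_container()]).
#' @return List with `reads` (list of `sim_read`) and `manifest` (data.frame).
#' @export
simulate_dataset <- function(references, n_reads, config, dir = NULL) {
  if (is.character(references) && length(references) == 1 &&
      file.exists(references))
    references <- read_fasta(references)
  if (length(references) == 0)
    ps_validation_error("no reference sequences supplied")
  if (n_reads < 1)
    ps_validation_error("n_reads must be >= 1")
  if (is.null(names(references)))
    names(references) <- paste0("ref_", seq_along(references))
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    ri <- ((i - 1) %% length(references)) + 1
    reads[[i]] <- simulate_read(
      references[[ri]], config,
      read_id = sprintf("read_%04d", i),
      reference_id = names(references)[ri],
      seed = derive_seed(config$seed, i))
  }
  manifest <- do.call(rbind, lapply(reads, function(r)
    data.frame(read_id = r$read_id, reference_id = r$reference_id,
               polya_start = r$polya_interval[1], polya_end = r$polya_interval[2],
               transcript_start = r$transcript_interval[1],
               transcript_end = r$transcript_interval[2],
               n_samples = length(r$signal), stringsAsFactors = FALSE)))
  if (!is.null(dir))
    write_signal_container(reads, dir)
  list(reads = reads, manifest = manifest)
}

#' Random reference under the sharp-step assumption
#'
#' Draws a random transcript sequence whose consecutive k-mers all differ in
#' baseline by at least `min_step` pA — under every modification state the
#' table defines for them, so a modified site remains separated from its
#' neighbours. The segmentation model assumes a sharp current change between
#' consecutive k-mers; this generator produces references on which block
#' boundaries are identifiable in principle. Optionally splices a fixed motif
#' (e.g. a DRACH 5-mer context) into the sequence while preserving the step
#' constraint.
#'
#' @param table a [kmer_table()].
#' @param length sequence length in nucleotides.
#' @param min_step minimum |baseline difference| between consecutive k-mers
#'   (pA).
#' @param include optional subsequence that must appear.
#' @param seed integer seed.
#' @param max_tries restart budget.
#' @return A reference sequence string.
#' @export
random_reference <- function(table, length, min_step = 5, include = NULL,
                             seed = 1L, max_tries = 500L) {
  k <- table_k(table)
  if (length < k)
    ps_validation_error("reference length must be >= k")
  if (!is.null(include)) {
    include <- normalize_reference(include)
    if (nchar(include) > length)
      ps_validation_error("`include` longer than the requested reference")
  }
  set.seed(seed)
  # per-k-mer level sets: the unmodified baseline plus the modified one where
  # defined; consecutive k-mers must be separated under every state pairing
  levels <- lapply(seq_len(nrow(table)), function(i)
    c(table$mu_un[i], if (table$mod_enabled[i]) table$mu_mod[i]))
  names(levels) <- rownames(table)
  sep_ok <- function(a, b)
    min(abs(outer(levels[[a]], levels[[b]], "-"))) >= min_step
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    seqv <- sample(bases, k, replace = TRUE)
    ok <- TRUE
    while (base::length(seqv) < length) {
      cur <- paste0(seqv[(base::length(seqv) - k + 1):base::length(seqv)],
                    collapse = "")
      cand <- sample(bases)
      placed <- FALSE
      for (b in cand) {
        nxt <- paste0(substr(cur, 2, k), b)
        if (sep_ok(cur, nxt)) {
          seqv <- c(seqv, b); placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    s <- paste0(seqv, collapse = "")
    if (is.null(include)) return(s)
    if (grepl(include, s, fixed = TRUE)) return(s)
    # try splicing the motif at a random admissible position
    for (p in sample(seq_len(length - nchar(include) + 1))) {
      cand_s <- paste0(substr(s, 1, p - 1), include,
                       substr(s, p + nchar(include), length))
      if (steps_ok(cand_s, sep_ok, k)) return(cand_s)
    }
  }
  ps_validation_error(
    "random_reference(): could not satisfy the step constraint; lower min_step")
}

steps_ok <- function(s, sep_ok, k) {
  n <- nchar(s) - k + 1
  kms <- substring(s, seq_len(n), seq_len(n) + k - 1)
  all(vapply(seq_len(n - 1), function(i) sep_ok(kms[i], kms[i + 1]),
             logical(1)))
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (U normalized to T).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    ps_io_error(paste0("FASTA file not found: ", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0)
    ps_validation_error(paste0("FASTA file is empty: ", path))
  out <- vapply(as.character(x), normalize_reference, character(1))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
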