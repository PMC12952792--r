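#' Plain-text signal container
#'
#' Reads are exchanged on disk as a directory of plain-text files (container
#' format version 1):
#' \itemize{
#'   \item `container.json` — format version and writer version.
#'   \item `manifest.tsv` — `read_id`, `reference_id`, `polya_start`,
#'     `polya_end`, `transcript_start`, `transcript_end`, `n_samples`
#'     (0-based half-open sample intervals).
#'   \item `signals.tsv` — `read_id` and the space-separated current samples
#'     (pA) of that read, one row per read.
#'   \item `truth_blocks.tsv`, `truth_mods.tsv` — ground truth, present only
#'     for simulated data.
#' }
#'
#' @param reads list of `read_record` / `sim_read` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_signal_container <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(format = "poreseg-signal-container", version = 1L,
         writer = as.character(utils::packageVersion("poreseg"))),
    file.path(dir, "container.json"), auto_unbox = TRUE)
  manifest <- do.call(rbind, lapply(reads, function(r)
    data.frame(read_id = r$read_id,
               reference_id = r$reference_id %||% NA_character_,
               polya_start = r$polya_interval[1],
               polya_end = r$polya_interval[2],
               transcript_start = r$transcript_interval[1],
               transcript_end = r$transcript_interval[2],
               n_samples = length(r$signal), stringsAsFactors = FALSE)))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "signals.tsv"), "w")
  on.exit(close(con))
  writeLines("read_id\tsamples", con)
  for (r in reads)
    writeLines(paste0(r$read_id, "\t",
                      paste(sprintf("%.4f", r$signal), collapse = " ")), con)
  has_truth <- all(vapply(reads, function(r)
    !is.null(r$truth_blocks) &&
      (!is.null(r[["truth_mods"]]) || !is.null(r$truth_mods_positions)), TRUE))
  if (has_truth) {
    tb <- do.call(rbind, lapply(reads, function(r)
      cbind(read_id = r$read_id, r$truth_blocks)))
    write.table(tb, file.path(dir, "truth_blocks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tm <- do.call(rbind, lapply(reads, function(r) {
      # [[ avoids partial matching against truth_mods_positions
      pos <- if (!is.null(r[["truth_mods"]])) which(r[["truth_mods"]]) - 1L
             else as.integer(r$truth_mods_positions)
      data.frame(read_id = rep(r$read_id, length(pos)),
                 reference_id = rep(r$reference_id, length(pos)),
                 position = pos, stringsAsFactors = FALSE)
    }))
    if (is.null(tm) || nrow(tm) == 0)
      tm <- data.frame(read_id = character(0), reference_id = character(0),
                       position = integer(0))
    write.table(tm, file.path(dir, "truth_mods.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_signal_container
#' @return `read_signal_container()` returns a list of `read_record` objects
#'   (with truth fields when present in the container).
#' @export
read_signal_container <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  sf <- file.path(dir, "signals.tsv")
  if (!file.exists(mf) || !file.exists(sf))
    ps_io_error(paste0("not a signal container (missing manifest/signals): ", dir))
  manifest <- read.delim(mf, stringsAsFactors = FALSE)
  lines <- readLines(sf)[-1]
  sig <- lapply(strsplit(lines, "\t", fixed = TRUE), function(p)
    as.numeric(strsplit(p[2], " ", fixed = TRUE)[[1]]))
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  names(sig) <- ids
  tbf <- file.path(dir, "truth_blocks.tsv")
  truth_blocks <- if (file.exists(tbf)) read.delim(tbf, stringsAsFactors = FALSE)
  tmf <- file.path(dir, "truth_mods.tsv")
  truth_mods <- if (file.exists(tmf)) read.delim(tmf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    r <- list(read_id = m$read_id, signal = sig[[m$read_id]],
              reference_id = m$reference_id,
              polya_interval = c(m$polya_start, m$polya_end),
              transcript_interval = c(m$transcript_start, m$transcript_end))
    if (!is.null(truth_blocks)) {
      r$truth_blocks <- truth_blocks[truth_blocks$read_id == m$read_id,
                                     -1, drop = FALSE]
      rownames(r$truth_blocks) <- NULL
      r$truth_mods_positions <-
        truth_mods$position[truth_mods$read_id == m$read_id]
    }
    structure(r, class = "read_record")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
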