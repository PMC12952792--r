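#' k-mer pore-model parameter tables
#'
#' A k-mer table stores, for every k-mer, the Gaussian current baseline of the
#' unmodified state (`mu_un`, `sigma_un`, in pA) and optionally of the modified
#' state (`mu_mod`, `sigma_mod`) together with mixture weights (`omega_un`,
#' `omega_mod`). ONT pore-model files provide only the unmodified baseline;
#' modification parameters are added by [reestimate_table()] or
#' [enable_modification()].
#'
#' @param entries data.frame with columns `kmer`, `mu_un`, `sigma_un`,
#'   `mu_mod`, `sigma_mod`, `omega_un`, `omega_mod`, `mod_enabled`.
#' @return An object of class `kmer_table`: the entries data.frame with an
#'   attribute `k` (k-mer length).
#' @export
kmer_table <- function(entries) {
  required <- c("kmer", "mu_un", "sigma_un", "mu_mod", "sigma_mod",
                "omega_un", "omega_mod", "mod_enabled")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0)
    ps_format_error(paste0("k-mer table is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  entries$kmer <- normalize_kmer(entries$kmer)
  lens <- unique(nchar(entries$kmer))
  if (length(lens) != 1)
    ps_validation_error("inconsistent k-mer lengths in table")
  if (anyDuplicated(entries$kmer))
    ps_validation_error("duplicate k-mers in table")
  if (any(!is.finite(entries$sigma_un)) || any(entries$sigma_un <= 0))
    ps_validation_error("sigma_un must be > 0 for all k-mers")
  mod <- entries$mod_enabled
  if (any(mod)) {
    if (any(!is.finite(entries$sigma_mod[mod])) ||
        any(entries$sigma_mod[mod] <= 0))
      ps_validation_error("sigma_mod must be > 0 for mod-enabled k-mers")
    bad <- abs(entries$omega_un[mod] + entries$omega_mod[mod] - 1) > 1e-9
    if (any(bad))
      ps_validation_error(paste0(
        "omega_un + omega_mod must equal 1 for mod-enabled k-mers: ",
        paste(entries$kmer[mod][bad], collapse = ", ")))
  }
  if (any(abs(entries$omega_un[!mod] - 1) > 1e-9))
    ps_validation_error("omega_un must be 1 for k-mers without modification")
  entries <- entries[order(entries$kmer), , drop = FALSE]
  rownames(entries) <- entries$kmer
  structure(entries, k = lens, class = c("kmer_table", "data.frame"))
}

# Uppercase + RNA->DNA alphabet (U becomes T) at every ingestion point.
normalize_kmer <- function(kmer) {
  kmer <- toupper(kmer)
  gsub("U", "T", kmer, fixed = TRUE)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("k-mer table: k = %d, %d entries, %d with modification parameters\n",
              attr(x, "k"), nrow(x), sum(x$mod_enabled)))
  cat(sprintf("unmodified level range: %.1f - %.1f pA\n",
              min(x$mu_un), max(x$mu_un)))
  invisible(x)
}

#' @rdname kmer_table
#' @param table a `kmer_table`.
#' @export
table_k <- function(table) attr(table, "k")

#' Look up the parameters of one k-mer
#'
#' @param table a [kmer_table()].
#' @param kmer k-mer string (U is normalized to T).
#' @return One-row data.frame of parameters.
#' @export
lookup_kmer <- function(table, kmer) {
  kmer <- normalize_kmer(kmer)
  idx <- match(kmer, rownames(table))
  if (is.na(idx))
    ps_validation_error(paste0("k-mer not present in table: ", kmer))
  table[idx, , drop = FALSE]
}

#' Load an ONT-dialect pore-model table
#'
#' Reads a tab-separated pore-model file with header columns `kmer`,
#' `level_mean` and `level_stdv` (extra columns are ignored) into a
#' [kmer_table()] with no modification parameters.
#'
#' @param path path to the TSV file.
#' @return A `kmer_table` with `mod_enabled = FALSE` and `omega_un = 1`
#'   everywhere.
#' @export
load_ont_table <- function(path) {
  if (!file.exists(path))
    ps_io_error(paste0("pore-model file not found: ", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("kmer", "level_mean", "level_stdv")) {
    if (!col %in% names(df))
      ps_format_error(paste0("pore-model file ", path,
                             " lacks required column '", col, "'"))
  }
  n <- nrow(df)
  kmer_table(data.frame(
    kmer = df$kmer,
    mu_un = as.numeric(df$level_mean),
    sigma_un = as.numeric(df$level_stdv),
    mu_mod = rep(NA_real_, n), sigma_mod = rep(NA_real_, n),
    omega_un = rep(1, n), omega_mod = rep(0, n),
    mod_enabled = rep(FALSE, n),
    stringsAsFactors = FALSE))
}

#' Save / load the extended table dialect
#'
#' The extended dialect is a TSV with columns `kmer`, `mu_un`, `sigma_un`,
#' `mu_mod`, `sigma_mod`, `omega_un`, `omega_mod`, `mod_enabled`; modification
#' columns of k-mers without modification parameters are written as `NA`.
#' Floats are written with six decimals, so a save/load round trip is the
#' identity at that precision.
#'
#' @param table a [kmer_table()].
#' @param path output path.
#' @return `save_table()` returns `path` invisibly; `load_table()` returns a
#'   `kmer_table`.
#' @export
save_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- c("mu_un", "sigma_un", "mu_mod", "sigma_mod", "omega_un", "omega_mod")
  for (col in num) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), "NA", sprintf("%.6f", v))
  }
  df$mod_enabled <- ifelse(df$mod_enabled, "TRUE", "FALSE")
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e)
      ps_io_error(paste0("cannot write k-mer table to ", path, ": ",
                         conditionMessage(e))))
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  if (!file.exists(path))
    ps_io_error(paste0("k-mer table file not found: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("kmer", "mu_un", "sigma_un", "mu_mod", "sigma_mod",
                "omega_un", "omega_mod", "mod_enabled")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    ps_format_error(paste0("extended table ", path, " lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  df$mod_enabled <- as.logical(df$mod_enabled)
  kmer_table(df)
}

#' DRACH motif test
#'
#' True iff a 5-mer matches D-R-A-C-H with D in \{A,G,T\}, R in \{A,G\}
#' (purine), the central base A, the fourth base C, and H in \{A,C,T\}.
#' U is accepted and normalized to T.
#'
#' @param kmer character vector of 5-mers.
#' @return Logical vector.
#' @export
is_drach <- function(kmer) {
  kmer <- normalize_kmer(kmer)
  if (any(nchar(kmer) != 5))
    ps_validation_error("is_drach() requires 5-mers")
  if (any(grepl("[^ACGT]", kmer)))
    ps_validation_error("is_drach(): k-mers must be over {A,C,G,T,U}")
  b <- function(i) substr(kmer, i, i)
  b(1) %in% c("A", "G", "T") & b(2) %in% c("A", "G") & b(3) == "A" &
    b(4) == "C" & b(5) %in% c("A", "C", "T")
}

#' All k-mers over the DNA alphabet
#'
#' @param k k-mer length.
#' @return Character vector of all `4^k` k-mers in lexicographic order.
#' @export
all_kmers <- function(k) {
  grids <- rep(list(c("A", "C", "G", "T")), k)
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(g)))
}

#' Synthetic pore-model table
#'
#' Builds a full k-mer table with realistic structure: each base contributes a
#' position-weighted offset to the level (the central position dominating, as
#' in real pore models), plus a small reproducible per-k-mer jitter, centred at
#' 100 pA. Per-k-mer `sigma_un` varies over a realistic 1.5-3 pA range. Intended
#' for simulation and tests; clearly synthetic, not an ONT calibration.
#'
#' @param k k-mer length (only 5 is exercised in the shipped tests).
#' @param seed integer seed controlling the jitter.
#' @return A [kmer_table()].
#' @export
synthetic_kmer_table <- function(k = 5, seed = 1L) {
  kmers <- all_kmers(k)
  codes <- c(A = -1.5, C = -0.5, G = 0.5, T = 1.5)
  centre <- (k + 1) / 2
  w <- 2 + 8 * exp(-(seq_len(k) - centre)^2 / 2)
  mat <- matrix(codes[unlist(strsplit(kmers, ""))], ncol = k, byrow = TRUE)
  structured <- as.vector(mat %*% w)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  jitter <- rnorm(length(kmers), 0, 1.5)
  sigma <- runif(length(kmers), 1.5, 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  n <- length(kmers)
  kmer_table(data.frame(
    kmer = kmers,
    mu_un = 100 + structured + jitter,
    sigma_un = sigma,
    mu_mod = rep(NA_real_, n), sigma_mod = rep(NA_real_, n),
    omega_un = rep(1, n), omega_mod = rep(0, n),
    mod_enabled = rep(FALSE, n),
    stringsAsFactors = FALSE))
}

#' Add modification parameters to selected k-mers
#'
#' Sets `mu_mod = mu_un + delta`, enabling the k-mer for modification calling.
#' Used to construct generating tables for simulations with modified sites.
#'
#' @param table a [kmer_table()].
#' @param kmers k-mers to enable.
#' @param delta baseline shift of the modified state (pA).
#' @param sigma_mod std of the modified state; defaults to the k-mer's
#'   `sigma_un`.
#' @param omega_mod mixture weight of the modified component.
#' @return The updated `kmer_table`.
#' @export
enable_modification <- function(table, kmers, delta = 8, sigma_mod = NULL,
                                omega_mod = 0.5) {
  kmers <- normalize_kmer(kmers)
  idx <- match(kmers, rownames(table))
  if (anyNA(idx))
    ps_validation_error(paste0("k-mer(s) not in table: ",
                               paste(kmers[is.na(idx)], collapse = ", ")))
  df <- as.data.frame(table)
  df$mu_mod[idx] <- df$mu_un[idx] + delta
  df$sigma_mod[idx] <- if (is.null(sigma_mod)) df$sigma_un[idx] else sigma_mod
  df$omega_mod[idx] <- omega_mod
  df$omega_un[idx] <- 1 - omega_mod
  df$mod_enabled[idx] <- TRUE
  kmer_table(df)
}
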