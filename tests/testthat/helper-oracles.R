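# Independent oracles and shared fixtures for the test suite.
# The oracles deliberately avoid the package's own DP/forward code paths:
# they enumerate hidden-state paths / alignment paths exhaustively.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Brute-force inner-HMM marginal: sum over all 4^n hidden-state paths.
# States: 1 prev, 2 curr, 3 next, 4 noise (Gaussian/Gaussian/Gaussian/uniform).
brute_inner_loglik <- function(y, mu3, trans, init, sigma, nb) {
  n <- length(y)
  lem <- matrix(-Inf, n, 4)
  for (s in 1:3)
    lem[, s] <- dnorm(y, mu3[s], sigma, log = TRUE)
  lem[, 4] <- ifelse(y >= nb[1] & y <= nb[2], -log(nb[2] - nb[1]), -Inf)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  lp <- log(init)[paths[, 1]] + lem[cbind(1, paths[, 1])]
  if (n > 1) {
    lt <- log(trans)
    for (t in 2:n)
      lp <- lp + lt[cbind(paths[, t - 1], paths[, t])] +
        lem[cbind(t, paths[, t])]
  }
  log_sum_exp(lp)
}

# Exhaustive full-alignment maximum: plain recursion over all admissible path
# prefixes (match / del / ins / stay), no memoization.
brute_align_full <- function(f, gap) {
  m <- nrow(f); n <- ncol(f)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1) + f[i, j])
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j) + f[i, j])
    best
  }
  rec(m, n)
}

# Exhaustive partial-alignment maximum: all means assigned to a prefix of the
# k-mer list via non-decreasing steps of 0/1 starting at k-mer 1.
brute_align_partial <- function(f) {
  m <- nrow(f); n <- ncol(f)
  rec <- function(i, j) {
    s <- f[i, j]
    if (i == m) return(s)
    best <- rec(i + 1, j)
    if (j < n) best <- max(best, rec(i + 1, j + 1))
    s + best
  }
  rec(1, 1)
}

# Small handcrafted k-mer table with well-separated baselines (k = 2 alphabet
# restricted on purpose is not allowed -- full {A,C,G,T} 5-mers).
tiny_table <- function(kmers = c("AAAAA", "CCCCC", "GGGGG", "TTTTT", "ACGTA"),
                       mus = c(80, 95, 110, 125, 102), sigmas = 2) {
  n <- length(kmers)
  kmer_table(data.frame(
    kmer = kmers, mu_un = mus, sigma_un = rep(sigmas, length.out = n),
    mu_mod = rep(NA_real_, n), sigma_mod = rep(NA_real_, n),
    omega_un = rep(1, n), omega_mod = rep(0, n),
    mod_enabled = rep(FALSE, n), stringsAsFactors = FALSE))
}

# Shared synthetic pore-model table (full 4^5), cached across tests.
shared_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- synthetic_kmer_table()
    tab
  }
})

# Fixture path helper.
extdata <- function(...) {
  system.file("extdata", ..., package = "poreseg", mustWork = TRUE)
}
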