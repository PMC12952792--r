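test_that("excursion-free simulation stays on the current k-mer baseline", {
  tab <- shared_table()
  ref <- random_reference(tab, 15, min_step = 5, seed = 21)
  cfg <- sim_config(tab, p_prev = 0, p_next = 0, p_noise = 0,
                    drift_sd = 0, offset_sd = 0, mod_rate = 0, seed = 3)
  r <- simulate_read(ref, cfg)
  base <- r$truth_blocks[r$truth_blocks$label == "B", ]
  expect_true(all(r$truth_states[(base$start[1] + 1):base$end[1]] == "curr"))
  inner <- r$truth_states[(r$transcript_interval[1] + 1):r$transcript_interval[2]]
  expect_true(all(inner %in% c("curr", "transition")))
  for (i in seq_len(nrow(base))) {
    p <- lookup_kmer(tab, base$kmer[i])
    x <- r$signal[(base$start[i] + 1):base$end[i]]
    expect_lt(abs(mean(x) - p$mu_un), 4 * p$sigma_un / sqrt(length(x)))
  }
})

test_that("identical seeds give bit-identical signals", {
  tab <- shared_table()
  ref <- random_reference(tab, 12, min_step = 5, seed = 4)
  cfg <- sim_config(tab, seed = 99)
  r1 <- simulate_read(ref, cfg)
  r2 <- simulate_read(ref, cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$truth_states, r2$truth_states)
  cfg2 <- sim_config(tab, seed = 100)
  expect_false(identical(simulate_read(ref, cfg2)$signal, r1$signal))
})

test_that("truth blocks alternate B,T,...,B and tile the transcript region", {
  tab <- shared_table()
  cfg <- sim_config(tab, n_blocks_per_kmer_max = 2, seed = 8)
  for (s in 1:5) {
    ref <- random_reference(tab, 10 + s, min_step = 5, seed = 30 + s)
    r <- simulate_read(ref, cfg, seed = s)
    tb <- r$truth_blocks
    expect_equal(tb$label[1], "B")
    expect_equal(tb$label[nrow(tb)], "B")
    expect_true(all(tb$label == rep(c("B", "T"), length.out = nrow(tb))))
    expect_equal(nrow(tb) %% 2, 1)               # 2K+1 blocks
    expect_equal(tb$start[1], r$transcript_interval[1])
    expect_equal(tb$end[nrow(tb)], r$transcript_interval[2])
    expect_true(all(tb$start[-1] == tb$end[-nrow(tb)]))   # no gaps/overlaps
    expect_true(all(tb$end > tb$start))
    # base blocks traverse the pore-order k-mer list without skips
    ki <- tb$kmer_index[tb$label == "B"]
    expect_equal(min(ki), 1)
    expect_equal(max(ki), nchar(ref) - 4)
    expect_true(all(diff(ki) %in% c(0, 1)))
  }
})

test_that("per-state sample fractions match the generating probabilities", {
  tab <- shared_table()
  cfg <- sim_config(tab, p_prev = 0.05, p_next = 0.05, p_noise = 0.01,
                    polya_len = 0, seed = 14)
  states <- character(0)
  s <- 1
  while (length(states) < 1e5) {
    ref <- random_reference(tab, 40, min_step = 5, seed = 400 + s)
    r <- simulate_read(ref, cfg, seed = s)
    tb <- r$truth_blocks
    base <- tb[tb$label == "B", ]
    # interior k-mers only: at the read ends prev/next mass is reassigned
    interior <- base[base$kmer_index > 1 & base$kmer_index < max(base$kmer_index), ]
    idx <- unlist(lapply(seq_len(nrow(interior)), function(i)
      (interior$start[i] + 1):interior$end[i]))
    states <- c(states, r$truth_states[idx])
    s <- s + 1
  }
  obs <- table(factor(states, levels = c("prev", "curr", "next", "noise")))
  expected <- c(0.05, 0.89, 0.05, 0.01)
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("pooled prev-state samples sit at the previous k-mer baseline", {
  tab <- shared_table()
  cfg <- sim_config(tab, p_prev = 0.15, p_next = 0, p_noise = 0,
                    drift_sd = 0, offset_sd = 0, polya_len = 0, seed = 5)
  ref <- random_reference(tab, 20, min_step = 5, seed = 77)
  devs <- numeric(0)
  for (s in 1:100) {
    r <- simulate_read(ref, cfg, seed = s)
    tb <- r$truth_blocks
    base <- tb[tb$label == "B" & tb$kmer_index > 1, ]
    po <- tb$kmer[match(base$kmer_index - 1, tb$kmer_index)]
    for (i in seq_len(nrow(base))) {
      sel <- (base$start[i] + 1):base$end[i]
      pv <- sel[r$truth_states[sel] == "prev"]
      if (length(pv) > 0)
        devs <- c(devs, r$signal[pv] - lookup_kmer(tab, po[i])$mu_un)
    }
  }
  expect_lt(abs(mean(devs)), 0.5)
})

test_that("modification labels are drawn at the configured rate", {
  ref <- random_reference(shared_table(), 18, min_step = 5,
                          include = "GGACT", seed = 9)
  # every DRACH 5-mer of the reference needs modification parameters
  n <- nchar(ref) - 4
  kms <- unique(substring(ref, 1:n, 5:nchar(ref)))
  tab <- enable_modification(shared_table(), kms[is_drach(kms)], delta = 8)
  pos <- regexpr("GGACT", ref)[1] + 1   # 0-based centre = start - 1 + 2
  cfg <- sim_config(tab, mod_rate = 0.3, polya_len = 0, seed = 2)
  mods <- vapply(1:500, function(s)
    simulate_read(ref, cfg, seed = s)$truth_mods[pos + 1], logical(1))
  expect_lt(abs(mean(mods) - 0.3), 0.06)        # binomial 99% band at n = 500
  cfg0 <- sim_config(tab, mod_rate = 0, polya_len = 0, seed = 2)
  expect_equal(sum(simulate_read(ref, cfg0)$truth_mods), 0)
})

test_that("simulate_dataset writes a readable container with one row per read", {
  tab <- shared_table()
  ref <- random_reference(tab, 12, min_step = 5, seed = 55)
  cfg <- sim_config(tab, polya_len = 100, seed = 1)
  dir <- tempfile()
  ds <- simulate_dataset(c(tx = ref), 10, cfg, dir = dir)
  expect_length(ds$reads, 10)
  expect_equal(nrow(ds$manifest), 10)
  back <- read_signal_container(dir)
  expect_length(back, 10)
  expect_equal(back[[3]]$read_id, ds$reads[[3]]$read_id)
  expect_equal(back[[3]]$signal, ds$reads[[3]]$signal, tolerance = 1e-4)
  expect_equal(back[[3]]$transcript_interval, ds$reads[[3]]$transcript_interval)
  expect_error(simulate_dataset(character(0), 5, cfg),
               class = "poreseg_validation_error")
})

test_that("invalid references and configs are rejected", {
  tab <- shared_table()
  cfg <- sim_config(tab)
  expect_error(simulate_read("ACGTN", cfg), class = "poreseg_validation_error")
  expect_error(simulate_read("ACG", cfg), class = "poreseg_validation_error")
  expect_error(sim_config(tab, p_prev = 0.6, p_next = 0.5),
               class = "poreseg_validation_error")
  expect_error(sim_config(tab, dwell_mean = 2),
               class = "poreseg_validation_error")
  expect_error(sim_config(tab, trans_len_range = c(1, 30)),
               class = "poreseg_validation_error")
  # mod_rate > 0 needs modification parameters on DRACH k-mers
  cfgm <- sim_config(tab, mod_rate = 0.5)
  ref <- random_reference(tab, 18, min_step = 5, include = "GGACT", seed = 9)
  expect_error(simulate_read(ref, cfgm), "GGACT",
               class = "poreseg_validation_error")
})

test_that("random_reference honours the k-mer step constraint and motif", {
  tab <- shared_table()
  ref <- random_reference(tab, 30, min_step = 5, include = "GGACT", seed = 3)
  expect_match(ref, "GGACT")
  n <- nchar(ref) - 4
  mu <- tab[substring(ref, 1:n, 5:nchar(ref)), "mu_un"]
  expect_true(all(abs(diff(mu)) >= 5))
})
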