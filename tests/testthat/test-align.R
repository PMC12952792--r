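test_that("match scores are the larger of the two state log-densities", {
  tab <- enable_modification(tiny_table(), "GGGGG", delta = 9, omega_mod = 0.5)
  p_un <- lookup_kmer(tab, "AAAAA")
  expect_equal(kmer_score(p_un$mu_un, "AAAAA", tab),
               -log(sqrt(2 * pi) * p_un$sigma_un), tolerance = 1e-12)
  p_m <- lookup_kmer(tab, "GGGGG")
  expect_equal(kmer_score(p_m$mu_mod, "GGGGG", tab),
               dnorm(p_m$mu_mod, p_m$mu_mod, p_m$sigma_mod, log = TRUE))
  set.seed(1)
  for (mu in runif(20, 70, 140)) {
    want <- max(dnorm(mu, p_m$mu_un, p_m$sigma_un, log = TRUE),
                dnorm(mu, p_m$mu_mod, p_m$sigma_mod, log = TRUE))
    expect_equal(kmer_score(mu, "GGGGG", tab), want)
  }
  expect_error(kmer_score(100, "ACGTC", tab), "ACGTC",
               class = "poreseg_validation_error")
})

test_that("indel score is a single constant that never beats a perfect match", {
  tab <- tiny_table()
  g <- indel_score(tab)
  expect_lt(g, 0)
  expect_equal(indel_score(tab, range = 50) - indel_score(tab, range = 100),
               log(2))
  for (km in rownames(tab))
    expect_lt(g, kmer_score(lookup_kmer(tab, km)$mu_un, km, tab))
})

test_that("1x1 alignment is a single match with the match score", {
  tab <- tiny_table()
  al <- align_full(80.3, "AAAAA", tab)
  expect_equal(nrow(al$path), 1)
  expect_identical(al$path$op, "match")
  expect_equal(al$score, kmer_score(80.3, "AAAAA", tab))
})

test_that("two means near one baseline and one near the next align many-to-one", {
  # the canonical sub-state pattern: mu1, mu2 belong to the first occurrence
  # of a k-mer, mu3 to the following k-mer
  tab <- tiny_table()
  means <- c(80.5, 79.2, 95.8)           # near AAAAA (80), then CCCCC (95)
  al <- align_full(means, c("AAAAA", "CCCCC"), tab)
  used <- al$path[al$path$op %in% c("match", "stay"), ]
  expect_equal(used$j[used$i == 1], 1)
  expect_equal(used$j[used$i == 2], 1)
  expect_equal(used$j[used$i == 3], 2)
})

test_that("full DP equals exhaustive path enumeration (m, n <= 6)", {
  set.seed(7)
  tab <- tiny_table()
  gap <- indel_score(tab)
  for (rep in 1:60) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    kms <- sample(rownames(tab), n, replace = TRUE)
    means <- runif(m, 75, 130)
    f <- vapply(kms, function(s) kmer_score(means, s, tab), numeric(m))
    f <- matrix(f, nrow = m)
    al <- align_full(means, kms, tab)
    expect_equal(al$score, brute_align_full(f, gap), tolerance = 1e-12)
  }
})

test_that("partial DP equals exhaustive prefix enumeration (m, n <= 6)", {
  set.seed(8)
  tab <- tiny_table()
  for (rep in 1:60) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    kms <- sample(rownames(tab), n, replace = TRUE)
    means <- runif(m, 75, 130)
    f <- vapply(kms, function(s) kmer_score(means, s, tab), numeric(m))
    f <- matrix(f, nrow = m)
    al <- align_partial(means, kms, tab)
    expect_equal(al$score, brute_align_partial(f), tolerance = 1e-12)
  }
})

test_that("alignment paths are monotone and respect the variant contracts", {
  set.seed(9)
  tab <- tiny_table()
  for (rep in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    kms <- sample(rownames(tab), n, replace = TRUE)
    means <- runif(m, 75, 130)
    for (variant in c("full", "partial")) {
      al <- if (variant == "full") align_full(means, kms, tab)
            else align_partial(means, kms, tab)
      path <- al$path
      expect_true(all(diff(path$i[!is.na(path$i)]) >= 0))
      expect_true(all(diff(path$j[!is.na(path$j)]) >= 0))
      ii <- path$i[path$op %in% c("match", "stay", "ins")]
      expect_equal(sort(ii), seq_len(m))          # every mean consumed once
      if (variant == "full") {
        expect_setequal(path$j[!is.na(path$j)], seq_len(n))  # all k-mers
      } else {
        expect_true(all(path$op %in% c("match", "stay")))
        jj <- sort(unique(path$j))
        expect_equal(jj, seq_len(max(jj)))        # a prefix, fully covered
      }
    }
  }
})

test_that("partial alignment of a prefix-matched read covers only that prefix", {
  tab <- shared_table()
  ref <- random_reference(tab, 14, min_step = 6, seed = 12)
  kms <- ref_kmer_seq(ref, 5)
  means <- tab[kms$kmers[1:3], "mu_un"]          # match first 3 of 10 k-mers
  al <- align_partial(means, kms, tab)
  expect_equal(sort(unique(al$path$j)), 1:3)
  al1 <- align_partial(means[1], kms, tab)
  expect_equal(al1$path$j, 1)                    # m = 1 is forced onto s_1
})

test_that("events merge member blocks by the combined-moments identity", {
  set.seed(4)
  x1 <- rnorm(10, 100, 1); x2 <- rnorm(30, 104, 1)
  blocks <- data.frame(
    start = c(0L, 10L, 14L), end = c(10L, 14L, 44L),
    label = c("B", "T", "B"),
    mean = c(mean(x1), 0, mean(x2)), std = c(sd(x1), 0, sd(x2)),
    n = c(10L, 4L, 30L))
  seg <- structure(list(read_id = "r", blocks = blocks, total_loglik = 0),
                   class = "segmentation")
  tab <- tiny_table()
  al <- align_full(c(mean(x1), mean(x2)), "ACGTA", tab)
  ev <- assemble_events(al, seg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_level_mean, mean(c(x1, x2)), tolerance = 1e-9)
  expect_equal(ev$event_stdv, sd(c(x1, x2)), tolerance = 1e-9)
  expect_equal(ev$event_length, 40)
  # the exact two-block example: (10, 100, 1) + (30, 104, 1) has mean 103
  blocks2 <- blocks
  blocks2$mean <- c(100, 0, 104); blocks2$std <- c(1, 0, 1)
  seg2 <- structure(list(read_id = "r", blocks = blocks2, total_loglik = 0),
                    class = "segmentation")
  ev2 <- assemble_events(align_full(c(100, 104), "ACGTA", tab), seg2)
  expect_equal(ev2$event_level_mean, 103.0)
})

test_that("single-block events equal the block statistics and deletions drop k-mers", {
  tab <- tiny_table()
  blocks <- data.frame(start = 0L, end = 20L, label = "B",
                       mean = 95.2, std = 1.7, n = 20L)
  seg <- structure(list(read_id = "r", blocks = blocks, total_loglik = 0),
                   class = "segmentation")
  kms <- c("CCCCC", "TTTTT")               # mean near CCCCC only
  al <- align_full(95.2, kms, tab)
  ev <- assemble_events(al, seg)
  expect_equal(nrow(ev), 1)                # TTTTT hit only by a deletion
  expect_equal(ev$model_kmer, "CCCCC")
  expect_equal(ev$event_level_mean, 95.2)
  expect_equal(ev$event_stdv, 1.7)
  expect_lte(nrow(ev), length(kms))        # pigeonhole
})

test_that("end-to-end events land on the generating k-mers", {
  tab <- shared_table()
  cfg <- sim_config(tab, p_prev = 0, p_next = 0, p_noise = 0,
                    drift_sd = 0, offset_sd = 0, seed = 19)
  ref <- random_reference(tab, 20, min_step = 8, seed = 44)
  ds <- simulate_dataset(c(tx = ref), 8, cfg)
  pe <- pipeline_events(ds$reads, c(tx = ref), tab, standardized = TRUE)
  ev <- pe$events
  err <- abs(ev$event_level_mean - tab[ev$model_kmer, "mu_un"])
  expect_gt(mean(err < 2), 0.95)
})

test_that("feature vectors project flanking event summaries in order", {
  ev <- data.frame(
    contig = "tx", position = c(4L, 5L, 6L), reference_kmer = "AAAAA",
    read_name = "r1", event_level_mean = c(101, 105, 99),
    event_stdv = c(1.2, 2.1, 0.8), event_length = c(12L, 30L, 7L),
    start_idx = 0L, end_idx = 0L, model_kmer = "AAAAA",
    stringsAsFactors = FALSE)
  v <- m6anet_features(ev, 5L)
  expect_true(attr(v, "available"))
  expect_equal(as.numeric(v), c(101, 1.2, 12, 105, 2.1, 30, 99, 0.8, 7))
  v2 <- m6anet_features(ev[-1, ], 5L)      # deleted left flank
  expect_false(attr(v2, "available"))
  expect_true(all(is.na(v2)))
})

test_that("feature matrix keeps exactly the reads with all three events", {
  tab <- shared_table()
  cfg <- sim_config(tab, seed = 23)
  ref <- random_reference(tab, 15, min_step = 6, seed = 15)
  ds <- simulate_dataset(c(tx = ref), 12, cfg)
  pe <- pipeline_events(ds$reads, c(tx = ref), tab)
  pos <- 5L
  complete <- vapply(unique(pe$events$read_name), function(rn) {
    e <- pe$events[pe$events$read_name == rn, ]
    all((pos + c(-1L, 0L, 1L)) %in% e$position)
  }, logical(1))
  fm <- m6anet_feature_matrix(pe$events, pos)
  expect_equal(nrow(fm), sum(complete))
})

test_that("eventalign TSV round-trips and handles empty event lists", {
  tab <- shared_table()
  cfg <- sim_config(tab, seed = 3)
  ref <- random_reference(tab, 12, min_step = 6, seed = 5)
  ds <- simulate_dataset(c(tx = ref), 2, cfg)
  pe <- pipeline_events(ds$reads, c(tx = ref), tab)
  path <- tempfile(fileext = ".tsv")
  write_eventalign(pe$events, path)
  back <- read_eventalign(path)
  expect_equal(nrow(back), nrow(pe$events))
  expect_equal(back$event_level_mean, pe$events$event_level_mean,
               tolerance = 1e-6)
  expect_identical(back$model_kmer, pe$events$model_kmer)
  empty <- pe$events[0, ]
  p2 <- tempfile(fileext = ".tsv")
  write_eventalign(empty, p2)
  expect_equal(length(readLines(p2)), 1)          # header only
  expect_equal(nrow(read_eventalign(p2)), 0)
})
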