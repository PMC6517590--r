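test_that("decade pools are unions of observed taxa per bin", {
  m <- matrix(c(1L, 1L, 0L, 0L,
                0L, 1L, 1L, 0L,
                0L, 0L, 0L, 1L), 3, 4, byrow = TRUE,
              dimnames = list(c("s90a", "s90b", "s00"),
                              c("A", "B", "C", "D")))
  comm <- as_community_tbl(m)
  meta <- tibble::tibble(sample_id = c("s90a", "s90b", "s00"),
                         lake_id = c("L1", "L2", "L1"),
                         year = c(1991L, 1999L, 2003L))
  pools <- build_pools(comm, meta)
  expect_setequal(pools$taxa[[match("1990s", pools$bin)]], c("A", "B", "C"))
  expect_setequal(pools$taxa[[match("2000s", pools$bin)]], "D")
  expect_equal(sort(pools$n_taxa), c(1L, 3L))

  meta_bad <- meta
  meta_bad$year[1] <- NA
  expect_error(build_pools(comm, meta_bad), "no year")
})

test_that("tip randomization is uniform over pool permutations", {
  set.seed(99)
  n_draw <- 10000
  hits <- sum(vapply(seq_len(n_draw), function(k) {
    randomize_tips(c("A", "B"))[["A"]] == "A"
  }, logical(1)))
  se <- sqrt(0.5 * 0.5 / n_draw)
  expect_lt(abs(hits / n_draw - 0.5), 3 * se)
  expect_identical(randomize_tips("only"), c(only = "only"))
  # relabeling preserves the multiset of pairwise distances
  D <- patristic_matrix(t1_tree())
  perm <- randomize_tips(c("A", "B", "C", "D"))
  expect_equal(sort(D[perm, perm][upper.tri(D)]), sort(D[upper.tri(D)]))
})

test_that("exhaustive SES on the 4-tip tree matches the enumeration oracle", {
  D <- patristic_matrix(t1_tree())
  pool <- c("A", "B", "C", "D")
  res <- ses_phylo(c("A", "B"), D, pool, exhaustive = TRUE)
  # null over the 6 richness-2 subsets: MNTD values {2,2,4,4,4,4}
  expect_equal(res$null_mean, 10 / 3, tolerance = 1e-12)
  expect_equal(res$null_sd, sqrt((16 / 3) / 5), tolerance = 1e-12)
  expect_equal(res$ses, (2 - 10 / 3) / sqrt((16 / 3) / 5), tolerance = 1e-12)
  expect_equal(res$nti, -res$ses)
  expect_equal(res$nti, 1.290994, tolerance = 1e-6)

  res_ac <- ses_phylo(c("A", "C"), D, pool, exhaustive = TRUE)
  expect_gt(res_ac$ses, 0)  # observed 4 above the null mean
  expect_lt(res_ac$nti, 0)

  # sample = whole pool: degenerate null
  res_all <- ses_phylo(pool, D, pool)
  expect_true(is.na(res_all$ses))
  expect_equal(res_all$classification, "random")
  expect_equal(res_all$null_sd, 0)

  expect_error(ses_phylo("A", D, pool), "richness")
  expect_error(ses_phylo(c("A", "B"), D, pool, n_rand = 0), "positive")
  expect_error(ses_phylo(c("A", "Z"), D, pool), "Z")
})

test_that("stochastic SES converges to the exhaustive null", {
  D <- patristic_matrix(t1_tree())
  pool <- c("A", "B", "C", "D")
  exact <- ses_phylo(c("A", "B"), D, pool, exhaustive = TRUE)
  # the exhaustive mode reports the sample SD over the K = choose(4,2) = 6
  # distinct assignments; random draws estimate the population SD of that
  # distribution, smaller by the finite-enumeration factor sqrt((K-1)/K)
  K <- choose(4, 2)
  sd_pop <- exact$null_sd * sqrt((K - 1) / K)
  nti_pop <- -(exact$observed - exact$null_mean) / sd_pop
  n_seed <- 60
  draws <- do.call(rbind, lapply(seq_len(n_seed), function(k) {
    r <- ses_phylo(c("A", "B"), D, pool, n_rand = 999, seed = k)
    c(r$null_mean, r$null_sd, r$nti)
  }))
  targets <- c(exact$null_mean, sd_pop, nti_pop)
  for (j in 1:3) {
    se <- sd(draws[, j]) / sqrt(n_seed)
    expect_lt(abs(mean(draws[, j]) - targets[j]), 3 * se + 1e-9)
  }
})

test_that("classification is invariant to rescaling all branch lengths", {
  tr <- random_test_tree(16)
  big <- tr
  big$edge.length <- big$edge.length * 37.5
  D1 <- patristic_matrix(tr)
  D2 <- patristic_matrix(big)
  pool <- tr$tip.label
  set.seed(3)
  for (k in 1:5) {
    s <- sample(pool, 6)
    r1 <- ses_phylo(s, D1, pool, n_rand = 199, seed = k)
    r2 <- ses_phylo(s, D2, pool, n_rand = 199, seed = k)
    expect_equal(r1$ses, r2$ses, tolerance = 1e-10)
    expect_identical(r1$classification, r2$classification)
  }
})

test_that("SES agrees with the picante reference null (taxa.labels)", {
  skip_if_not_installed("picante")
  set.seed(41)
  tr <- random_test_tree(12)
  D <- patristic_matrix(tr)
  pool <- tr$tip.label
  s <- sample(pool, 5)
  mine <- ses_phylo(s, D, pool, exhaustive = TRUE)
  m <- rbind(s1 = as.integer(pool %in% s),
             s2 = as.integer(pool %in% sample(pool, 6)))
  colnames(m) <- pool
  ref <- picante::ses.mntd(m, D, null.model = "taxa.labels", runs = 999)
  # same observed metric; stochastic picante null close to the exact null
  expect_equal(mine$observed, ref$mntd.obs[1], tolerance = 1e-10)
  expect_lt(abs(mine$null_mean - ref$mntd.rand.mean[1]), 4 * ref$mntd.rand.sd[1] / sqrt(999))
})

test_that("type-I error is calibrated for random assembly from a Yule pool", {
  tree <- simulate_tree(64, 202)
  D <- patristic_matrix(tree)
  pool <- tree$tip.label
  set.seed(73)
  cls <- vapply(seq_len(200), function(i) {
    rich <- min(max(5L, stats::rpois(1, 20)), 63L)
    ses_phylo(sample(pool, rich), D, pool, n_rand = 199,
              seed = 5000 + i)$classification
  }, character(1))
  frac <- mean(cls != "random")
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("extreme filtering constructions classify as clustered", {
  # MPD: samples confined to either clade of a deep two-clade tree are
  # basally extreme under every mixed null subset
  txt <- paste0("((a1:0.1,(a2:0.1,(a3:0.1,(a4:0.1,a5:0.1):0.1):0.1):0.1):10,",
                "(b1:0.1,(b2:0.1,(b3:0.1,(b4:0.1,b5:0.1):0.1):0.1):0.1):10);")
  tr <- read_phylogeny(text = txt)
  D <- patristic_matrix(tr)
  pool <- tr$tip.label
  ra <- ses_phylo(paste0("a", 1:5), D, pool, metric = "mpd", exhaustive = TRUE)
  rb <- ses_phylo(paste0("b", 1:5), D, pool, metric = "mpd", exhaustive = TRUE)
  expect_identical(ra$classification, "clustered")
  expect_identical(rb$classification, "clustered")
  expect_gt(ra$nti, 0)

  # MNTD: a tight clade inside a pool of scattered singletons is tip-extreme
  # (every other equal-richness subset carries at least one distant taxon)
  tight <- "(c1:0.1,(c2:0.1,(c3:0.1,(c4:0.1,c5:0.1):0.05):0.05):0.05):5"
  loners <- paste0("(x", 1:4, ":5,y", 1:4, ":5):5", collapse = ",")
  tr2 <- read_phylogeny(text = paste0("(", tight, ",", loners, ");"))
  D2 <- patristic_matrix(tr2)
  rc <- ses_phylo(paste0("c", 1:5), D2, tr2$tip.label, exhaustive = TRUE)
  expect_identical(rc$classification, "clustered")
  expect_gt(rc$nti, 0)
})

test_that("nti_series scores every sample reproducibly and order-independently", {
  set.seed(55)
  tr <- random_test_tree(20)
  m <- matrix(rbinom(8 * 20, 1, 0.4) * rpois(160, 5), 8, 20,
              dimnames = list(paste0("s", 1:8), tr$tip.label))
  m[rowSums(m > 0) < 2, 1:2] <- 3L
  comm <- as_community_tbl(m)
  meta <- tibble::tibble(sample_id = rownames(m),
                         lake_id = rep(c("L1", "L2"), 4),
                         year = as.integer(seq(1931, 2001, by = 10)))
  r1 <- nti_series(comm, tr, meta, n_rand = 99, seed = 42)
  expect_equal(nrow(r1), 8L)
  expect_equal(r1$nti, -r1$ses)
  r2 <- nti_series(comm, tr, meta, n_rand = 99, seed = 42)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # sample order must not matter: per-sample streams derive from sample_id
  shuffle <- c(5:8, 1:4)
  r3 <- nti_series(comm[shuffle, ], tr, meta[shuffle, ], n_rand = 99, seed = 42)
  r3 <- r3[match(r1$sample_id, r3$sample_id), ]
  expect_equal(r1$nti, r3$nti, tolerance = 1e-12)

  g <- glance(r1)
  expect_equal(g$n_samples, 8L)
  expect_equal(g$fraction_non_random,
               g$fraction_clustered + g$fraction_overdispersed)
})

test_that("unscorable samples are skipped with a warning, not fatal", {
  tr <- t1_tree()
  m <- matrix(c(5L, 5L, 0L, 0L,
                7L, 0L, 0L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("ok", "single"), tr$tip.label))
  comm <- as_community_tbl(m)
  meta <- tibble::tibble(sample_id = c("ok", "single"),
                         lake_id = "L1", year = c(1950L, 1950L))
  expect_warning(res <- nti_series(comm, tr, meta, n_rand = 99, seed = 1),
                 "single")
  expect_equal(res$sample_id, "ok")
})
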