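test_that("haversine distances match the closed form on the equator", {
  coords <- tibble::tibble(lake_id = c("p", "q"), lat = c(0, 0), lon = c(0, 1))
  d <- haversine_matrix(coords)
  expect_equal(d["p", "q"], 6371 * pi / 180, tolerance = 1e-9)
  expect_equal(d["p", "p"], 0)
  set.seed(8)
  rnd <- tibble::tibble(lake_id = paste0("l", 1:6),
                        lat = runif(6, -80, 80), lon = runif(6, -170, 170))
  D <- haversine_matrix(rnd)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0))
  bad <- tibble::tibble(lake_id = "x", lat = 91, lon = 0)
  expect_error(haversine_matrix(bad), "Invalid coordinates")
})

test_that("decade binning follows the [d0, d0+9] convention", {
  expect_identical(decade_bin(1937L), "1930s")
  expect_identical(decade_bin(1930L), "1930s")
  expect_identical(decade_bin(c(1939L, 1940L)), c("1930s", "1940s"))
  expect_error(decade_bin(1750L), "1800")
})

test_that("sparse bins are excluded with a note", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:5),
                         year = c(1931L, 1935L, 1947L, 1949L, 1961L))
  expect_message(kept <- filter_bins(meta, min_samples = 2), "1960s")
  expect_setequal(kept$bin, c("1930s", "1940s"))
})

test_that("mantel test recovers perfect and affine-invariant correlation", {
  set.seed(21)
  n <- 5
  M <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(M) <- list(paste0("s", 1:n), paste0("s", 1:n))
  r1 <- mantel_test(M, M, exhaustive = TRUE)
  expect_equal(r1$r, 1)
  expect_gte(r1$p, 1 / factorial(n))
  r2 <- mantel_test(M, 3.7 * M + 2, exhaustive = TRUE)
  expect_equal(r2$r, 1)
  expect_equal(r2$p, r1$p)
  flat <- M * 0
  expect_warning(r3 <- mantel_test(M, flat, n_perm = 99), "Zero variance")
  expect_true(is.na(r3$r))
  expect_error(mantel_test(M[1:2, 1:2], M[1:2, 1:2]), "at least 3")
})

test_that("stochastic mantel p agrees with the exhaustive enumeration", {
  set.seed(33)
  for (n in 4:6) {
    A <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    B <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    ex <- mantel_test(A, B, exhaustive = TRUE)
    st <- mantel_test(A, B, n_perm = 999, seed = n)
    se <- sqrt(ex$p * (1 - ex$p) / 999)
    expect_equal(st$r, ex$r, tolerance = 1e-12)
    expect_lt(abs(st$p - ex$p), 3 * se + 2 / 1000)
  }
})

test_that("mantel agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(29)
  n <- 12
  A <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  B <- as.matrix(dist(matrix(rnorm(n * 3), n))) + 0.4 * A
  mine <- mantel_test(A, B, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p - ref$signif), 0.05)
})

test_that("environmental gradients difference pairs and drop missing", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:3),
                         TP = c(10, 25, NA), air_temp = c(8, 9, 10.5))
  g <- env_gradient(meta, "TP")
  expect_equal(nrow(g), 1L)
  expect_equal(g$delta, 15)
  gt <- env_gradient(meta, "air_temp")
  expect_equal(nrow(gt), 3L)
  expect_equal(sort(gt$delta), c(1, 1.5, 2.5))
  expect_error(env_gradient(meta, "salinity"), "Unknown")
})

test_that("OLS decay fit matches the closed form on three points", {
  frame <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 4),
                          same_lake = FALSE)
  fit <- distance_decay(frame, "y", "x")
  g <- glance(fit)
  expect_equal(g$slope, 2, tolerance = 1e-12)
  expect_equal(g$intercept, -1 / 3, tolerance = 1e-12)
  # closed form: SSE = 2/3, SST = 26/3 -> R^2 = 12/13, adj = 11/13
  expect_equal(g$r_squared, 12 / 13, tolerance = 1e-12)
  expect_equal(g$adj_r_squared, 11 / 13, tolerance = 1e-12)
  expect_equal(g$adj_r_squared,
               1 - (1 - g$r_squared) * (3 - 1) / (3 - 2), tolerance = 1e-12)
  expect_equal(g$df_residual, 1L)
})

test_that("noise-free linear responses are recovered exactly", {
  set.seed(61)
  frame <- tibble::tibble(x = runif(40, 0, 5))
  frame$y <- 3 - 0.7 * frame$x
  fit <- distance_decay(frame, "y", "x")
  g <- suppressWarnings(glance(fit))  # summary.lm warns on a perfect fit
  expect_equal(g$slope, -0.7, tolerance = 1e-10)
  expect_equal(g$adj_r_squared, 1, tolerance = 1e-10)
})

test_that("slope p-values are uniform under independence", {
  set.seed(71)
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(k) {
    frame <- tibble::tibble(x = rnorm(60), y = rnorm(60))
    glance(distance_decay(frame, "y", "x"))$p_slope
  }, numeric(1))
  rej <- mean(pvals <= 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej - 0.05), 4 * se)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("non-random pair subsetting honours the both/either rules", {
  frame <- tibble::tibble(
    beta = c(1, 2, 3, 4), x = c(1, 2, 3, 4),
    same_lake = FALSE,
    non_random_both = c(TRUE, TRUE, TRUE, FALSE),
    non_random_either = c(TRUE, TRUE, TRUE, TRUE))
  fit <- distance_decay(frame, "beta", "x", subset = "non_random")
  expect_equal(fit$n, 3L)
  fit2 <- distance_decay(frame, "beta", "x", subset = "non_random",
                         pair_rule = "either")
  expect_equal(fit2$n, 4L)
  expect_error(distance_decay(frame[1:2, ], "beta", "x"), "Too few pairs")
  expect_error(distance_decay(frame, "beta", "zzz"), "zzz")
})

test_that("per-bin geographic mantel never mixes decades", {
  set.seed(83)
  tr <- random_test_tree(12)
  n_s <- 12
  m <- matrix(rbinom(n_s * 12, 1, 0.5) * 3L, n_s, 12,
              dimnames = list(paste0("s", 1:n_s), tr$tip.label))
  m[rowSums(m > 0) < 2, 1:2] <- 3L
  comm <- as_community_tbl(m)
  meta <- tibble::tibble(sample_id = rownames(m),
                         lake_id = rep(paste0("L", 1:4), 3),
                         year = rep(c(1941L, 1955L, 1968L), each = 4),
                         lat = rep(c(46, 46.5, 47, 47.5), 3),
                         lon = rep(c(6.5, 7.5, 8.5, 9.5), 3))
  beta <- pairwise_beta(comm, tr, "beta_mntd")
  geo <- log(haversine_matrix(dplyr::distinct(meta, lake_id, lat, lon)) + 1)
  mg <- mantel_by_bin(beta, meta, geo, n_perm = 99, seed = 4)
  expect_setequal(mg$bin, c("1940s", "1950s", "1960s"))
  expect_true(all(mg$n == 4))  # each test sees exactly one decade's samples
  expect_true(!is.na(attr(mg, "fisher_p")))
  # pairwise frame marks decade identity for the geographic subset
  frame <- build_pairwise_frame(beta, meta)
  expect_true(all(frame$same_decade == (frame$decade_1 == frame$decade_2)))
})

test_that("pairwise frames hold one row per unordered pair with exact zeros", {
  tr <- t1_tree()
  m <- matrix(c(2L, 3L, 0L, 0L,
                0L, 4L, 5L, 0L,
                1L, 0L, 0L, 6L), 3, 4, byrow = TRUE,
              dimnames = list(c("x1", "x2", "x3"), tr$tip.label))
  comm <- as_community_tbl(m)
  meta <- tibble::tibble(sample_id = c("x1", "x2", "x3"),
                         lake_id = c("L1", "L1", "L2"),
                         year = c(1950L, 1960L, 1950L),
                         lat = c(46, 46, 47), lon = c(7, 7, 8),
                         TP = c(10, 12, NA))
  beta <- pairwise_beta(comm, tr, "beta_mntd")
  frame <- build_pairwise_frame(beta, meta, env_vars = "TP")
  expect_equal(nrow(frame), 3L)
  expect_false(any(duplicated(paste(frame$sample_1, frame$sample_2))))
  same_lake <- frame$lake_1 == frame$lake_2
  expect_equal(frame$geographic_km == 0, same_lake)
  expect_equal(frame$temporal_years[same_lake], 10)
  expect_equal(frame$d_TP[frame$sample_1 == "x1" & frame$sample_2 == "x2"], 2)
  expect_true(all(is.na(frame$d_TP[frame$sample_2 == "x3"])))
  expect_true(all(frame$d_TP >= 0, na.rm = TRUE))
})
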