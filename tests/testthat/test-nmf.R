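# NMF factorization, consensus clustering, cophenetic rank selection and
# group profiles.

test_that("rank-1 structure is reconstructed almost exactly", {
  set.seed(1)
  u <- runif(30, 0.5, 2)
  v <- runif(8, 0.5, 2)
  X <- u %*% t(v)
  fit <- nmf_factorize(X, k = 1, seed = 3)
  rel_err <- sqrt(sum((X - fit$W %*% fit$H)^2) / sum(X^2))
  expect_lt(rel_err, 1e-4)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("the objective trace is non-increasing on random inputs", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(10:40, 1); p <- sample(5:15, 1)
    X <- matrix(rgamma(n * p, 2, 1), n, p)
    k <- sample(2:4, 1)
    fit <- nmf_factorize(X, k, seed = i, max_iter = 300)
    dec <- diff(fit$trace)
    expect_true(all(dec <= 1e-8 * pmax(fit$trace[-length(fit$trace)], 1)))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
})

test_that("invalid factorization inputs are rejected", {
  X <- matrix(1:12, 3, 4)
  expect_error(nmf_factorize(-X, 2), "non-negative")
  expect_error(nmf_factorize(X, 0), ">= 1")
  expect_error(nmf_factorize(X, 3), "smaller")
})

test_that("planted blocks are recovered by argmax-W grouping", {
  bm <- simulate_block_matrix(n_per_block = 25, n_blocks = 2, snr = 6,
                              seed = 4)
  fit <- nmf_factorize(bm$matrix, k = 2, seed = 7)
  g <- assign_groups(fit)
  expect_equal(ari(g, bm$block), 1)
})

test_that("group assignment breaks ties low and flags all-zero rows", {
  W <- rbind(c(0.1, 0.9), c(0.5, 0.5), c(0, 0))
  expect_warning(g <- assign_groups(W), "group 0")
  expect_equal(unname(g), c(2L, 1L, 0L))
})

test_that("consensus matrices are symmetric unit-diagonal co-clustering rates", {
  bm <- simulate_block_matrix(n_per_block = 15, n_blocks = 2, snr = 6,
                              seed = 5)
  cons <- consensus_matrix(bm$matrix, k = 2, n_restarts = 5, seed = 1)
  expect_equal(cons, t(cons))
  expect_equal(unname(diag(cons)), rep(1, 30))
  expect_true(all(cons >= 0 & cons <= 1))
  # perfectly separable: ones within true blocks, zeros across
  expect_true(all(cons[bm$block == 1, bm$block == 1] == 1))
  expect_true(all(cons[bm$block == 1, bm$block == 2] == 0))

  # two restarts can only produce multiples of 1/2
  cons2 <- consensus_matrix(bm$matrix, k = 2, n_restarts = 2, seed = 1)
  expect_true(all(cons2 %in% c(0, 0.5, 1)))
})

test_that("cophenetic coefficient is 1 for perfect structures and < 1 for noise", {
  block <- matrix(0, 20, 20)
  block[1:10, 1:10] <- 1
  block[11:20, 11:20] <- 1
  expect_equal(cophenetic_coefficient(block), 1)
  expect_equal(cophenetic_coefficient(block, distance = "one-minus"), 1)

  # all-singleton consensus: constant distances, 1 by convention
  expect_equal(cophenetic_coefficient(diag(10)), 1)

  set.seed(6)
  u <- matrix(runif(50 * 50), 50)
  noisy <- (u + t(u)) / 2
  diag(noisy) <- 1
  expect_lt(cophenetic_coefficient(noisy), 1)

  expect_error(cophenetic_coefficient(diag(2)), "3 genes")
})

test_that("the sequential rank rule adopts the last rank before the first decrease", {
  rule <- function(...) trimark:::rank_from_cophenetic_curve(
    ..., rule = "first-decrease")
  expect_equal(rule(2:5, c(0.99, 0.995, 0.96, 0.97)), 3)
  expect_equal(rule(2:5, c(0.99, 0.95, 0.96, 0.97)), 2)
  expect_warning(k <- rule(2:5, c(0.9, 0.95, 0.96, 0.97)), "never decreases")
  expect_equal(k, 5)
})

test_that("the max-stability rank rule agrees on clean curves and resists jitter", {
  rule <- function(...) trimark:::rank_from_cophenetic_curve(
    ..., rule = "max-stability")
  # plateau-then-fall curves: identical to the sequential rule
  expect_equal(rule(2:5, c(0.99, 0.995, 0.96, 0.97)), 3)
  expect_equal(rule(2:5, c(0.99, 0.95, 0.96, 0.97)), 2)
  expect_equal(rule(2:5, c(0.9, 0.95, 0.96, 0.97)), 5)
  # a noise dip before the exact-1.0 true rank no longer derails selection
  expect_equal(rule(2:6, c(0.995, 0.987, 1.0, 0.998, 0.996)), 4)
  # ties resolve to the larger rank
  expect_equal(rule(2:6, c(1.0, 0.99, 1.0, 0.998, 0.996)), 4)
})

test_that("rank selection recovers a planted four-block structure", {
  hits <- 0
  for (seed in 1:10) {
    bm <- simulate_block_matrix(n_per_block = 30, features_per_block = 4,
                                n_blocks = 4, snr = 3, seed = seed)
    sel <- suppressWarnings(
      select_rank(bm$matrix, ranks = 2:6, n_restarts = 10, seed = seed,
                  max_iter = 500))
    hits <- hits + (sel$k_star == 4)
  }
  expect_gte(hits, 8)
})

test_that("grouping recovers planted blocks with high agreement end to end", {
  aris <- vapply(1:5, function(seed) {
    bm <- simulate_block_matrix(n_per_block = 30, features_per_block = 4,
                                n_blocks = 4, snr = 3, seed = seed)
    fit <- nmf_factorize(bm$matrix, k = 4, seed = seed + 100,
                         max_iter = 1000)
    ari(assign_groups(fit), bm$block)
  }, numeric(1))
  expect_gte(min(aris), 0.8)
})

test_that("group profiles binarize medians at the strict threshold", {
  X <- rbind(c(10.5, 3), c(10.5, 3), c(10, 0), c(10, 0), c(0, 0))
  colnames(X) <- c("fA", "fB")
  asg <- c(1L, 1L, 2L, 2L, 3L)
  prof <- group_profile(X, asg, threshold = 10)
  p1 <- prof[prof$group == 1, ]
  expect_equal(unname(p1$mark[p1$feature == "fA"]), "@")   # 10.5 > 10
  expect_equal(unname(p1$mark[p1$feature == "fB"]), "-")
  p2 <- prof[prof$group == 2, ]
  expect_equal(unname(p2$mark[p2$feature == "fA"]), "-")   # 10 is not over 10
  p3 <- prof[prof$group == 3, ]
  expect_equal(unname(p3$mark), c("-", "-"))
})

test_that("the high-level grouping ties rank scan, fit and profile together", {
  bm <- simulate_block_matrix(n_per_block = 20, features_per_block = 3,
                              n_blocks = 3, snr = 5, seed = 12)
  res <- suppressWarnings(
    nmf_group(bm$matrix, ranks = 2:4, n_restarts = 5, seed = 12,
              max_iter = 500))
  expect_s3_class(res, "trimark_nmf")
  expect_equal(res$fit$k, 3)
  expect_gte(ari(res$assignment$group, bm$block), 0.95)
  gl <- glance(res)
  expect_equal(gl$rank, 3)
  expect_equal(gl$n_genes, 60)
  td <- tidy(res)
  expect_equal(nrow(td), 60)
  # the planted features light up in each block's profile
  expect_true(all(c("group", "feature", "mark") %in% names(res$profile)))
})
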