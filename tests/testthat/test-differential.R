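# DEG classification (normalize + Welch on log-CPM + BH), factor fold
# changes with pseudocount, and the BH step-up itself.

mk_counts <- function(mat, genes = sprintf("g%03d", seq_len(nrow(mat)))) {
  colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(mat))
}

mk_samples <- function(n_esc, n_fib) {
  tibble::tibble(
    sample_id = sprintf("s%d", seq_len(n_esc + n_fib)),
    cell_type = rep(c("ESC", "fibroblast"), c(n_esc, n_fib)))
}

test_that("identical counts in both cell types give label non and FC 0", {
  m <- matrix(rep(c(100L, 50L, 0L), 6), nrow = 3)
  counts <- mk_counts(m)
  out <- deg_classify(counts, mk_samples(3, 3))
  expect_equal(out$label, rep("non", 3))
  expect_equal(out$log2_expression_fc, rep(0, 3))
})

test_that("a significant but small fold change stays non", {
  # 1.5-fold ~ log2 FC 0.58: below the 2-fold rule regardless of q
  set.seed(2)
  base <- matrix(rpois(2000 * 3, 200), ncol = 3)
  up <- matrix(rpois(2000 * 3, 200), ncol = 3)
  up[1, ] <- rpois(3, 300)  # ~1.5-fold, tight counts -> tiny p
  counts <- mk_counts(cbind(up, base))
  out <- deg_classify(counts, mk_samples(3, 3))
  expect_lt(abs(out$log2_expression_fc[1] - log2(1.5)), 0.3)
  expect_equal(out$label[1], "non")
})

test_that("a planted 8-fold cohort is recovered as up", {
  # 5% of genes shifted 8-fold at dispersion 0.05, 3 vs 3 replicates:
  # per-seed sensitivity stays high
  sens <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 2000
    planted <- seq_len(n * 0.05)
    mu <- rep(100, n)
    mu_esc <- mu; mu_esc[planted] <- mu[planted] * 8
    draw <- function(mu) matrix(rnbinom(n * 3, size = 20, mu = mu), ncol = 3)
    out <- deg_classify(mk_counts(cbind(draw(mu_esc), draw(mu))),
                        mk_samples(3, 3))
    mean(out$label[planted] == "up")
  }, numeric(1))
  expect_gte(sum(sens >= 0.9), 9)
})

test_that("the welch statistic is available but underpowered at tiny n", {
  # same design as above, one seed: the per-gene Welch test runs and
  # controls errors, but variance estimation at n=3 costs sensitivity,
  # which is why the moderated statistic is the default
  set.seed(1)
  n <- 2000
  planted <- seq_len(100)
  mu <- rep(100, n)
  mu_esc <- mu; mu_esc[planted] <- mu[planted] * 8
  draw <- function(mu) matrix(rnbinom(n * 3, size = 20, mu = mu), ncol = 3)
  counts <- mk_counts(cbind(draw(mu_esc), draw(mu)))
  welch <- deg_classify(counts, mk_samples(3, 3), method = "welch")
  mod <- deg_classify(counts, mk_samples(3, 3))
  expect_false(any(welch$label[-planted] == "up"))
  expect_gte(mean(mod$label[planted] == "up"),
             mean(welch$label[planted] == "up"))
  expect_gt(mean(welch$label[planted] == "up"), 0.3)
})

test_that("single-replicate designs fall back to fold-change-only labels", {
  # balanced library sizes so CPM scaling does not distort the example
  m <- cbind(c(800L, 100L, 9100L), c(100L, 100L, 9800L))
  counts <- mk_counts(m)
  expect_warning(out <- deg_classify(counts, mk_samples(1, 1)),
                 "single replicate")
  expect_true(all(is.na(out$q_value)))
  expect_equal(out$label, c("up", "non", "non"))
})

test_that("missing sample labels are rejected", {
  counts <- mk_counts(matrix(1:6, nrow = 1))
  expect_error(deg_classify(counts, mk_samples(2, 2)), "missing")
})

test_that("factor fold changes follow the pseudocount log-ratio", {
  esc <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        `5hmC` = c(3, 7, 15))
  fib <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        `5hmC` = c(3, 1, 0))
  fc <- factor_log2fc(esc, fib, pseudocount = 1)
  expect_equal(fc[["5hmC"]], c(0, 2, 4))  # identity; log2(8/2); log2(16/1)

  fib_bad <- dplyr::rename(fib, hmc = `5hmC`)
  expect_error(factor_log2fc(esc, fib_bad), "labels")
  expect_error(factor_log2fc(esc, fib, pseudocount = 0), "positive")
})

test_that("benjamini-hochberg matches the hand step-up on small cases", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # sort: (.01, .03, .04); raw steps: .01*3/1=.03, .03*3/2=.045, .04*3/3=.04;
  # cumulative min from the largest: (.03, .04, .04); back to input order
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("bh is monotone after sorting, capped at 1, and fixes the largest p", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q <= 1))
    expect_equal(q[o][length(p)], max(p))
  }
})

test_that("null simulations stay under the nominal false-label rate", {
  rates <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 2000
    m <- matrix(rnbinom(n * 6, size = 20, mu = 100), ncol = 6)
    out <- deg_classify(mk_counts(m), mk_samples(3, 3))
    mean(out$label != "non")
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})
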