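# Ternary fold-change pattern logic, trivalent flags, mark-count strata
# and per-pattern expression summaries.

mk_fc <- function(hmc, mc, k4, k8, genes = sprintf("g%03d", seq_along(hmc))) {
  tibble::tibble(gene_id = genes, `5hmC` = hmc, `5mC` = mc,
                 H3K4me1 = k4, H4K8ac = k8)
}

test_that("patterns encode +/-/0 with inclusive boundaries", {
  fc <- mk_fc(c(2.1, 0, 1.0), c(-1.5, 0, 0.99), c(1.2, 0, -1.0),
              c(3.0, 0, -0.99))
  enc <- encode_patterns(fc)
  expect_equal(enc$pattern, c("+-++", "0000", "+0-0"))

  bad <- fc; bad$`5mC`[2] <- NaN
  expect_error(encode_patterns(bad), "finite")
})

test_that("pattern grouping equals brute-force dictionary grouping", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    fc <- mk_fc(rnorm(n, sd = 2), rnorm(n, sd = 2), rnorm(n, sd = 2),
                rnorm(n, sd = 2))
    cl <- cluster_by_pattern(fc, min_size = 1)
    # brute force: dictionary keyed by the encoded state vector
    dict <- split(fc$gene_id, encode_patterns(fc)$pattern)
    got <- split(cl$assignment$gene_id, cl$assignment$pattern)
    expect_equal(got[order(names(got))], dict[order(names(dict))])
    expect_lte(nrow(cl$patterns), 81)  # <= 3^4 distinct codes
    # partition: sizes sum to the universe
    expect_equal(sum(cl$patterns$n), n)
  }
})

test_that("patterns below min_size pool into a rare group, ranked by size", {
  fc <- mk_fc(c(rep(2, 10), rep(0, 7), -2), c(rep(0, 18)),
              c(rep(0, 18)), c(rep(0, 18)))
  cl <- cluster_by_pattern(fc, min_size = 5)
  expect_equal(cl$patterns$pattern_id[1:2], c("P01", "P02"))
  expect_equal(cl$patterns$n[1:2], c(10, 7))
  expect_true("rare" %in% cl$assignment$pattern_id)
  expect_equal(sum(cl$assignment$pattern_id == "rare"), 1)

  expect_error(cluster_by_pattern(mk_fc(double(), double(), double(),
                                        double())), "non-empty")
})

test_that("re-encoding an assignment reproduces it exactly", {
  set.seed(9)
  fc <- mk_fc(rnorm(50, sd = 2), rnorm(50, sd = 2), rnorm(50, sd = 2),
              rnorm(50, sd = 2))
  a1 <- cluster_by_pattern(fc)
  a2 <- cluster_by_pattern(fc)
  expect_identical(a1$assignment, a2$assignment)
  expect_identical(a1$patterns, a2$patterns)
})

test_that("the trivalent flag applies the strict two-fold rule per mark", {
  lin2log <- function(x) log2(x)
  fc <- mk_fc(lin2log(c(2.1, 1.9, 2.0)), 0,
              lin2log(c(2.5, 2.5, 2.0)), lin2log(c(3.0, 3.0, 2.0)))
  fl <- trivalent_flag(fc, fc_threshold = 2)
  expect_equal(fl$trivalent, c(TRUE, FALSE, FALSE))
  expect_equal(fl$n_marks, c(3, 2, 0))  # exactly 2.0 fails the strict rule

  expect_error(trivalent_flag(dplyr::select(fc, -H4K8ac)), "H4K8ac")
})

test_that("mark-count strata classify by flag combination", {
  fc <- mk_fc(log2(c(3, 3, 3, 3, 0.5)), 0,
              log2(c(1, 3, 3, 1, 3)), log2(c(1, 1, 3, 3, 3)))
  fl <- trivalent_flag(fc)
  expr <- tibble::tibble(gene_id = fc$gene_id,
                         log2_expression_fc = c(0.5, 1.5, 3, 2, 1))
  st <- mark_count_strata(fl, fc, expr)
  members <- setNames(as.character(st$members$stratum), st$members$gene_id)
  expect_equal(unname(members["g001"]), "5hmC_only")
  expect_equal(unname(members["g002"]), "5hmC_H3K4me1")
  expect_equal(unname(members["g003"]), "trivalent")
  # g004 (5hmC + H4K8ac without H3K4me1) fits no stratum; g005 lacks the
  # 5hmC membership gain
  expect_false("g004" %in% names(members))
  expect_false("g005" %in% names(members))
  expect_equal(st$summary$n, c(1, 1, 1))
})

test_that("planted strata show strictly increasing median expression change", {
  s <- generate_study(generator_config(n_genes = 3000, seed = 23))
  gb_esc <- study_region_counts(s, "gene_body", "ESC")
  gb_fib <- study_region_counts(s, "gene_body", "fibroblast")
  fc <- factor_log2fc(gb_esc, gb_fib)
  fl <- trivalent_flag(fc)
  truth_fc <- tibble::tibble(gene_id = s$truth$gene_id,
                             log2_expression_fc = s$truth$expression_log2fc)
  st <- mark_count_strata(fl, fc, truth_fc)
  med <- st$summary$median_expression_log2fc
  expect_equal(as.character(st$summary$stratum),
               c("5hmC_only", "5hmC_H3K4me1", "trivalent"))
  expect_true(all(diff(med) > 0))
})

test_that("pattern expression summaries report medians and DEG fractions", {
  fc <- mk_fc(c(2, 2, 2, 0), 0, c(2, 2, 2, 0), c(2, 2, 2, 0))
  cl <- cluster_by_pattern(fc, min_size = 1)
  deg <- tibble::tibble(gene_id = fc$gene_id,
                        label = c("up", "up", "non", "non"),
                        log2_expression_fc = c(3, 2, 1, 0))
  s <- pattern_expression_summary(cl, deg)
  triv <- s[s$pattern == "+0++", ]
  expect_equal(triv$n, 3L)
  expect_equal(triv$median_fc, 2)
  expect_equal(triv$frac_up, 2 / 3)
  single <- s[s$pattern == "0000", ]
  expect_equal(single$median_fc, 0)

  # universe mismatch restricts with a warning
  expect_warning(pattern_expression_summary(cl, deg[1:3, ]), "intersection")
})

test_that("the planted trivalent pattern tops the per-pattern expression medians", {
  s <- generate_study(generator_config(n_genes = 2000, seed = 29))
  gb_esc <- study_region_counts(s, "gene_body", "ESC")
  gb_fib <- study_region_counts(s, "gene_body", "fibroblast")
  fc <- factor_log2fc(gb_esc, gb_fib)
  cl <- cluster_by_pattern(fc)
  deg <- tibble::tibble(gene_id = s$truth$gene_id,
                        label = ifelse(s$truth$expression_log2fc >= 1,
                                       "up", "non"),
                        log2_expression_fc = s$truth$expression_log2fc)
  sm <- pattern_expression_summary(cl, deg)
  sm <- sm[!sm$is_rare, ]
  top <- sm$pattern[which.max(sm$median_fc)]
  expect_equal(top, "+-++")
})
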