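# Synthetic-study generator: placement guarantees, determinism, planted
# structure recovery, fixture round-trips.

test_that("generated genomes are disjoint, in bounds, and deterministic", {
  cfg <- generator_config(n_genes = 100, chrom_length = 1e7, seed = 1)
  ann <- generate_genome(cfg)
  expect_equal(nrow(ann), 100)
  expect_true(all(ann$start >= 0 & ann$end <= 1e7))
  expect_true(all(ann$start < ann$end))
  # disjoint with >= 10 kb spacing (annotation is coordinate-sorted)
  expect_true(all(ann$start[-1] - ann$end[-nrow(ann)] >= 10000))
  expect_identical(ann, generate_genome(cfg))

  empty <- generate_genome(generator_config(n_genes = 0, chrom_length = 1e6))
  expect_equal(nrow(empty), 0)

  expect_error(
    generate_genome(generator_config(n_genes = 100, chrom_length = 1e5)),
    "cannot place")
})

test_that("same config and seed give an identical study", {
  cfg <- generator_config(n_genes = 60, seed = 42)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
})

test_that("every gene appears exactly once in the truth table", {
  s <- generate_study(generator_config(n_genes = 80, seed = 3))
  expect_setequal(s$truth$gene_id, s$annotation$gene_id)
  expect_equal(anyDuplicated(s$truth$gene_id), 0)
})

test_that("invalid correlation targets are rejected", {
  expect_error(
    generator_config(planted_rho = rho_pair("5hmC", "H4K8ac", 1.0)),
    "\\|rho\\| < 1")
  expect_error(
    generator_config(planted_rho = rho_pair("5hmC", "H4K8ac", -1.2)),
    "\\|rho\\| < 1")
})

test_that("planted pairwise correlations are recovered in the intensities", {
  s <- generate_study(flat_config(
    n_genes = 5000, rho_pairs = rho_pair("5hmC", "H4K8ac", 0.7), seed = 5))
  gb <- study_region_counts(s, "gene_body", "ESC")
  expect_equal(cor(gb[["5hmC"]], gb[["H4K8ac"]]), 0.7, tolerance = 0.05 / 0.7)
  # an unplanted pair stays near zero
  expect_lt(abs(cor(gb[["5mC"]], gb[["H3K9me3"]])), 0.07)
})

test_that("planted group fractions match their binomial sampling bands", {
  s <- generate_study(generator_config(n_genes = 5000, seed = 9))
  frac_triv <- sum(s$truth$group == "trivalent")
  # exact binomial 99% interval around the configured 0.10
  band <- qbinom(c(0.005, 0.995), 5000, 0.10)
  expect_gte(frac_triv, band[1])
  expect_lte(frac_triv, band[2])
})

test_that("planted expression fold change is realized by the counts", {
  cfg <- generator_config(n_genes = 5000, expression_dispersion = 0.01,
                          seed = 13)
  s <- generate_study(cfg)
  esc_cols <- s$samples$sample_id[s$samples$cell_type == "ESC"]
  fib_cols <- s$samples$sample_id[s$samples$cell_type == "fibroblast"]
  mean_esc <- rowMeans(as.matrix(s$expression[esc_cols]))
  mean_fib <- rowMeans(as.matrix(s$expression[fib_cols]))
  obs_fc <- log2((mean_esc + 1) / (mean_fib + 1))
  triv <- s$truth$group == "trivalent"
  expect_equal(mean(obs_fc[triv]), 3, tolerance = 0.2 / 3)
  expect_equal(mean(obs_fc[s$truth$group == "background"]), 0,
               tolerance = 0.1)
})

test_that("study fixtures round-trip through write_study and read_study", {
  s <- generate_study(generator_config(n_genes = 30, seed = 21))
  # force at least one zero-count peak to check it is preserved
  s$peaks$score[1] <- 0L
  dir <- withr::local_tempdir()
  write_study(s, dir)
  back <- read_study(dir)
  expect_identical(back$annotation, s$annotation)
  ord <- function(p) dplyr::arrange(p, cell_type, factor, start, end)
  expect_identical(ord(back$peaks)[c("chrom", "start", "end", "factor",
                                     "score", "strand", "cell_type")],
                   ord(s$peaks)[c("chrom", "start", "end", "factor",
                                  "score", "strand", "cell_type")])
  expect_equal(as.data.frame(back$expression), as.data.frame(s$expression))
  expect_equal(as.data.frame(back$truth), as.data.frame(s$truth))
  expect_true(any(back$peaks$score == 0))
})

test_that("an empty study writes valid empty files", {
  cfg <- generator_config(n_genes = 0, chrom_length = 1e6)
  # bypass the group-size floor: an empty genome has no groups to draw
  ann <- generate_genome(cfg)
  expect_equal(nrow(ann), 0)
  s <- structure(list(
    annotation = ann,
    peaks = mk_peaks(integer(), integer(), character(), integer())[0, ] |>
      dplyr::mutate(cell_type = character()),
    expression = tibble::tibble(gene_id = character()),
    samples = tibble::tibble(sample_id = character(), cell_type = character()),
    truth = tibble::tibble(gene_id = character(), group = character(),
                           trivalent = logical(),
                           expression_log2fc = double()),
    config = cfg), class = "trimark_study")
  dir <- withr::local_tempdir()
  write_study(s, dir)
  back <- read_study(dir)
  expect_equal(nrow(back$annotation), 0)
  expect_equal(nrow(back$peaks), 0)
  expect_named(back$truth, c("gene_id", "group", "trivalent",
                             "expression_log2fc"))
})

test_that("peak splitting conserves total counts within each region", {
  cfg1 <- generator_config(n_genes = 40, seed = 8, split_peaks = 1)
  cfg3 <- generator_config(n_genes = 40, seed = 8, split_peaks = 3)
  s1 <- generate_study(cfg1)
  s3 <- generate_study(cfg3)
  tot1 <- s1$peaks |>
    dplyr::group_by(cell_type, factor) |>
    dplyr::summarise(total = sum(score), .groups = "drop")
  tot3 <- s3$peaks |>
    dplyr::group_by(cell_type, factor) |>
    dplyr::summarise(total = sum(score), .groups = "drop")
  expect_equal(tot1, tot3)
  expect_gt(nrow(s3$peaks), nrow(s1$peaks))
})

test_that("block matrices carry their planted structure", {
  bm <- simulate_block_matrix(n_per_block = 20, n_blocks = 3, snr = 5,
                              seed = 2)
  expect_true(all(bm$matrix >= 0))
  expect_equal(dim(bm$matrix), c(60, 12))
  # block means dominate their own feature blocks
  for (b in 1:3) {
    own <- mean(bm$matrix[bm$block == b, (4 * b - 3):(4 * b)])
    other <- mean(bm$matrix[bm$block == b, -((4 * b - 3):(4 * b))])
    expect_gt(own, other + 2)
  }
})

test_that("term catalogs plant a term inside the trivalent-stable genes", {
  s <- generate_study(generator_config(n_genes = 400, seed = 17))
  terms <- make_term_sets(s, n_terms = 10, seed = 17)
  expect_true("planted_trivalent_stable" %in% names(terms))
  stable <- s$truth$gene_id[s$truth$group == "trivalent_stable"]
  planted <- terms[["planted_trivalent_stable"]]
  expect_gt(mean(planted %in% stable), 0.7)
  expect_true(all(unlist(terms) %in% s$truth$gene_id))
})
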