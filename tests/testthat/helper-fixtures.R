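# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no data files.

# Small single-group config: homogeneous means, so sample correlations
# reflect the planted copula targets alone.
flat_config <- function(n_genes = 1000, rho_pairs = NULL, seed = 1, ...) {
  if (is.null(rho_pairs)) rho_pairs <- default_planted_rho()
  generator_config(
    n_genes = n_genes,
    group_fractions = c(background = 1),
    planted_rho = rho_pairs,
    seed = seed,
    ...
  )
}

rho_pair <- function(a, b, rho) {
  tibble::tibble(factor_a = a, factor_b = b, rho = rho)
}

# Tiny peak tibble helper.
mk_peaks <- function(start, end, factor, score, chrom = "chr1",
                     strand = ".", cell_type = NULL) {
  p <- tibble::tibble(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), factor = factor,
                      score = as.integer(score), strand = strand)
  if (!is.null(cell_type)) p$cell_type <- cell_type
  p
}

mk_regions <- function(start, end, region_id = NULL, chrom = "chr1") {
  if (is.null(region_id)) region_id <- sprintf("r%02d", seq_along(start))
  tibble::tibble(region_id = region_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end))
}

# Brute-force all-pairs overlap oracle for intensity assignment.
brute_force_intensity <- function(peaks, regions) {
  combos <- tidyr::expand_grid(region_id = regions$region_id,
                               factor = unique(peaks$factor))
  combos$intensity <- purrr::map2_dbl(
    combos$region_id, combos$factor, function(rid, fac) {
      rg <- regions[regions$region_id == rid, ]
      tot <- 0
      for (i in seq_len(nrow(peaks))) {
        if (peaks$factor[i] != fac) next
        if (peaks$chrom[i] != rg$chrom) next
        if (peaks$start[i] < rg$end && peaks$end[i] > rg$start) {
          tot <- tot + peaks$cpm[i]
        }
      }
      tot
    })
  combos
}

# Exact hypergeometric upper tail by enumerating all C(N, n) draws.
enumerate_enrichment_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  term <- seq_len(K)  # term genes are 1..K wlog
  hits <- apply(draws, 2, function(d) sum(d %in% term))
  mean(hits >= k)
}

# Adjusted Rand index (independent implementation for recovery tests when
# mclust is unavailable).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
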