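#' Canonical factor panel
#'
#' The default panel of 19 epigenetic factors: 5hmC and 5mC (DNA
#' modification assays) plus 17 histone modifications. Slots for the marks
#' with special roles downstream (5hmC, 5mC, H3K4me1, H4K8ac) are always
#' present.
#'
#' @return Character vector of 19 factor names.
#' @export
trimark_factors <- function() {
  c("5hmC", "5mC",
    "H3K4me1", "H3K4me2", "H3K4me3",
    "H3K9ac", "H3K9me3", "H3K14ac", "H3K18ac", "H3K23ac",
    "H3K27ac", "H3K27me3", "H3K36me3", "H3K79me2",
    "H4K5ac", "H4K8ac", "H4K12ac", "H4K16ac", "H4K20me1")
}

trimark_cell_types <- function() c("ESC", "fibroblast")

#' Default planted gene groups
#'
#' Five latent groups: an unmarked background; genes gaining only 5hmC in
#' ESCs; genes gaining 5hmC and H3K4me1; a trivalent group gaining 5hmC,
#' H3K4me1 and H4K8ac (and losing 5mC) with strongly elevated ESC
#' expression; and a trivalent "stable" group carrying the same marks but no
#' expression change (the moderately-expressed trivalent genes seen in the
#' NMF grouping).
#' @keywords internal
default_group_fractions <- function() {
  c(background = 0.65, hmc_only = 0.10, hmc_k4me1 = 0.10,
    trivalent = 0.10, trivalent_stable = 0.05)
}

default_expression_fc <- function() {
  c(background = 0, hmc_only = 0.5, hmc_k4me1 = 1.5,
    trivalent = 3, trivalent_stable = 0)
}

# Expected read count per (group, factor, cell type, region kind).
# Baseline means are flat across factors; marked groups multiply the ESC
# mean of their marks by `gain` (and 5mC by `loss` for trivalent groups).
default_group_means <- function(groups, factors,
                                base_gene_body = 500, base_promoter = 300,
                                gain = 5, loss = 0.2) {
  grid <- tidyr::expand_grid(
    group = groups, factor = factors,
    cell_type = trimark_cell_types(),
    region = c("gene_body", "promoter")
  )
  grid$mean_count <- ifelse(grid$region == "gene_body",
                            base_gene_body, base_promoter)
  marked <- list(
    hmc_only = "5hmC",
    hmc_k4me1 = c("5hmC", "H3K4me1"),
    trivalent = c("5hmC", "H3K4me1", "H4K8ac"),
    trivalent_stable = c("5hmC", "H3K4me1", "H4K8ac")
  )
  for (g in intersect(names(marked), groups)) {
    up <- grid$group == g & grid$cell_type == "ESC" & grid$factor %in% marked[[g]]
    grid$mean_count[up] <- grid$mean_count[up] * gain
    if (g %in% c("trivalent", "trivalent_stable")) {
      dn <- grid$group == g & grid$cell_type == "ESC" & grid$factor == "5mC"
      grid$mean_count[dn] <- grid$mean_count[dn] * loss
    }
  }
  tibble::as_tibble(grid)
}

default_planted_rho <- function() {
  tibble::tibble(
    factor_a = c("5hmC", "5hmC", "H3K4me1"),
    factor_b = c("H3K4me1", "H4K8ac", "H4K8ac"),
    rho = c(0.8, 0.7, 0.6)
  )
}

#' Configuration for the synthetic-study generator
#'
#' Bundles every knob of the generator: the gene universe, the factor panel,
#' planted gene groups with their expected intensities per cell type and
#' region, the pairwise correlation targets, and the expression model.
#'
#' The intensity model is gamma-Poisson: each gene carries a latent
#' multiplicative propensity per factor (gamma-distributed, mean 1, variance
#' `intensity_dispersion`), shared between the two cell types, and read
#' counts are Poisson around `group mean x propensity`. Correlation targets
#' in `planted_rho` are imposed on the propensities through a Gaussian
#' copula whose input correlation is adjusted (normal-to-anything) so the
#' realized Pearson correlation of the gamma margins hits the target.
#'
#' @param n_genes Number of genes to simulate.
#' @param chrom_length Length in bp of the single synthetic chromosome.
#'   Defaults to `50000 * n_genes`, enough for non-overlapping genes with
#'   >= 10 kb spacing.
#' @param factors Character vector of factor names (default the 19-factor
#'   panel of [trimark_factors()]).
#' @param group_fractions Named proportions of the planted gene groups; must
#'   sum to 1 and include a `trivalent` group.
#' @param group_mean_intensity Tibble `(group, factor, cell_type, region,
#'   mean_count)` of expected read counts; default built by the package
#'   (see Details in the vignette).
#' @param intensity_dispersion Variance of the gene-level multiplicative
#'   propensity (gamma, mean 1). Positive.
#' @param planted_rho Tibble `(factor_a, factor_b, rho)` of target Pearson
#'   correlations between factor propensities at gene bodies; `|rho| < 1`.
#' @param promoter_rho_scale Scale in `[0, 1]` applied to `planted_rho` for
#'   the promoter-region propensities; `0` makes the correlation plant
#'   strictly gene-body-localized.
#' @param expression_baseline Mean expression count in fibroblasts.
#' @param expression_dispersion Negative-binomial dispersion of expression
#'   counts (variance `mu + mu^2 * dispersion`).
#' @param expression_fc_by_group Named planted log2 fold change
#'   (ESC / fibroblast) of expression per group.
#' @param n_replicates Expression replicates per cell type.
#' @param split_peaks Number of sub-intervals each synthetic peak is
#'   fragmented into (total count conserved); 1 keeps one peak per region.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `trimark_config` (a validated list).
#' @export
generator_config <- function(n_genes = 2000,
                             chrom_length = NULL,
                             factors = trimark_factors(),
                             group_fractions = default_group_fractions(),
                             group_mean_intensity = NULL,
                             intensity_dispersion = 0.4,
                             planted_rho = default_planted_rho(),
                             promoter_rho_scale = 1,
                             expression_baseline = 100,
                             expression_dispersion = 0.05,
                             expression_fc_by_group = NULL,
                             n_replicates = 2,
                             split_peaks = 1,
                             seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes")
  if (is.null(chrom_length)) chrom_length <- 50000 * max(n_genes, 1)
  chrom_length <- assert_count(chrom_length, "chrom_length", min = 1)
  stopifnot(is.character(factors), length(factors) >= 2, !anyDuplicated(factors))

  if (is.null(names(group_fractions)) || any(names(group_fractions) == "")) {
    abort("`group_fractions` must be a named vector of proportions")
  }
  if (abs(sum(group_fractions) - 1) > 1e-8) {
    abort("`group_fractions` must sum to 1")
  }
  if (any(group_fractions < 0)) abort("`group_fractions` must be non-negative")
  groups <- names(group_fractions)

  if (is.null(group_mean_intensity)) {
    group_mean_intensity <- default_group_means(groups, factors)
  }
  assert_columns(group_mean_intensity,
                 c("group", "factor", "cell_type", "region", "mean_count"),
                 "group_mean_intensity")
  if (any(group_mean_intensity$mean_count <= 0)) {
    abort("all entries of `group_mean_intensity$mean_count` must be positive")
  }
  if (intensity_dispersion <= 0) abort("`intensity_dispersion` must be positive")
  if (expression_dispersion < 0) abort("`expression_dispersion` must be non-negative")
  if (expression_baseline <= 0) abort("`expression_baseline` must be positive")

  if (nrow(planted_rho) > 0) {
    assert_columns(planted_rho, c("factor_a", "factor_b", "rho"), "planted_rho")
    planted_rho <- dplyr::filter(planted_rho,
                                 .data$factor_a %in% factors,
                                 .data$factor_b %in% factors)
    if (any(abs(planted_rho$rho) >= 1)) {
      abort("planted correlation targets must satisfy |rho| < 1")
    }
  }
  stopifnot(promoter_rho_scale >= 0, promoter_rho_scale <= 1)

  if (is.null(expression_fc_by_group)) {
    fc <- default_expression_fc()
    expression_fc_by_group <- setNames(
      ifelse(groups %in% names(fc), fc[groups], 0), groups)
  }
  if (!all(groups %in% names(expression_fc_by_group))) {
    abort("`expression_fc_by_group` must name every group")
  }

  cfg <- list(
    n_genes = n_genes, chrom_length = chrom_length, factors = factors,
    group_fractions = group_fractions,
    group_mean_intensity = group_mean_intensity,
    intensity_dispersion = intensity_dispersion,
    planted_rho = tibble::as_tibble(planted_rho),
    promoter_rho_scale = promoter_rho_scale,
    expression_baseline = expression_baseline,
    expression_dispersion = expression_dispersion,
    expression_fc_by_group = expression_fc_by_group[groups],
    n_replicates = assert_count(n_replicates, "n_replicates", min = 1),
    split_peaks = assert_count(split_peaks, "split_peaks", min = 1),
    seed = assert_count(seed, "seed")
  )
  structure(cfg, class = "trimark_config")
}

# ---- normal-to-anything correlation adjustment ------------------------------

# Probabilists' Gauss-Hermite nodes/weights by Golub-Welsch.
gauss_hermite <- function(n = 32) {
  if (n == 1) return(list(x = 0, w = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
}

# Pearson correlation of gamma(shape, rate = shape) margins induced by a
# Gaussian copula with input correlation rho_z (quadrature, deterministic).
gamma_copula_cor <- function(rho_z, shape, gh = gauss_hermite(32)) {
  # clamp tail probabilities: the outermost quadrature nodes otherwise map
  # to qgamma(1) = Inf with negligible weight
  g <- function(z) qgamma(pmin(pmax(pnorm(z), 1e-15), 1 - 1e-15),
                          shape = shape, rate = shape)
  gx <- g(gh$x)
  exy <- 0
  s <- sqrt(max(0, 1 - rho_z^2))
  for (i in seq_along(gh$x)) {
    exy <- exy + gh$w[i] * gx[i] * sum(gh$w * g(rho_z * gh$x[i] + s * gh$x))
  }
  (exy - 1) * shape  # mean 1, variance 1/shape
}

# Input z-correlation whose gamma-margin Pearson correlation equals target.
norta_z_rho <- function(target, shape) {
  if (target == 0) return(0)
  f <- function(r) gamma_copula_cor(r, shape) - target
  upper <- 0.9999
  if (sign(f(upper * sign(target)) - 0) * sign(f(0)) > 0) {
    abort(sprintf("planted correlation %.3f unattainable for gamma shape %.3f",
                  target, shape))
  }
  stats::uniroot(f, interval = sort(c(0, upper * sign(target))),
                 tol = 1e-8)$root
}

# Build the copula correlation matrix over factors for the given targets.
build_copula_chol <- function(factors, planted_rho, shape, scale = 1) {
  R <- diag(length(factors))
  dimnames(R) <- list(factors, factors)
  if (nrow(planted_rho) > 0 && scale > 0) {
    for (i in seq_len(nrow(planted_rho))) {
      a <- planted_rho$factor_a[i]; b <- planted_rho$factor_b[i]
      z <- norta_z_rho(planted_rho$rho[i] * scale, shape)
      R[a, b] <- z; R[b, a] <- z
    }
  }
  ch <- tryCatch(chol(R), error = function(e) {
    abort("`planted_rho` does not define a positive-definite correlation structure")
  })
  ch
}

# ---- genome and study -------------------------------------------------------

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes (lengths 2-20 kb, inter-gene gaps
#' 10-30 kb, alternating strands) on one synthetic chromosome `chrS`.
#' Coordinates are 0-based half-open.
#'
#' @param config A [generator_config()].
#' @return Tibble `(gene_id, chrom, start, end, strand)`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "trimark_config"))
  n <- config$n_genes
  if (n == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  with_seed(derive_seed(config$seed, "genome"), {
    len <- floor(runif(n, 2000, 20000))
    gap <- floor(runif(n, 10000, 30000))
    start <- cumsum(gap) + cumsum(c(0, head(len, -1)))
    end <- start + len
    if (end[n] > config$chrom_length) {
      abort(sprintf(
        "cannot place %d genes with >=10 kb spacing on a %d bp chromosome",
        n, config$chrom_length))
    }
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = "chrS",
      start = as.integer(start),
      end = as.integer(end),
      strand = rep_len(c("+", "-"), n)
    )
  })
}

# Draw one region's gene x factor count matrix for both cell types, sharing
# the gene-level propensity between cells so cross-cell fold changes reflect
# the planted mean ratios plus Poisson noise only.
draw_region_counts <- function(n, factors, groups_of_gene, means, region,
                               chol_R, shape) {
  z <- matrix(rnorm(n * length(factors)), nrow = n) %*% chol_R
  propensity <- qgamma(pnorm(z), shape = shape, rate = shape)
  colnames(propensity) <- factors
  out <- list()
  for (cell in trimark_cell_types()) {
    mu_tab <- means[means$cell_type == cell & means$region == region, ]
    mu_lookup <- matrix(NA_real_, nrow = length(unique(mu_tab$group)),
                        ncol = length(factors),
                        dimnames = list(unique(mu_tab$group), factors))
    mu_lookup[cbind(mu_tab$group, mu_tab$factor)] <- mu_tab$mean_count
    mu <- mu_lookup[groups_of_gene, , drop = FALSE] * propensity
    cnt <- matrix(rpois(length(mu), lambda = mu), nrow = n,
                  dimnames = list(NULL, factors))
    out[[cell]] <- cnt
  }
  out
}

# Fragment peak rows into k sub-intervals conserving the total count.
split_peak_rows <- function(peaks, k) {
  if (k == 1) return(peaks)
  idx <- rep(seq_len(nrow(peaks)), each = k)
  sub <- peaks[idx, ]
  part <- rep(seq_len(k), times = nrow(peaks))
  w <- (sub$end - sub$start)
  cut <- sub$start + floor(w * (part - 1) / k)
  cut_end <- sub$start + floor(w * part / k)
  sub$start <- as.integer(cut)
  sub$end <- as.integer(cut_end)
  counts <- unlist(lapply(peaks$score, function(s) {
    as.vector(stats::rmultinom(1, size = s, prob = rep(1, k)))
  }))
  sub$score <- as.integer(counts)
  sub[sub$end > sub$start, ]
}

#' Generate a full synthetic study
#'
#' Draws per-gene latent groups, gamma-Poisson peak read counts at gene
#' bodies and promoter flanks for every factor and cell type (with the
#' configured planted correlations), negative-binomial expression counts
#' with planted per-group log2 fold changes between ESC and fibroblast, and
#' records the planted truth per gene.
#'
#' Synthetic promoter peaks are placed in the upstream flank
#' (`TSS - 4500` to `TSS - 500`) so gene-body and promoter signal remain
#' spatially separable; gene-body peaks span the annotated gene.
#'
#' @param config A [generator_config()].
#' @return An object of class `trimark_study`: a list with tibbles
#'   `annotation`, `peaks` (`chrom,start,end,factor,score,strand,cell_type`),
#'   `expression` (wide counts, one column per sample), `samples`
#'   (`sample_id, cell_type`), `truth` (`gene_id, group, trivalent,
#'   expression_log2fc`) and the `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "trimark_config"))
  n <- config$n_genes
  groups <- names(config$group_fractions)
  if (n < 2 * length(groups)) {
    abort("`n_genes` must be at least twice the number of planted groups")
  }
  annotation <- generate_genome(config)
  factors <- config$factors
  shape <- 1 / config$intensity_dispersion

  chol_gb <- build_copula_chol(factors, config$planted_rho, shape, scale = 1)
  chol_pm <- build_copula_chol(factors, config$planted_rho, shape,
                               scale = config$promoter_rho_scale)

  study <- with_seed(derive_seed(config$seed, "study"), {
    gene_group <- sample(groups, n, replace = TRUE,
                         prob = config$group_fractions)

    counts_gb <- draw_region_counts(n, factors, gene_group,
                                    config$group_mean_intensity, "gene_body",
                                    chol_gb, shape)
    counts_pm <- draw_region_counts(n, factors, gene_group,
                                    config$group_mean_intensity, "promoter",
                                    chol_pm, shape)

    # promoter peak interval: 4 kb in the upstream flank, strand-aware
    tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end)
    up <- annotation$strand == "+"
    pm_start <- ifelse(up, tss - 4500, tss + 500)
    pm_end <- ifelse(up, tss - 500, tss + 4500)
    pm_start <- pmax(pm_start, 0)
    pm_end <- pmin(pm_end, config$chrom_length)

    peak_block <- function(counts, start, end) {
      purrr::map_dfr(trimark_cell_types(), function(cell) {
        cnt <- counts[[cell]]
        tibble::tibble(
          chrom = rep(annotation$chrom, times = length(factors)),
          start = rep(as.integer(start), times = length(factors)),
          end = rep(as.integer(end), times = length(factors)),
          factor = rep(factors, each = n),
          score = as.integer(cnt),
          strand = ".",
          cell_type = cell
        )
      })
    }
    peaks <- dplyr::bind_rows(
      peak_block(counts_gb, annotation$start, annotation$end),
      peak_block(counts_pm, pm_start, pm_end)
    )
    peaks <- split_peak_rows(peaks, config$split_peaks)
    peaks <- dplyr::arrange(peaks, .data$cell_type, .data$factor,
                            .data$start, .data$end)

    # expression counts
    fc <- config$expression_fc_by_group[gene_group]
    mu_esc <- config$expression_baseline * 2^fc
    mu_fib <- rep(config$expression_baseline, n)
    draw_expr <- function(mu) {
      if (config$expression_dispersion < 1e-12) {
        rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), size = 1 / config$expression_dispersion, mu = mu)
      }
    }
    expr <- list()
    samples <- tibble::tibble(sample_id = character(), cell_type = character())
    for (cell in trimark_cell_types()) {
      mu <- if (cell == "ESC") mu_esc else mu_fib
      for (r in seq_len(config$n_replicates)) {
        sid <- sprintf("%s_%d", cell, r)
        expr[[sid]] <- draw_expr(mu)
        samples <- dplyr::add_row(samples, sample_id = sid, cell_type = cell)
      }
    }
    expression <- dplyr::bind_cols(
      tibble::tibble(gene_id = annotation$gene_id),
      tibble::as_tibble(expr)
    )

    truth <- tibble::tibble(
      gene_id = annotation$gene_id,
      group = gene_group,
      trivalent = gene_group %in% c("trivalent", "trivalent_stable"),
      expression_log2fc = unname(fc)
    )
    list(peaks = peaks, expression = expression, samples = samples,
         truth = truth)
  })

  structure(
    list(annotation = annotation, peaks = study$peaks,
         expression = study$expression, samples = study$samples,
         truth = study$truth, config = config),
    class = "trimark_study"
  )
}

#' @export
print.trimark_study <- function(x, ...) {
  cat(sprintf("<trimark_study> %d genes, %d factors, %d peaks, %d samples\n",
              nrow(x$annotation), length(x$config$factors),
              nrow(x$peaks), nrow(x$samples)))
  invisible(x)
}

#' Extract generated intensity columns directly from a study
#'
#' Returns the per-gene peak read counts of one region kind and cell type as
#' a wide tibble (gene x factor), bypassing interval quantification. Useful
#' for checking the planted structure against the quantified path.
#'
#' @param study A `trimark_study`.
#' @param region `"gene_body"` or `"promoter"`.
#' @param cell_type Cell type label.
#' @return Wide tibble `gene_id` plus one count column per factor.
#' @export
study_region_counts <- function(study, region = c("gene_body", "promoter"),
                                cell_type = "ESC") {
  region <- match.arg(region)
  ann <- study$annotation
  # identify region by interval: gene-body peaks start at (or within) the
  # annotated gene; promoter peaks lie in the upstream flank
  gr_regions <- if (region == "gene_body") {
    GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start + 1, ann$end))
  } else {
    tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    up <- ann$strand == "+"
    s <- pmax(ifelse(up, tss - 4500, tss + 500), 0)
    e <- pmin(ifelse(up, tss - 500, tss + 4500), study$config$chrom_length)
    GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(s + 1, e))
  }
  pk <- dplyr::filter(study$peaks, .data$cell_type == !!cell_type)
  gr_pk <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1, pk$end))
  hits <- GenomicRanges::findOverlaps(gr_pk, gr_regions, type = "within")
  agg <- tibble::tibble(
    gene_id = ann$gene_id[S4Vectors::subjectHits(hits)],
    factor = pk$factor[S4Vectors::queryHits(hits)],
    score = pk$score[S4Vectors::queryHits(hits)]
  ) %>%
    dplyr::group_by(.data$gene_id, .data$factor) %>%
    dplyr::summarise(count = sum(.data$score), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "factor", values_from = "count",
                       values_fill = 0)
  dplyr::left_join(tibble::tibble(gene_id = ann$gene_id), agg, by = "gene_id")
}

#' Synthetic planted-block matrix
#'
#' A non-negative genes x features matrix with `n_blocks` disjoint gene
#' blocks, each elevated over its own feature block; the elevation is
#' `snr * noise_sd` above baseline with additive Gaussian noise truncated at
#' zero. Used to exercise factorization-based grouping against known truth.
#'
#' @param n_per_block Genes per block.
#' @param features_per_block Features per block.
#' @param n_blocks Number of blocks.
#' @param snr Separation between on- and off-block means in noise-sd units.
#' @param noise_sd Noise standard deviation.
#' @param baseline Off-block mean.
#' @param seed Integer seed.
#' @return List with `matrix` (rownames `gene_id`) and integer vector
#'   `block` (the planted group of each row).
#' @export
simulate_block_matrix <- function(n_per_block = 50, features_per_block = 4,
                                  n_blocks = 4, snr = 3, noise_sd = 1,
                                  baseline = 1, seed = 1) {
  with_seed(seed, {
    n <- n_per_block * n_blocks
    p <- features_per_block * n_blocks
    block <- rep(seq_len(n_blocks), each = n_per_block)
    fblock <- rep(seq_len(n_blocks), each = features_per_block)
    mu <- matrix(baseline, n, p)
    for (b in seq_len(n_blocks)) {
      mu[block == b, fblock == b] <- baseline + snr * noise_sd
    }
    X <- pmax(mu + matrix(rnorm(n * p, sd = noise_sd), n, p), 0)
    rownames(X) <- sprintf("g%05d", seq_len(n))
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(matrix = X, block = block)
  })
}

#' Synthetic term catalog for enrichment testing
#'
#' Builds a synthetic annotation-term catalog: `n_terms` decoy terms drawn
#' uniformly from the gene universe plus one planted term concentrated in
#' the trivalent, expression-stable genes (the subgroup the enrichment
#' analysis is meant to flag). Entirely synthetic; no curated gene sets are
#' used.
#'
#' @param study A `trimark_study`.
#' @param n_terms Number of decoy terms.
#' @param term_size Mean decoy term size.
#' @param planted_coverage Fraction of the trivalent-stable genes included
#'   in the planted term.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors; the planted term is named
#'   `"planted_trivalent_stable"`.
#' @export
make_term_sets <- function(study, n_terms = 20, term_size = 60,
                           planted_coverage = 0.8,
                           seed = study$config$seed) {
  universe <- study$truth$gene_id
  stable <- study$truth$gene_id[study$truth$group == "trivalent_stable"]
  with_seed(derive_seed(seed, "terms"), {
    terms <- lapply(seq_len(n_terms), function(i) {
      size <- max(5, rpois(1, term_size))
      sort(sample(universe, min(size, length(universe))))
    })
    names(terms) <- sprintf("term_%02d", seq_len(n_terms))
    n_core <- max(1, floor(planted_coverage * length(stable)))
    planted <- sort(c(
      sample(stable, n_core),
      sample(setdiff(universe, stable), max(2, floor(n_core * 0.1)))
    ))
    terms[["planted_trivalent_stable"]] <- planted
    terms
  })
}
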