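# Differential-expression classification between cell types and per-gene
# factor fold changes. Genes are labelled up / down / non by the rule:
# up   <=> q <= fdr AND log2 FC >=  log2(min_fc)
# down <=> q <= fdr AND log2 FC <= -log2(min_fc)
# with fold changes oriented ESC / fibroblast (positive = higher in ESC).

# Vectorized Welch two-sample t-test over matrix rows.
welch_rows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1, var)
  v2 <- apply(x[, idx2, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero variance in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

#' Classify genes as differentially expressed between cell types
#'
#' Normalizes counts to CPM per sample, tests each gene on
#' `log2(CPM + 1)` across replicates, adjusts p-values by
#' Benjamini-Hochberg over all genes, and labels genes `up` / `down` /
#' `non` at the given FDR and minimum fold change. The fold change is
#' `log2((mean CPM in ESC + c) / (mean CPM in fibroblast + c))` with
#' pseudocount `c = 1` CPM.
#'
#' Two test statistics are available. The default, `"moderated"`, is the
#' limma empirical-Bayes moderated t-statistic with a mean-variance trend
#' (limma-trend), which borrows variance information across genes — with
#' the 2-3 replicates typical of these designs, a per-gene variance
#' estimate has too few degrees of freedom to clear genome-wide FDR
#' control even for large fold changes. `"welch"` is a plain per-gene
#' Welch two-sample t-test.
#'
#' With a single replicate per cell type no test is possible: genes are
#' classified on fold change alone and `q` is `NA` (with a warning).
#'
#' @param counts Wide tibble: `gene_id` plus one integer count column per
#'   sample.
#' @param samples Tibble `(sample_id, cell_type)` covering every count
#'   column; exactly two cell types.
#' @param fdr FDR threshold (default 0.05).
#' @param min_fc Minimum linear fold change (default 2, i.e. |log2 FC| >= 1).
#' @param numerator Cell type placed in the fold-change numerator (default
#'   `"ESC"`); the other cell type is the denominator.
#' @param method `"moderated"` (limma-trend, default) or `"welch"`.
#' @return Tibble `(gene_id, label, log2_expression_fc, p_value, q_value)`
#'   with `label` in `up`, `down`, `non`.
#' @export
deg_classify <- function(counts, samples, fdr = 0.05, min_fc = 2,
                         numerator = "ESC",
                         method = c("moderated", "welch")) {
  method <- match.arg(method)
  assert_columns(counts, "gene_id", "counts")
  assert_columns(samples, c("sample_id", "cell_type"), "samples")
  sample_cols <- setdiff(names(counts), "gene_id")
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples sheet missing cell-type labels for: %s",
                  paste(missing, collapse = ", ")))
  }
  cells <- unique(samples$cell_type)
  if (length(cells) != 2 || !numerator %in% cells) {
    abort("`samples` must contain exactly two cell types including `numerator`")
  }
  denominator <- setdiff(cells, numerator)

  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(m < 0) || any(m != floor(m))) {
    abort("expression counts must be non-negative integers")
  }
  lib <- colSums(m)
  if (any(lib == 0)) abort("sample(s) with zero total count")
  cpm <- sweep(m, 2, lib, "/") * 1e6

  cell_of <- setNames(samples$cell_type, samples$sample_id)[sample_cols]
  idx_num <- which(cell_of == numerator)
  idx_den <- which(cell_of == denominator)

  pseudo <- 1
  fc <- log2((rowMeans(cpm[, idx_num, drop = FALSE]) + pseudo) /
               (rowMeans(cpm[, idx_den, drop = FALSE]) + pseudo))

  if (length(idx_num) < 2 || length(idx_den) < 2) {
    warn("single replicate per cell type: classifying on fold change alone (q = NA)")
    p <- rep(NA_real_, nrow(m))
    q <- rep(NA_real_, nrow(m))
    signif <- rep(TRUE, nrow(m))
  } else {
    logcpm <- log2(cpm + 1)
    p <- if (method == "moderated") {
      design <- cbind(intercept = 1,
                      diff = as.numeric(cell_of == numerator))
      # zero-variance rows (e.g. all-identical counts) are offset by limma
      # internally; its advisory warning is redundant here
      mfit <- suppressWarnings(
        limma::eBayes(limma::lmFit(logcpm, design), trend = TRUE))
      unname(mfit$p.value[, "diff"])
    } else {
      welch_rows(logcpm, idx_num, idx_den)
    }
    q <- bh_adjust(p)
    signif <- q <= fdr
  }

  thr <- log2(min_fc)
  label <- dplyr::case_when(
    signif & fc >= thr ~ "up",
    signif & fc <= -thr ~ "down",
    TRUE ~ "non"
  )
  tibble::tibble(gene_id = counts$gene_id, label = label,
                 log2_expression_fc = fc, p_value = p, q_value = q)
}

#' Per-gene factor log2 fold changes between cell types
#'
#' Elementwise `log2((I_num + c) / (I_den + c))` between two intensity
#' tables sharing gene and factor labels. Positive values mean higher
#' intensity in the numerator cell type (ESC by convention).
#'
#' @param intensity_num,intensity_den Wide gene x factor tables (first
#'   column the gene id) for numerator (ESC) and denominator (fibroblast).
#' @param pseudocount Positive pseudocount `c` (default 1 CPM).
#' @return Wide tibble `gene_id` plus one log2-fold-change column per
#'   factor.
#' @export
factor_log2fc <- function(intensity_num, intensity_den, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive")
  a <- as_feature_matrix(intensity_num)
  b <- as_feature_matrix(intensity_den)
  if (!identical(dimnames(a), dimnames(b))) {
    abort("intensity tables must share identical gene and factor labels")
  }
  fc <- log2((a + pseudocount) / (b + pseudocount))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(fc)),
                   tibble::as_tibble(fc))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
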