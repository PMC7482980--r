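# Pairwise correlation screen between factor intensity columns at each
# region kind (1-kb bins, gene bodies, promoters).

#' Pairwise correlation between factor intensity columns
#'
#' Computes the Pearson (product-moment) or Spearman (average-rank)
#' correlation between every pair of factor columns over regions. Constant
#' columns have undefined correlation and yield `NA` (never 0).
#'
#' @param intensity Wide region x factor table (first column the region id;
#'   see [intensity_wide()]) or a numeric matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param drop_empty Drop regions whose intensity is zero for every factor
#'   before correlating (default `FALSE`; the genome-wide bin screen in
#'   [run_pipeline()] enables it).
#' @return Object of class `trimark_corr`: list with the symmetric
#'   correlation `matrix` (unit diagonal), `method` and `n_regions`.
#' @export
pairwise_correlation <- function(intensity,
                                 method = c("pearson", "spearman"),
                                 drop_empty = FALSE) {
  method <- match.arg(method)
  m <- as_feature_matrix(intensity)
  if (drop_empty) m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 3) abort("at least 3 regions are required")
  if (ncol(m) < 2) abort("at least 2 factors are required")

  constant <- apply(m, 2, function(x) sd(x) == 0 || !all(is.finite(x)))
  r <- suppressWarnings(cor(m, method = method))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  structure(list(matrix = r, method = method, n_regions = nrow(m)),
            class = "trimark_corr")
}

#' @export
print.trimark_corr <- function(x, ...) {
  cat(sprintf("<trimark_corr> %s, %d factors, %d regions\n",
              x$method, ncol(x$matrix), x$n_regions))
  print(round(x$matrix, 2))
  invisible(x)
}

#' @describeIn pairwise_correlation Tidy a correlation object into one row
#'   per unordered factor pair (self-pairs excluded).
#' @param x A `trimark_corr`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trimark_corr <- function(x, ...) {
  r <- x$matrix
  labs <- colnames(r)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble::tibble(
    factor_a = labs[idx[, 1]],
    factor_b = labs[idx[, 2]],
    method = x$method,
    r = r[idx],
    n = x$n_regions
  )
}

#' Long-format correlation report across region kinds
#'
#' Serializes one or more correlation matrices (one per region kind) into a
#' single long table with one row per unordered factor pair. Pairs whose
#' correlation is undefined (constant column) are dropped with a warning.
#'
#' @param matrices Named list of `trimark_corr` objects, names = region
#'   kinds. All must share identical factor labels.
#' @return Tibble `(region_kind, factor_a, factor_b, method, r, n)`.
#' @export
correlation_report <- function(matrices) {
  if (length(matrices) == 0) {
    return(tibble::tibble(region_kind = character(), factor_a = character(),
                          factor_b = character(), method = character(),
                          r = double(), n = integer()))
  }
  labs <- lapply(matrices, function(m) colnames(m$matrix))
  if (!all(vapply(labs, identical, logical(1), y = labs[[1]]))) {
    abort("all correlation matrices must share the same factor labels")
  }
  out <- purrr::imap_dfr(matrices, function(m, kind) {
    dplyr::mutate(tidy(m), region_kind = kind, .before = 1)
  })
  if (anyNA(out$r)) {
    warn(sprintf(
      "dropping %d factor pair(s) with undefined correlation (constant column)",
      sum(is.na(out$r))))
    out <- dplyr::filter(out, !is.na(.data$r))
  }
  out
}

#' Heatmap of a factor correlation matrix
#'
#' @param x A `trimark_corr`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trimark_corr <- function(x, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(x$matrix, rownames = "factor_a"),
    -"factor_a", names_to = "factor_b", values_to = "r")
  lv <- colnames(x$matrix)
  df$factor_a <- factor(df$factor_a, levels = lv)
  df$factor_b <- factor(df$factor_b, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$factor_a, .data$factor_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s correlation (%d regions)",
                                  x$method, x$n_regions)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
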