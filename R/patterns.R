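# Combinatorial classification of genes by the joint direction of factor
# fold changes (default factor set: 5hmC, 5mC, H3K4me1, H4K8ac), trivalent
# mark flagging, mark-count strata, and per-pattern expression summaries.

pattern_factors_default <- function() c("5hmC", "5mC", "H3K4me1", "H4K8ac")
trivalent_marks <- function() c("5hmC", "H3K4me1", "H4K8ac")

#' Encode per-gene ternary fold-change patterns
#'
#' Each factor's log2 fold change is mapped to `+` (>= `up_log2`), `-`
#' (<= `down_log2`) or `0` (in between); the per-gene pattern is the
#' concatenation over `factors` in order. Boundaries are inclusive.
#'
#' @param fc_table Wide gene x factor log2-fold-change tibble (first column
#'   `gene_id`; see [factor_log2fc()]).
#' @param factors Ordered factor subset to encode (default the four-mark
#'   panel 5hmC, 5mC, H3K4me1, H4K8ac).
#' @param up_log2,down_log2 State thresholds in log2 units (defaults +1 /
#'   -1, i.e. two-fold).
#' @return Tibble `(gene_id, pattern)` with patterns like `"+-0+"`.
#' @export
encode_patterns <- function(fc_table, factors = pattern_factors_default(),
                            up_log2 = 1, down_log2 = -1) {
  assert_columns(fc_table, c("gene_id", factors), "fc_table")
  if (up_log2 <= down_log2) abort("`up_log2` must exceed `down_log2`")
  m <- as.matrix(fc_table[, factors, drop = FALSE])
  if (any(!is.finite(m))) abort("fold changes must be finite (no NaN/NA)")
  st <- matrix("0", nrow(m), ncol(m))
  st[m >= up_log2] <- "+"
  st[m <= down_log2] <- "-"
  tibble::tibble(
    gene_id = fc_table$gene_id,
    pattern = apply(st, 1, paste0, collapse = "")
  )
}

#' Group genes by identical fold-change pattern
#'
#' Partitions the gene universe by ternary pattern code. Patterns are
#' ranked by descending size (ties by code); patterns smaller than
#' `min_size` are pooled into a `rare` catch-all, reported separately via
#' the `is_rare` flag.
#'
#' @inheritParams encode_patterns
#' @param min_size Minimum pattern size kept as its own group.
#' @return Object of class `trimark_patterns`: list with `assignment`
#'   (`gene_id, pattern, pattern_id, is_rare`) and `patterns` (`pattern_id,
#'   pattern, n, is_rare`, size-ordered). `tidy()` returns the assignment.
#' @export
cluster_by_pattern <- function(fc_table, factors = pattern_factors_default(),
                               up_log2 = 1, down_log2 = -1, min_size = 5) {
  if (nrow(fc_table) == 0) abort("`fc_table` must be non-empty")
  enc <- encode_patterns(fc_table, factors, up_log2, down_log2)
  sizes <- enc %>%
    dplyr::count(.data$pattern, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$pattern)
  sizes$is_rare <- sizes$n < min_size
  kept <- dplyr::filter(sizes, !.data$is_rare)
  kept$pattern_id <- sprintf("P%02d", seq_len(nrow(kept)))
  rare <- dplyr::filter(sizes, .data$is_rare)
  if (nrow(rare) > 0) rare$pattern_id <- "rare"
  sizes <- dplyr::bind_rows(kept, rare)

  assignment <- enc %>%
    dplyr::left_join(dplyr::select(sizes, "pattern", "pattern_id", "is_rare"),
                     by = "pattern")
  structure(
    list(
      assignment = assignment,
      patterns = dplyr::select(sizes, "pattern_id", "pattern", "n", "is_rare"),
      factors = factors,
      thresholds = c(up_log2 = up_log2, down_log2 = down_log2),
      min_size = min_size
    ),
    class = "trimark_patterns"
  )
}

#' @export
print.trimark_patterns <- function(x, ...) {
  cat(sprintf("<trimark_patterns> %d genes, %d patterns (+%d rare pooled) over [%s]\n",
              nrow(x$assignment), sum(!x$patterns$is_rare),
              sum(x$patterns$is_rare), paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' @describeIn cluster_by_pattern Tidy method: the per-gene assignment.
#' @param x A `trimark_patterns`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trimark_patterns <- function(x, ...) x$assignment

#' Flag trivalent-mark genes
#'
#' A gene is enriched for a mark if the linear fold change of that mark's
#' intensity (ESC over fibroblast) is strictly greater than `fc_threshold`;
#' it is trivalent when all three marks (5hmC, H3K4me1, H4K8ac) are
#' enriched.
#'
#' @param fc_table Wide gene x factor log2-fold-change tibble containing
#'   the three mark columns.
#' @param fc_threshold Linear fold-change threshold (default 2; strict
#'   inequality).
#' @return Tibble `(gene_id, flag_5hmC, flag_H3K4me1, flag_H4K8ac, n_marks,
#'   trivalent)`.
#' @export
trivalent_flag <- function(fc_table, fc_threshold = 2) {
  marks <- trivalent_marks()
  assert_columns(fc_table, c("gene_id", marks), "fc_table")
  thr <- log2(fc_threshold)
  flags <- lapply(marks, function(f) fc_table[[f]] > thr)
  names(flags) <- paste0("flag_", marks)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = fc_table$gene_id),
                          tibble::as_tibble(flags))
  out$n_marks <- rowSums(as.matrix(out[paste0("flag_", marks)]))
  out$trivalent <- out$n_marks == 3
  out
}

#' Expression summaries across mark-count strata
#'
#' Among genes with 5hmC enrichment in ESCs (linear 5hmC fold change >
#' `membership_fc`), forms three strata by mark combination: 5hmC only,
#' 5hmC + H3K4me1 only, and trivalent (all three marks), where individual
#' marks are flagged at `flag_fc` (see [trivalent_flag()]). Summarizes the
#' expression log2 fold change per stratum.
#'
#' @param flags Output of [trivalent_flag()].
#' @param fc_table The fold-change table used for flagging (for the 5hmC
#'   membership filter).
#' @param expression_fc Tibble `(gene_id, log2_expression_fc)` (e.g. from
#'   [deg_classify()]).
#' @param membership_fc Linear 5hmC fold change required for stratum
#'   membership (default 1: any 5hmC gain).
#' @return List with `summary` (`stratum, n, median_expression_log2fc`) and
#'   `members` (`gene_id, stratum`). Strata are ordered 5hmC_only,
#'   5hmC_H3K4me1, trivalent.
#' @export
mark_count_strata <- function(flags, fc_table, expression_fc,
                              membership_fc = 1) {
  assert_columns(flags, c("gene_id", "flag_5hmC", "flag_H3K4me1",
                          "flag_H4K8ac"), "flags")
  assert_columns(expression_fc, c("gene_id", "log2_expression_fc"),
                 "expression_fc")
  eligible <- fc_table$gene_id[fc_table[["5hmC"]] > log2(membership_fc)]
  df <- flags %>%
    dplyr::filter(.data$gene_id %in% eligible) %>%
    dplyr::mutate(stratum = dplyr::case_when(
      .data$flag_5hmC & .data$flag_H3K4me1 & .data$flag_H4K8ac ~ "trivalent",
      .data$flag_5hmC & .data$flag_H3K4me1 & !.data$flag_H4K8ac ~ "5hmC_H3K4me1",
      .data$flag_5hmC & !.data$flag_H3K4me1 & !.data$flag_H4K8ac ~ "5hmC_only",
      TRUE ~ NA_character_
    )) %>%
    dplyr::filter(!is.na(.data$stratum)) %>%
    dplyr::left_join(dplyr::select(expression_fc, "gene_id",
                                   "log2_expression_fc"), by = "gene_id")
  lv <- c("5hmC_only", "5hmC_H3K4me1", "trivalent")
  summary <- df %>%
    dplyr::mutate(stratum = factor(.data$stratum, levels = lv)) %>%
    dplyr::group_by(.data$stratum, .drop = FALSE) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_expression_log2fc = median(.data$log2_expression_fc),
      .groups = "drop")
  list(summary = summary,
       members = dplyr::select(df, "gene_id", "stratum"))
}

#' Per-pattern expression statistics
#'
#' For each fold-change pattern: size, median and quartiles of the
#' expression log2 fold change, and the fraction of genes labelled `up`.
#' Genes outside the intersection of the two tables are dropped with a
#' warning.
#'
#' @param patterns A `trimark_patterns` from [cluster_by_pattern()].
#' @param deg_table Tibble `(gene_id, label, log2_expression_fc)` from
#'   [deg_classify()].
#' @return Tibble `(pattern_id, pattern, n, median_fc, q1_fc, q3_fc,
#'   frac_up, is_rare)` ordered by descending size.
#' @export
pattern_expression_summary <- function(patterns, deg_table) {
  stopifnot(inherits(patterns, "trimark_patterns"))
  assert_columns(deg_table, c("gene_id", "label", "log2_expression_fc"),
                 "deg_table")
  asg <- patterns$assignment
  common <- intersect(asg$gene_id, deg_table$gene_id)
  if (length(common) < nrow(asg) || length(common) < nrow(deg_table)) {
    warn("gene universes differ; restricting to their intersection")
  }
  asg %>%
    dplyr::inner_join(deg_table, by = "gene_id") %>%
    dplyr::group_by(.data$pattern_id, .data$pattern, .data$is_rare) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_fc = median(.data$log2_expression_fc),
      q1_fc = quantile(.data$log2_expression_fc, 0.25, names = FALSE),
      q3_fc = quantile(.data$log2_expression_fc, 0.75, names = FALSE),
      frac_up = mean(.data$label == "up"),
      .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Boxplot-style summary plot of expression change per pattern
#'
#' @param summary Output of [pattern_expression_summary()].
#' @return A ggplot object (median point, interquartile bar per pattern).
#' @export
plot_pattern_expression <- function(summary) {
  df <- dplyr::mutate(summary,
                      pattern_lab = paste0(.data$pattern_id, " ",
                                           .data$pattern))
  df$pattern_lab <- factor(df$pattern_lab, levels = df$pattern_lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern_lab)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q1_fc,
                                         ymax = .data$q3_fc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_fc), size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "fold-change pattern (size order)",
                  y = "expression log2 FC (ESC / fibroblast)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
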