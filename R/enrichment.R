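# Over-representation analysis of gene groups against annotation term sets:
# exact upper-tail hypergeometric test per term with Benjamini-Hochberg
# correction across terms.

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the overlap between the query gene set and
#' the term members (both intersected with the universe) exceeds chance:
#' `p = P(X >= k)` for hypergeometric X with `K` term genes among `N`
#' universe genes and `n` draws (the query size). Terms with no member in
#' the universe are skipped. Rows are sorted by `q`, then `p`, then term.
#'
#' @param query Character vector of gene ids; must be contained in
#'   `universe` (violations are dropped with a warning).
#' @param universe Character vector of background gene ids.
#' @param annotations Named list of character vectors (term -> member gene
#'   ids), e.g. from [read_gmt()].
#' @return Tibble `(term, k, K, n, N, p, q)`.
#' @export
hypergeometric_enrichment <- function(query, universe, annotations) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe were dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)

  rows <- purrr::imap_dfr(annotations, function(members, term) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    tibble::tibble(term = term, k = k, K = K, n = n, N = N,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = double(),
                          q = double()))
  }
  rows$q <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$q, .data$p, .data$term)
}

#' Subgroup enrichment mirroring the DEG split
#'
#' Splits a gene group by differential-expression label (`up` / `down` /
#' `non`) and runs [hypergeometric_enrichment()] separately per subgroup.
#' Empty subgroups yield no rows.
#'
#' @param group_genes Character vector of gene ids in the group.
#' @param deg_labels Tibble `(gene_id, label)` covering the group genes.
#' @param annotations Named list of term gene sets.
#' @param universe Background gene ids (default: all genes in
#'   `deg_labels`).
#' @return Tibble with a leading `subgroup` column followed by the
#'   enrichment columns.
#' @export
subgroup_enrichment <- function(group_genes, deg_labels, annotations,
                                universe = deg_labels$gene_id) {
  assert_columns(deg_labels, c("gene_id", "label"), "deg_labels")
  missing <- setdiff(group_genes, deg_labels$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("%d group gene(s) have no DEG label", length(missing)))
  }
  lab <- setNames(deg_labels$label, deg_labels$gene_id)[group_genes]
  purrr::map_dfr(c("up", "down", "non"), function(l) {
    sub <- group_genes[lab == l]
    if (length(sub) == 0) return(NULL)
    res <- hypergeometric_enrichment(sub, universe, annotations)
    dplyr::mutate(res, subgroup = l, .before = 1)
  })
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, tab-separated gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readr::read_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
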