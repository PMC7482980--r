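# Nonnegative matrix factorization of the gene x (factor x region)
# intensity matrix, with multi-restart consensus clustering and cophenetic
# rank selection, argmax-W group assignment and binarized group profiles.
#
# The factorization minimizes the squared Frobenius reconstruction error
# ||X - WH||_F^2 by Lee-Seung multiplicative updates, which guarantee a
# non-increasing objective at every iteration (asserted in the tests).

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `X ~ W H` (`W`: genes x k, `H`: k x
#' features) minimizing `||X - WH||_F^2`. Factors are initialized uniform
#' on (0, 1] scaled to the matrix mean, updated multiplicatively, and
#' iteration stops when the relative objective change falls below `tol` or
#' at `max_iter`.
#'
#' @param X Non-negative numeric matrix (or wide tibble, first column ids).
#' @param k Rank, `1 <= k < min(dim(X))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @return Object of class `trimark_nmf_fit`: list with `W`, `H`, the
#'   objective `trace` (value per iteration, starting from the initial
#'   factors), `k`, `seed`, `iterations`, `converged`.
#' @export
nmf_factorize <- function(X, k, seed = 1, max_iter = 2000, tol = 1e-6) {
  X <- as_feature_matrix(X)
  if (any(X < 0)) abort("`X` must be non-negative")
  if (any(!is.finite(X))) abort("`X` must be finite")
  k <- assert_count(k, "k", min = 1)
  if (k >= min(dim(X))) abort("`k` must be smaller than both dimensions of `X`")

  n <- nrow(X); p <- ncol(X)
  eps <- .Machine$double.eps
  scale <- sqrt(max(mean(X), eps) / k)
  init <- with_seed(seed, {
    list(W = matrix(runif(n * k), n, k) * scale,
         H = matrix(runif(k * p), k, p) * scale)
  })
  W <- init$W; H <- init$H

  obj <- function(W, H) sum((X - W %*% H)^2)
  trace <- numeric(max_iter + 1)
  trace[1] <- obj(W, H)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    trace[it + 1] <- obj(W, H)
    if (trace[it] - trace[it + 1] < tol * max(trace[it], eps)) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[seq_len(it + 1)]
  dimnames(W) <- list(rownames(X), paste0("grp", seq_len(k)))
  dimnames(H) <- list(paste0("grp", seq_len(k)), colnames(X))
  structure(list(W = W, H = H, trace = trace, k = k, seed = seed,
                 iterations = it, converged = converged),
            class = "trimark_nmf_fit")
}

#' @export
print.trimark_nmf_fit <- function(x, ...) {
  cat(sprintf("<trimark_nmf_fit> rank %d, %d x %d, %d iterations, objective %.4g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations,
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Assign genes to groups by their dominant factorization component
#'
#' Group = argmax over the gene's row of `W`; ties break to the lowest
#' group index. All-zero rows cannot be assigned and get group 0 with a
#' warning.
#'
#' @param W Non-negative genes x k matrix (or a `trimark_nmf_fit`).
#' @return Integer vector of group indices (named by gene when `W` has
#'   rownames).
#' @export
assign_groups <- function(W) {
  if (inherits(W, "trimark_nmf_fit")) W <- W$W
  stopifnot(is.matrix(W))
  g <- max.col(W, ties.method = "first")
  zero <- rowSums(W) == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero row(s) in W assigned group 0", sum(zero)))
    g[zero] <- 0L
  }
  setNames(as.integer(g), rownames(W))
}

#' Consensus matrix over factorization restarts
#'
#' Runs `n_restarts` factorizations at rank `k` from different random
#' initializations (seeds `seed + 0:(n_restarts-1)`); entry (i, j) of the
#' consensus is the fraction of restarts in which genes i and j fall in the
#' same argmax-W group.
#'
#' @inheritParams nmf_factorize
#' @param n_restarts Number of restarts (>= 2).
#' @return Symmetric genes x genes matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_matrix <- function(X, k, n_restarts = 30, seed = 1,
                             max_iter = 2000, tol = 1e-6) {
  n_restarts <- assert_count(n_restarts, "n_restarts", min = 2)
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  cons <- matrix(0, n, n)
  for (r in seq_len(n_restarts)) {
    fit <- nmf_factorize(Xm, k, seed = seed + r - 1, max_iter = max_iter,
                         tol = tol)
    g <- suppressWarnings(assign_groups(fit$W))
    cons <- cons + outer(g, g, "==")
  }
  cons <- cons / n_restarts
  diag(cons) <- 1
  dimnames(cons) <- list(rownames(Xm), rownames(Xm))
  cons
}

# Euclidean distances between matrix rows via the Gram matrix (BLAS-backed;
# much faster than stats::dist for the wide consensus matrices used here).
euclidean_rows_dist <- function(m) {
  g <- tcrossprod(m)
  rs <- diag(g)
  d2 <- outer(rs, rs, "+") - 2 * g
  d2[d2 < 0] <- 0
  stats::as.dist(sqrt(d2))
}

#' Cophenetic correlation of a consensus matrix
#'
#' Genes are clustered hierarchically (complete linkage) on distances
#' derived from the consensus matrix — Euclidean distances between
#' consensus rows by default, or `1 - consensus` directly — and the
#' cophenetic coefficient is the Pearson correlation between the original
#' distances and the dendrogram-implied (cophenetic) distances. When all
#' pairwise distances are equal (a perfectly flat hierarchy, e.g. perfect
#' block consensus collapses to this after merging) the coefficient is 1 by
#' convention.
#'
#' @param consensus Symmetric consensus matrix from [consensus_matrix()].
#' @param distance `"euclidean-rows"` (default) or `"one-minus"`.
#' @return Single value in `[0, 1]` (can be slightly negative for
#'   pathological consensus structures, as with any Pearson correlation).
#' @export
cophenetic_coefficient <- function(consensus,
                                   distance = c("euclidean-rows",
                                                "one-minus")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus))
  if (nrow(consensus) < 3) abort("at least 3 genes are required")
  d <- if (distance == "euclidean-rows") {
    euclidean_rows_dist(consensus)
  } else {
    stats::as.dist(1 - consensus)
  }
  hc <- hclust(d, method = "complete")
  cp <- cophenetic(hc)
  if (sd(d) == 0 || sd(cp) == 0) return(1)
  cor(as.vector(d), as.vector(cp))
}

# Rank rules operating on the (rank, cophenetic) curve.
#
# "first-decrease": scan ascending, adopt the last rank before the first
# strict decrease of the cophenetic value; a never-decreasing curve falls
# back to the maximum rank (with a warning), an immediately-decreasing one
# to the minimum. Strictness uses a 1e-12 numerical guard. This is the
# literal reading of the classical rule, and is exact on clean curves that
# sit on a plateau and then fall.
#
# "max-stability": the largest rank attaining the maximum cophenetic value
# (within 1e-9). On clean unimodal curves both rules agree; under restart-
# sampling noise — sub-optimal ranks merge planted groups in different ways
# across restarts, jittering their cophenetic values by ~0.01 while the
# true rank sits at 1.0 — the first-decrease rule can stop one noise-dip
# early, so max-stability is the default.
rank_from_cophenetic_curve <- function(ranks, coph,
                                       rule = c("max-stability",
                                                "first-decrease")) {
  rule <- match.arg(rule)
  stopifnot(length(ranks) == length(coph), !is.unsorted(ranks))
  if (rule == "max-stability") {
    at_max <- which(coph >= max(coph) - 1e-9)
    return(ranks[at_max[length(at_max)]])
  }
  drop_at <- which(diff(coph) < -1e-12)
  if (length(drop_at) == 0) {
    warn("cophenetic curve never decreases over the scanned ranks; returning the maximum rank")
    return(ranks[length(ranks)])
  }
  ranks[drop_at[1]]
}

#' Select the factorization rank by the cophenetic rule
#'
#' Scans candidate ranks in ascending order, computing the consensus
#' cophenetic coefficient at each, and returns the last rank before the
#' first strict decrease. If the curve never decreases the maximum rank is
#' returned with a warning; if it decreases immediately, the minimum rank.
#'
#' @inheritParams consensus_matrix
#' @param ranks Integer vector of candidate ranks (default `2:10`),
#'   ascending.
#' @param distance Consensus distance passed to
#'   [cophenetic_coefficient()].
#' @param rule `"max-stability"` (default): the largest rank attaining the
#'   maximum cophenetic value; `"first-decrease"`: the literal sequential
#'   rule. The two agree on clean plateau-then-fall curves; max-stability
#'   is robust to the ~0.01 restart-sampling jitter of sub-optimal ranks.
#' @return Object of class `trimark_rank_scan`: list with `k_star` and the
#'   `scan` tibble `(rank, cophenetic)`. `tidy()` returns the scan.
#' @export
select_rank <- function(X, ranks = 2:10, n_restarts = 30, seed = 1,
                        max_iter = 2000, tol = 1e-6,
                        distance = c("euclidean-rows", "one-minus"),
                        rule = c("max-stability", "first-decrease")) {
  distance <- match.arg(distance)
  rule <- match.arg(rule)
  if (length(ranks) == 0) abort("`ranks` must be non-empty")
  ranks <- sort(unique(as.integer(ranks)))
  coph <- vapply(ranks, function(k) {
    cons <- consensus_matrix(X, k, n_restarts = n_restarts,
                             seed = derive_seed(seed, paste0("rank", k)),
                             max_iter = max_iter, tol = tol)
    cophenetic_coefficient(cons, distance = distance)
  }, numeric(1))

  k_star <- rank_from_cophenetic_curve(ranks, coph, rule = rule)
  structure(list(k_star = k_star,
                 scan = tibble::tibble(rank = ranks, cophenetic = coph),
                 distance = distance, n_restarts = n_restarts, rule = rule),
            class = "trimark_rank_scan")
}

#' @export
print.trimark_rank_scan <- function(x, ...) {
  cat(sprintf("<trimark_rank_scan> k* = %d (%s distance, %d restarts)\n",
              x$k_star, x$distance, x$n_restarts))
  print(x$scan)
  invisible(x)
}

#' @describeIn select_rank Tidy method: the `(rank, cophenetic)` scan.
#' @param x A `trimark_rank_scan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trimark_rank_scan <- function(x, ...) x$scan

#' @describeIn select_rank Rank-scan curve with the selected rank marked.
#' @exportS3Method ggplot2::autoplot
autoplot.trimark_rank_scan <- function(x, ...) {
  ggplot2::ggplot(x$scan, ggplot2::aes(.data$rank, .data$cophenetic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$k_star, linetype = 2,
                        colour = "#B2182B") +
    ggplot2::scale_x_continuous(breaks = x$scan$rank) +
    ggplot2::labs(x = "rank", y = "cophenetic coefficient",
                  title = sprintf("selected rank k* = %d", x$k_star)) +
    ggplot2::theme_minimal()
}

#' Binarized per-group factor profiles
#'
#' Per group and feature: the median intensity over member genes, binarized
#' to `@` when strictly greater than `threshold` (default 10) and `-`
#' otherwise. Empty groups get an all-`-` profile with size 0.
#'
#' @param intensity Wide gene x feature intensity table (first column gene
#'   id) or matrix; the rows covered by `assignment`.
#' @param assignment Named integer vector of group indices (from
#'   [assign_groups()]).
#' @param threshold Intensity threshold for the `@` mark (strict).
#' @return Tibble `(group, n_genes, feature, median_intensity, mark)`.
#' @export
group_profile <- function(intensity, assignment, threshold = 10) {
  m <- as_feature_matrix(intensity)
  if (nrow(m) != length(assignment)) {
    abort("`assignment` must cover every intensity row")
  }
  groups <- sort(unique(assignment[assignment > 0]))
  purrr::map_dfr(groups, function(g) {
    rows <- which(assignment == g)
    med <- if (length(rows) == 0) {
      rep(0, ncol(m))
    } else {
      unname(apply(m[rows, , drop = FALSE], 2, median))
    }
    tibble::tibble(
      group = g, n_genes = length(rows), feature = colnames(m),
      median_intensity = med,
      mark = ifelse(length(rows) > 0 & med > threshold, "@", "-")
    )
  })
}

#' Full NMF gene grouping with rank selection
#'
#' High-level wrapper: selects the rank by the cophenetic rule, refits
#' `n_restarts` factorizations at the selected rank keeping the best
#' objective, and derives the consensus matrix, group assignment and
#' binarized group profile.
#'
#' @inheritParams select_rank
#' @param profile_threshold Intensity threshold for the `@` mark in the
#'   group profile.
#' @return Object of class `trimark_nmf`: list with `fit`
#'   (`trimark_nmf_fit`), `rank_scan`, `consensus`, `assignment` (tibble
#'   `gene_id, group`), `profile`. `tidy()` returns the assignment,
#'   `glance()` a one-row summary.
#' @export
nmf_group <- function(X, ranks = 2:10, n_restarts = 30, seed = 1,
                      max_iter = 2000, tol = 1e-6,
                      distance = c("euclidean-rows", "one-minus"),
                      profile_threshold = 10) {
  distance <- match.arg(distance)
  Xm <- as_feature_matrix(X)
  scan <- select_rank(Xm, ranks = ranks, n_restarts = n_restarts,
                      seed = seed, max_iter = max_iter, tol = tol,
                      distance = distance)
  k <- scan$k_star
  fits <- lapply(seq_len(n_restarts), function(r) {
    nmf_factorize(Xm, k, seed = derive_seed(seed, "final") + r - 1,
                  max_iter = max_iter, tol = tol)
  })
  best <- fits[[which.min(vapply(fits, function(f) f$trace[length(f$trace)],
                                 numeric(1)))]]
  cons <- consensus_matrix(Xm, k, n_restarts = n_restarts,
                           seed = derive_seed(seed, paste0("rank", k)),
                           max_iter = max_iter, tol = tol)
  groups <- suppressWarnings(assign_groups(best$W))
  structure(
    list(fit = best, rank_scan = scan, consensus = cons,
         assignment = tibble::tibble(gene_id = rownames(Xm),
                                     group = unname(groups)),
         profile = group_profile(Xm, groups, threshold = profile_threshold)),
    class = "trimark_nmf"
  )
}

#' @export
print.trimark_nmf <- function(x, ...) {
  cat(sprintf("<trimark_nmf> %d genes in %d groups (rank %d)\n",
              nrow(x$assignment), length(unique(x$assignment$group)),
              x$fit$k))
  print(dplyr::count(x$assignment, .data$group))
  invisible(x)
}

#' @describeIn nmf_group Tidy method: per-gene group assignment.
#' @param x A `trimark_nmf`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trimark_nmf <- function(x, ...) x$assignment

#' @describeIn nmf_group Glance method: one-row fit summary.
#' @exportS3Method generics::glance
glance.trimark_nmf <- function(x, ...) {
  tibble::tibble(
    rank = x$fit$k,
    n_genes = nrow(x$assignment),
    n_features = ncol(x$fit$H),
    objective = x$fit$trace[length(x$fit$trace)],
    iterations = x$fit$iterations,
    cophenetic = x$rank_scan$scan$cophenetic[
      x$rank_scan$scan$rank == x$fit$k]
  )
}

#' @describeIn nmf_group Heatmap of the binarized group profile.
#' @exportS3Method ggplot2::autoplot
autoplot.trimark_nmf <- function(x, ...) {
  df <- x$profile
  df$feature <- factor(df$feature, levels = unique(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, factor(.data$group),
                                   fill = log10(.data$median_intensity + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166AC") +
    ggplot2::labs(x = NULL, y = "group",
                  fill = "log10 median\nintensity + 1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
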