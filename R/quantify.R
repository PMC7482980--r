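# Peak-intensity quantification: CPM normalization of per-peak mapped read
# counts, tiling of the genome into fixed-width bins, strand-aware promoter
# windows around the TSS, and assignment of normalized counts to regions by
# interval overlap.

#' Normalize peak read counts to counts per million
#'
#' Applies `cpm = mapped_read_count / library_total * 1e6` to every peak.
#' By default the library total is the summed peak count of each track
#' (factor x cell type when a `cell_type` column is present, factor
#' otherwise), so a track's CPM values sum to exactly one million.
#'
#' @param peaks Tibble with columns `factor`, `score` (mapped read count)
#'   and optionally `cell_type`.
#' @param library_total Either `NULL` (per-track totals from the data) or a
#'   single positive count used for all peaks.
#' @return The input tibble with a `cpm` column appended; row order
#'   preserved.
#' @export
cpm_normalize <- function(peaks, library_total = NULL) {
  assert_columns(peaks, c("factor", "score"), "peaks")
  if (any(peaks$score < 0)) abort("peak read counts must be non-negative")
  if (!is.null(library_total)) {
    if (!is.numeric(library_total) || length(library_total) != 1L ||
        is.na(library_total) || library_total <= 0) {
      abort("`library_total` must be a single positive count")
    }
    peaks$cpm <- peaks$score / library_total * 1e6
    return(peaks)
  }
  track <- if ("cell_type" %in% names(peaks)) {
    paste(peaks$factor, peaks$cell_type, sep = "\r")
  } else {
    peaks$factor
  }
  totals <- tapply(peaks$score, track, sum)
  if (any(totals <= 0)) {
    bad <- names(totals)[totals <= 0]
    abort(sprintf("track(s) with zero total read count: %s",
                  paste(gsub("\r", "/", bad), collapse = ", ")))
  }
  peaks$cpm <- peaks$score / as.numeric(totals[track]) * 1e6
  peaks
}

#' Tile chromosomes into fixed-width bins
#'
#' Half-open tiles covering each chromosome; the last bin of a chromosome
#' may be shorter than `width`.
#'
#' @param chrom_sizes Named numeric vector (`chrom -> length in bp`) or a
#'   tibble with columns `chrom`, `length`.
#' @param width Bin width in bp (default 1000).
#' @return Tibble `(region_id, chrom, start, end)`.
#' @export
bin_genome <- function(chrom_sizes, width = 1000) {
  if (width <= 0) abort("`width` must be positive")
  if (is.data.frame(chrom_sizes)) {
    assert_columns(chrom_sizes, c("chrom", "length"), "chrom_sizes")
    sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  } else {
    sizes <- chrom_sizes
  }
  purrr::map_dfr(names(sizes), function(ch) {
    len <- sizes[[ch]]
    if (len <= 0) {
      return(tibble::tibble(region_id = character(), chrom = character(),
                            start = integer(), end = integer()))
    }
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(
      region_id = sprintf("%s:%d-%d", ch, starts, pmin(starts + width, len)),
      chrom = ch,
      start = as.integer(starts),
      end = as.integer(pmin(starts + width, len))
    )
  })
}

#' Promoter windows around the TSS
#'
#' The promoter of a gene is the window `TSS - flank` to `TSS + flank`
#' (default 5000 bp each side), strand-aware (TSS = `start` on `+`, `end`
#' on `-`), clamped to `[0, chrom_length)`.
#'
#' @param annotation Tibble `(gene_id, chrom, start, end, strand)` with
#'   strands `+` or `-` only.
#' @param flank Flank size in bp on each side of the TSS.
#' @param chrom_length Chromosome length (single value or named vector by
#'   chromosome) used to clamp the right edge; `Inf` to skip.
#' @return Tibble `(region_id, chrom, start, end, strand)` with
#'   `region_id = gene_id`.
#' @export
promoter_windows <- function(annotation, flank = 5000, chrom_length = Inf) {
  assert_columns(annotation, c("gene_id", "chrom", "start", "end", "strand"),
                 "annotation")
  if (nrow(annotation) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  if (any(!annotation$strand %in% c("+", "-"))) {
    abort("promoter windows require strand '+' or '-' for every gene")
  }
  lens <- if (length(chrom_length) == 1L && is.null(names(chrom_length))) {
    rep(chrom_length, nrow(annotation))
  } else {
    unname(chrom_length[annotation$chrom])
  }
  tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end)
  s <- pmax(tss - flank, 0)
  e <- pmin(tss + flank, lens)
  tibble::tibble(
    region_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = as.integer(s),
    end = as.integer(e),
    strand = annotation$strand
  )
}

#' Gene-body regions from an annotation
#'
#' @param annotation Tibble `(gene_id, chrom, start, end, ...)`.
#' @return Tibble `(region_id, chrom, start, end)`.
#' @export
gene_body_regions <- function(annotation) {
  assert_columns(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  tibble::tibble(region_id = annotation$gene_id, chrom = annotation$chrom,
                 start = annotation$start, end = annotation$end)
}

#' Assign normalized peak intensities to regions
#'
#' For every region and factor (and cell type, when present), sums the CPM
#' of all peaks of that factor overlapping the region by at least 1 bp. A
#' peak overlapping several regions contributes its full CPM to each;
#' regions without overlapping peaks get 0.
#'
#' @param peaks Normalized peaks (must carry a `cpm` column; see
#'   [cpm_normalize()]).
#' @param regions Tibble `(region_id, chrom, start, end)`; 0-based
#'   half-open.
#' @return Long tibble `(region_id, factor, [cell_type,] intensity)`
#'   covering every region x factor (x cell type) combination.
#' @export
assign_intensity <- function(peaks, regions) {
  if (!"cpm" %in% names(peaks)) {
    abort("peaks must be normalized first (missing `cpm`); see cpm_normalize()")
  }
  assert_columns(peaks, c("chrom", "start", "end", "factor"), "peaks")
  assert_columns(regions, c("region_id", "chrom", "start", "end"), "regions")
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  has_cell <- "cell_type" %in% names(peaks)

  groups <- if (has_cell) {
    tidyr::expand_grid(region_id = regions$region_id,
                       factor = unique(peaks$factor),
                       cell_type = unique(peaks$cell_type))
  } else {
    tidyr::expand_grid(region_id = regions$region_id,
                       factor = unique(peaks$factor))
  }

  if (nrow(peaks) == 0) {
    groups$intensity <- 0
    return(groups)
  }

  # 1-based closed coordinates for IRanges; half-open [s, e) -> [s+1, e]
  gr_pk <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$start + 1, peaks$end))
  gr_rg <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1,
                                                   regions$end))
  hits <- GenomicRanges::findOverlaps(gr_pk, gr_rg, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  # aggregate hit cpm by (region, factor[, cell]) with rowsum (C-level)
  hit_key <- if (has_cell) {
    paste(regions$region_id[sh], peaks$factor[qh], peaks$cell_type[qh],
          sep = "\r")
  } else {
    paste(regions$region_id[sh], peaks$factor[qh], sep = "\r")
  }
  sums <- rowsum(peaks$cpm[qh], hit_key)
  out_key <- if (has_cell) {
    paste(groups$region_id, groups$factor, groups$cell_type, sep = "\r")
  } else {
    paste(groups$region_id, groups$factor, sep = "\r")
  }
  idx <- match(out_key, rownames(sums))
  groups$intensity <- ifelse(is.na(idx), 0, sums[idx, 1])
  groups
}

#' Widen a long intensity table into a region x factor matrix-tibble
#'
#' @param intensity Long table from [assign_intensity()], optionally
#'   filtered to one cell type.
#' @param feature_cols Columns to combine into the feature label (default
#'   `"factor"`; use `c("factor", "region_kind")` for joint gene-body /
#'   promoter features).
#' @return Wide tibble with `region_id` first, one column per feature.
#' @export
intensity_wide <- function(intensity, feature_cols = "factor") {
  assert_columns(intensity, c("region_id", feature_cols, "intensity"),
                 "intensity")
  if ("cell_type" %in% names(intensity) &&
      !"cell_type" %in% feature_cols &&
      length(unique(intensity$cell_type)) > 1) {
    abort("multiple cell types present; filter to one or add 'cell_type' to `feature_cols`")
  }
  intensity %>%
    tidyr::unite("feature", dplyr::all_of(feature_cols), sep = ".") %>%
    dplyr::select("region_id", "feature", "intensity") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "intensity",
                       values_fill = 0)
}

#' Coarse meta-gene profile of peak signal across gene bodies
#'
#' Splits every gene body into `n_bins` equal sub-windows and averages the
#' assigned CPM per sub-window over genes, per factor and cell type. A
#' plotting-level summary only.
#'
#' @param peaks Normalized peaks.
#' @param annotation Gene annotation tibble.
#' @param n_bins Number of sub-windows per gene.
#' @return Tibble `(factor, [cell_type,] bin, mean_intensity)`.
#' @export
metagene_profile <- function(peaks, annotation, n_bins = 20) {
  assert_columns(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  sub <- purrr::map_dfr(seq_len(n_bins), function(b) {
    w <- annotation$end - annotation$start
    tibble::tibble(
      region_id = paste0(annotation$gene_id, "#", b),
      chrom = annotation$chrom,
      start = as.integer(annotation$start + floor(w * (b - 1) / n_bins)),
      end = as.integer(annotation$start + floor(w * b / n_bins)),
      bin = b
    )
  })
  sub <- dplyr::filter(sub, .data$end > .data$start)
  x <- assign_intensity(peaks, sub)
  x$bin <- as.integer(sub$bin[match(x$region_id, sub$region_id)])
  keys <- intersect(c("factor", "cell_type", "bin"), names(x))
  x %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(mean_intensity = mean(.data$intensity), .groups = "drop")
}
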