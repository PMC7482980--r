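# Fixture I/O for synthetic studies: BED12 annotation, BED6 peak tracks,
# TSV expression / sample sheet / truth, YAML config echo. All plain text,
# 0-based half-open coordinates throughout.

#' Write a synthetic study to disk
#'
#' Emits `annotation.bed` (BED12), one BED6 peak file per cell type and
#' factor under `peaks/` (name column = factor, score = mapped read count),
#' `expression.tsv` (wide counts), `samples.tsv`, `truth.tsv` and
#' `config.yaml` (scalar configuration echo including the seed). The files
#' round-trip losslessly through [read_study()].
#'
#' @param study A `trimark_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a character vector of the files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "trimark_study"))
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, path, col_names = TRUE) {
    readr::write_tsv(df, path, col_names = col_names)
    written <<- c(written, path)
  }

  ann <- study$annotation
  bed12 <- tibble::tibble(
    chrom = ann$chrom, start = ann$start, end = ann$end,
    name = ann$gene_id, score = 0L, strand = ann$strand,
    thickStart = ann$start, thickEnd = ann$end, itemRgb = "0",
    blockCount = 1L,
    blockSizes = paste0(ann$end - ann$start, ","),
    blockStarts = "0,"
  )
  emit(bed12, file.path(dir, "annotation.bed"), col_names = FALSE)

  for (cell in sort(unique(study$peaks$cell_type))) {
    for (fac in sort(unique(study$peaks$factor))) {
      pk <- dplyr::filter(study$peaks, .data$cell_type == cell,
                          .data$factor == fac)
      bed6 <- tibble::tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                             name = pk$factor, score = pk$score,
                             strand = pk$strand)
      emit(bed6, file.path(dir, "peaks", sprintf("%s_%s.bed", cell, fac)),
           col_names = FALSE)
    }
  }

  emit(study$expression, file.path(dir, "expression.tsv"))
  emit(study$samples, file.path(dir, "samples.tsv"))
  emit(study$truth, file.path(dir, "truth.tsv"))

  cfg <- study$config
  echo <- list(
    n_genes = cfg$n_genes, chrom_length = cfg$chrom_length,
    factors = as.list(cfg$factors),
    group_fractions = as.list(cfg$group_fractions),
    intensity_dispersion = cfg$intensity_dispersion,
    promoter_rho_scale = cfg$promoter_rho_scale,
    expression_baseline = cfg$expression_baseline,
    expression_dispersion = cfg$expression_dispersion,
    expression_fc_by_group = as.list(cfg$expression_fc_by_group),
    n_replicates = cfg$n_replicates,
    split_peaks = cfg$split_peaks,
    seed = cfg$seed,
    # upstream provenance note: peak calling assumed done at FDR < 0.001
    peak_calling_fdr = 0.001
  )
  yaml_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(echo, yaml_path)
  written <- c(written, yaml_path)
  invisible(written)
}

#' Read a study fixture back from disk
#'
#' Reconstructs the tibbles written by [write_study()]. Peak files are read
#' in sorted filename order (`<cell>_<factor>.bed`); zero-count peaks are
#' preserved.
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `annotation`, `peaks`, `expression`, `samples`,
#'   `truth` tibbles (class `trimark_study_files`).
#' @export
read_study <- function(dir) {
  ann_path <- file.path(dir, "annotation.bed")
  if (!file.exists(ann_path)) {
    abort(sprintf("no annotation.bed under '%s'", dir))
  }
  annotation <- read_annotation_bed12(ann_path)

  peak_files <- sort(list.files(file.path(dir, "peaks"), pattern = "\\.bed$",
                                full.names = TRUE))
  peaks <- purrr::map_dfr(peak_files, function(f) {
    cell <- sub("_.*$", "", basename(f))
    pk <- read_peaks_bed(f)
    pk$cell_type <- cell
    pk
  })

  expression <- readr::read_tsv(file.path(dir, "expression.tsv"),
                                show_col_types = FALSE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  structure(list(annotation = annotation, peaks = peaks,
                 expression = expression, samples = samples, truth = truth),
            class = "trimark_study_files")
}

#' Read a BED6 peak file
#'
#' @param path BED6 file (chrom, start, end, name = factor, score = mapped
#'   read count, strand); 0-based half-open.
#' @return Tibble `(chrom, start, end, factor, score, strand)`.
#' @export
read_peaks_bed <- function(path) {
  pk <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "factor", "score", "strand"),
    col_types = readr::cols(
      chrom = "c", start = "i", end = "i", factor = "c",
      score = "i", strand = "c"),
    progress = FALSE)
  tibble::as_tibble(pk)
}

#' Read a BED12 gene annotation
#'
#' Only the interval-level fields are used (chrom, start, end, name, strand).
#'
#' @param path BED12 file, 0-based half-open.
#' @return Tibble `(gene_id, chrom, start, end, strand)`.
#' @export
read_annotation_bed12 <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb", "blockCount",
            "blockSizes", "blockStarts")
  ann <- readr::read_tsv(path, col_names = cols,
                         col_types = readr::cols(
                           chrom = "c", start = "i", end = "i", name = "c",
                           score = "i", strand = "c", thickStart = "i",
                           thickEnd = "i", itemRgb = "c", blockCount = "i",
                           blockSizes = "c", blockStarts = "c"),
                         progress = FALSE)
  tibble::tibble(gene_id = ann$name, chrom = ann$chrom, start = ann$start,
                 end = ann$end, strand = ann$strand)
}
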