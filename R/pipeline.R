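# End-to-end orchestration: generate (or load) -> quantify -> correlate ->
# differential -> patterns -> NMF grouping -> enrichment, with deterministic
# seeding and a JSON manifest of every artifact written.

#' Pipeline configuration
#'
#' Either a generator configuration (for a fully synthetic run) or a
#' directory of study fixture files (as written by [write_study()]) must be
#' supplied.
#'
#' @param generator A [generator_config()], or `NULL` when reading from
#'   `study_dir`.
#' @param study_dir Directory of fixture files, or `NULL` when generating.
#' @param fdr,min_fc DEG thresholds (defaults 0.05 and 2-fold).
#' @param trivalent_fc Linear fold-change threshold of the trivalent flag
#'   (default 2).
#' @param up_log2,down_log2 Ternary pattern state thresholds.
#' @param profile_threshold Intensity threshold of the `@` mark in NMF
#'   group profiles (default 10).
#' @param bin_width Genomic bin width in bp (default 1000).
#' @param flank Promoter flank in bp each side of the TSS (default 5000).
#' @param keep_empty_bins Keep all-zero bins in the genome-wide correlation
#'   screen (default `FALSE`).
#' @param ranks Candidate NMF ranks (default `2:6`).
#' @param n_restarts NMF restarts per rank (default 10).
#' @param nmf_max_iter,nmf_tol Per-fit iteration budget and stopping
#'   tolerance for the pipeline's factorizations.
#' @param peak_calling_fdr Upstream peak-calling FDR recorded as provenance
#'   metadata only (default 0.001; nothing is computed from it).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Object of class `trimark_pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, study_dir = NULL,
                            fdr = 0.05, min_fc = 2, trivalent_fc = 2,
                            up_log2 = 1, down_log2 = -1,
                            profile_threshold = 10,
                            bin_width = 1000, flank = 5000,
                            keep_empty_bins = FALSE,
                            ranks = 2:6, n_restarts = 10,
                            nmf_max_iter = 500, nmf_tol = 1e-5,
                            peak_calling_fdr = 0.001,
                            seed = 1) {
  if (is.null(generator) && is.null(study_dir)) {
    abort("pipeline_config requires either `generator` or `study_dir`")
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "trimark_config"))
  structure(
    list(generator = generator, study_dir = study_dir,
         fdr = fdr, min_fc = min_fc, trivalent_fc = trivalent_fc,
         up_log2 = up_log2, down_log2 = down_log2,
         profile_threshold = profile_threshold,
         bin_width = bin_width, flank = flank,
         keep_empty_bins = keep_empty_bins,
         ranks = ranks, n_restarts = n_restarts,
         nmf_max_iter = nmf_max_iter, nmf_tol = nmf_tol,
         peak_calling_fdr = peak_calling_fdr,
         seed = assert_count(seed, "seed")),
    class = "trimark_pipeline_config"
  )
}

#' Demo pipeline configuration
#'
#' A self-contained synthetic run at demo scale: 2,000 genes, the 19-factor
#' panel, NMF ranks 2-6 with 10 restarts.
#'
#' @param seed Master seed.
#' @param n_genes Number of genes (default 2000).
#' @return A `trimark_pipeline_config`.
#' @export
demo_config <- function(seed = 1, n_genes = 2000) {
  pipeline_config(generator = generator_config(n_genes = n_genes,
                                               seed = seed),
                  seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes generate/load -> quantify -> correlate -> differential ->
#' patterns -> NMF grouping -> enrichment, writing each stage artifact as a
#' plain TSV under `out_dir` plus a JSON manifest of file hashes. The run
#' is a deterministic function of the configuration (including its seed):
#' identical config implies identical manifest hashes. On a stage failure
#' the error names the failing stage and a `FAILED_<stage>` marker is left
#' beside any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "trimark_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0("FAILED_", name)))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- generate / load --------------------------------------------------
  study <- stage("generate", {
    if (!is.null(config$generator)) {
      st <- generate_study(config$generator)
      written <- write_study(st, file.path(out_dir, "study"))
      artifacts <- c(artifacts, written)
      st
    } else {
      files <- read_study(config$study_dir)
      chrom_length <- max(files$annotation$end, files$peaks$end)
      structure(
        list(annotation = files$annotation, peaks = files$peaks,
             expression = files$expression, samples = files$samples,
             truth = files$truth,
             config = list(chrom_length = chrom_length,
                           factors = sort(unique(files$peaks$factor)),
                           seed = config$seed)),
        class = "trimark_study")
    }
  })

  # -- quantify ---------------------------------------------------------
  quant <- stage("quantify", {
    peaks <- cpm_normalize(study$peaks)
    ann <- study$annotation
    chrom_sizes <- setNames(study$config$chrom_length,
                            unique(ann$chrom)[1])
    bins <- bin_genome(chrom_sizes, width = config$bin_width)
    if (!config$keep_empty_bins) {
      gr_b <- GenomicRanges::GRanges(bins$chrom,
                                     IRanges::IRanges(bins$start + 1,
                                                      bins$end))
      gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                     IRanges::IRanges(peaks$start + 1,
                                                      peaks$end))
      keep <- unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(gr_p, gr_b)))
      bins <- bins[sort(keep), ]
    }
    list(
      peaks = peaks,
      bins = assign_intensity(peaks, bins),
      gene_body = assign_intensity(peaks, gene_body_regions(ann)),
      promoter = assign_intensity(
        peaks, promoter_windows(ann, flank = config$flank,
                                chrom_length = study$config$chrom_length))
    )
  })
  for (kind in c("bins", "gene_body", "promoter")) {
    emit(quant[[kind]], sprintf("intensity_%s.tsv", kind))
  }

  # -- correlation screen (ESC) ----------------------------------------
  stage("correlate", {
    esc_wide <- function(kind) {
      intensity_wide(dplyr::filter(quant[[kind]], .data$cell_type == "ESC"))
    }
    for (method in c("pearson", "spearman")) {
      mats <- lapply(c(bins = "bins", gene_body = "gene_body",
                       promoter = "promoter"),
                     function(kind) pairwise_correlation(esc_wide(kind),
                                                         method = method))
      emit(correlation_report(mats), sprintf("correlation_%s.tsv", method))
    }
  })

  # -- differential expression -----------------------------------------
  deg <- stage("differential", {
    deg_classify(study$expression, study$samples, fdr = config$fdr,
                 min_fc = config$min_fc)
  })
  emit(deg, "deg.tsv")

  # -- fold-change patterns --------------------------------------------
  pat <- stage("patterns", {
    wide_by_cell <- function(kind, cell) {
      intensity_wide(dplyr::filter(quant[[kind]], .data$cell_type == cell))
    }
    out <- list()
    for (kind in c("gene_body", "promoter")) {
      fc <- factor_log2fc(wide_by_cell(kind, "ESC"),
                          wide_by_cell(kind, "fibroblast"))
      emit(fc, sprintf("factor_log2fc_%s.tsv", kind))
      cl <- cluster_by_pattern(fc, up_log2 = config$up_log2,
                               down_log2 = config$down_log2)
      emit(tidy(cl), sprintf("patterns_%s.tsv", kind))
      emit(pattern_expression_summary(cl, deg),
           sprintf("pattern_expression_%s.tsv", kind))
      out[[kind]] <- list(fc = fc, patterns = cl)
    }
    flags <- trivalent_flag(out$gene_body$fc,
                            fc_threshold = config$trivalent_fc)
    emit(flags, "trivalent_flags.tsv")
    strata <- mark_count_strata(flags, out$gene_body$fc, deg)
    emit(strata$summary, "mark_count_strata.tsv")
    out$flags <- flags
    out
  })

  # -- NMF grouping -----------------------------------------------------
  nmf <- stage("nmf", {
    joint <- dplyr::bind_rows(
      dplyr::mutate(dplyr::filter(quant$gene_body, .data$cell_type == "ESC"),
                    region_kind = "gene_body"),
      dplyr::mutate(dplyr::filter(quant$promoter, .data$cell_type == "ESC"),
                    region_kind = "promoter"))
    X <- intensity_wide(joint, feature_cols = c("factor", "region_kind"))
    res <- nmf_group(X, ranks = config$ranks,
                     n_restarts = config$n_restarts,
                     seed = derive_seed(config$seed, "nmf"),
                     max_iter = config$nmf_max_iter, tol = config$nmf_tol,
                     profile_threshold = config$profile_threshold)
    emit(tidy(res$rank_scan), "nmf_rank_scan.tsv")
    emit(tibble::as_tibble(res$fit$W, rownames = "gene_id"), "nmf_W.tsv")
    emit(tibble::as_tibble(res$fit$H, rownames = "group"), "nmf_H.tsv")
    emit(tibble::as_tibble(res$consensus, rownames = "gene_id"),
         "nmf_consensus.tsv")
    emit(res$assignment, "nmf_groups.tsv")
    emit(res$profile, "nmf_profile.tsv")
    res
  })

  # -- enrichment -------------------------------------------------------
  stage("enrich", {
    terms <- if (!is.null(config$generator)) {
      make_term_sets(study, seed = derive_seed(config$seed, "terms"))
    } else {
      gmt <- file.path(config$study_dir, "terms.gmt")
      if (file.exists(gmt)) read_gmt(gmt) else NULL
    }
    if (!is.null(terms)) {
      gmt_path <- file.path(out_dir, "terms.gmt")
      write_gmt(terms, gmt_path)
      artifacts <- c(artifacts, gmt_path)
      # target group: the NMF group with the strongest trivalent-mark
      # profile (summed median intensity over the six mark features)
      mark_feats <- paste(rep(trivalent_marks(), each = 2),
                          c("gene_body", "promoter"), sep = ".")
      score <- nmf$profile %>%
        dplyr::filter(.data$feature %in% mark_feats) %>%
        dplyr::group_by(.data$group) %>%
        dplyr::summarise(score = sum(.data$median_intensity),
                         .groups = "drop")
      target <- score$group[which.max(score$score)]
      genes <- nmf$assignment$gene_id[nmf$assignment$group == target]
      enr <- subgroup_enrichment(genes, deg, terms,
                                 universe = nmf$assignment$gene_id)
      emit(dplyr::mutate(enr, target_group = target), "enrichment.tsv")
    }
  })

  # -- manifest ---------------------------------------------------------
  manifest <- stage("manifest", {
    rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", out_dir),
                      "/?"), "", artifacts)
    ord <- order(rel)
    m <- list(
      package = "trimark",
      version = as.character(utils::packageVersion("trimark")),
      seed = config$seed,
      peak_calling_fdr = config$peak_calling_fdr,
      artifacts = lapply(seq_along(rel[ord]), function(i) {
        list(path = rel[ord][i],
             md5 = unname(tools::md5sum(artifacts[ord][i])))
      })
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })
  invisible(manifest)
}
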