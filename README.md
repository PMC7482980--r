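# trimark

Combinatorial analysis of DNA and histone modifications at genic regions,
built around the proposed **trivalent mark** in embryonic stem cells: the
co-occurrence of 5-hydroxymethylcytosine (5hmC), H3K4me1 and H4K8ac.

Embryonic stem cells accumulate 5hmC, and its genomic distribution tracks
activating histone marks. `trimark` provides a tested, fully reproducible
pipeline for asking whether such marks act *combinatorially*: quantify
peak signal over genomic regions, screen all factor pairs for
co-occurrence, relate joint fold-change patterns between cell types to
differential expression, and group genes by their full epigenetic profile
with nonnegative matrix factorization. Every stage is driven by a
synthetic-study generator with planted truth, so the whole analysis is
verifiable end to end without external downloads. It is aimed at
computational epigenomics researchers who have post-peak-calling data
(BED-like peak intervals with read counts, a gene annotation, RNA-seq
counts) for two cell types.

## The model in brief

- **Intensity.** Each peak's mapped read count is normalized to counts
  per million, `CPM = count / library total x 10^6`, and a region's
  intensity for a factor is the CPM sum of all overlapping peaks (>= 1 bp
  overlap). Regions are 1-kb bins, gene bodies, or promoters
  (TSS +/- 5000 bp, strand-aware).
- **Co-occurrence.** Pearson's (or Spearman's) correlation between factor
  intensity columns over regions, per region kind.
- **Differential genes.** `up` / `down` / `non` between ESC and
  fibroblast at FDR <= 0.05 and |fold change| > 2, from a moderated t
  test on log2(CPM + 1) (a plain Welch test is available). Per-factor
  ratios are `log2((I_ESC + 1) / (I_fib + 1))`.
- **Patterns and the trivalent flag.** Genes are partitioned by the
  ternary (+ / - / 0, at two-fold) direction of the 5hmC, 5mC, H3K4me1
  and H4K8ac changes; a gene is *trivalent* when each of 5hmC, H3K4me1
  and H4K8ac individually gains more than two-fold.
- **NMF grouping.** `X ~ W H` with non-negative factors by Lee-Seung
  multiplicative updates on the gene x (19 factors x 2 regions) matrix;
  restart-consensus clustering and cophenetic-based rank selection;
  groups profiled by median intensity, binarized at `> 10` (`@` / `-`).
- **Enrichment.** Exact hypergeometric upper-tail tests of gene groups
  against term sets, BH-corrected, split by differential label.

See `vignettes/trimark-methods.Rmd` for the full model description,
parameter defaults, and design rationale.

## Worked example

```r
library(trimark)
library(dplyr)

cfg <- generator_config(n_genes = 1000, seed = 42)
study <- generate_study(cfg)
study
#> <trimark_study> 1000 genes, 19 factors, 76000 peaks, 4 samples

# quantify ESC gene-body intensities and screen factor pairs
peaks <- cpm_normalize(study$peaks)
gb <- assign_intensity(filter(peaks, cell_type == "ESC"),
                       gene_body_regions(study$annotation))
corr <- pairwise_correlation(intensity_wide(gb))
tidy(corr) %>%
  filter(factor_a %in% c("5hmC", "H3K4me1"),
         factor_b %in% c("H3K4me1", "H4K8ac"))
#> # A tibble: 3 x 5
#>   factor_a factor_b method      r     n
#>   <chr>    <chr>    <chr>   <dbl> <int>
#> 1 5hmC     H3K4me1  pearson 0.742  1000
#> 2 5hmC     H4K8ac   pearson 0.607  1000
#> 3 H3K4me1  H4K8ac   pearson 0.661  1000
```

The generator planted correlations of 0.8 / 0.7 / 0.6 on these pairs;
the recovered values are attenuated slightly because the default study
mixes five gene groups with different mean profiles on top of the
planted within-group correlation.

```r
# differential expression and the mark-count strata
deg <- deg_classify(study$expression, study$samples)
count(deg, label)
#> # A tibble: 3 x 2
#>   label     n
#>   <chr> <int>
#> 1 down    379
#> 2 non     501
#> 3 up      120

fib <- assign_intensity(filter(peaks, cell_type == "fibroblast"),
                        gene_body_regions(study$annotation))
fc <- factor_log2fc(intensity_wide(gb), intensity_wide(fib))
strata <- mark_count_strata(trivalent_flag(fc), fc, deg)
strata$summary
#> # A tibble: 3 x 3
#>   stratum          n median_expression_log2fc
#>   <fct>        <int>                    <dbl>
#> 1 5hmC_only       73                   -0.428
#> 2 5hmC_H3K4me1    66                    0.414
#> 3 trivalent      118                    1.81
```

Median expression change increases strictly with the number of
co-occurring marks — the pipeline's headline observation. (Absolute
levels are shifted downward by CPM composition: the ESC library is
inflated by the planted gains, which also produces the `down` labels
among unchanged genes.)

The full chain — generate, quantify, correlate, classify, pattern, NMF
group, enrich, manifest — runs from one configuration:

```r
manifest <- run_pipeline(demo_config(seed = 1), "out/")
```

which writes every stage artifact as TSV plus `manifest.json` with file
hashes (identical seed, identical hashes; the 2,000-gene demo takes
about a minute).

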