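# hltme

Tumor-microenvironment (TME) characterization of classic Hodgkin lymphoma
(HL) stratified by HLA class I / class II expression on
Hodgkin–Reed–Sternberg cells (HRSCs).

In HL, the rare CD30+ neoplastic HRSCs sit scattered in an abundant immune
microenvironment and frequently lose surface HLA-I (via
beta-2-microglobulin) or HLA-II, hiding from CD8+ and CD4+ T cells. `hltme`
is a tested, reusable pipeline for asking how HLA status on HRSCs shapes
that microenvironment, across four data modalities:

- **Differential bulk gene expression** — per-gene logistic GLM with HLA
  status as the response and centered log2 NanoString-like counts as the
  predictor, optionally adjusted for EBV as a second predictor; fold-change
  FC(g) = mean log2 expression in HLA− cases − mean in HLA+ cases; volcano
  classification at p ≤ 0.05 and |FC| beyond 0.6; Benjamini–Hochberg
  q-values.
- **Spatial zoning** of multiplexed-immunofluorescence cell detections:
  per-cell distance d to the nearest CD30+ cell; zones *close* (d ≤ 28.33 µm),
  *intermediate*, *distant* (d > 75 µm); phenotype composition per zone
  (CD68, CD8, LAG3, FoxP3, PD1 fractions of all cells, and CD8-co-expression
  phenotypes as fractions of CD8+ cells); paired close-vs-distant t-tests.
- **TCR-β repertoire clonality** — Simpson's clonality √(Σ pᵢ²) of
  productive clone frequencies, compared between HLA groups.
- **Association statistics** — two-sided Fisher exact test (point-probability
  rule, log-space hypergeometric pmf) and uncorrected Pearson χ² on cohort
  contingency tables.

Because the patient-level data the analysis targets are only available on
request, the package includes a first-class **synthetic cohort generator**
(marked Poisson point processes with radial near-HRSC enrichment,
negative-binomial counts with group-level log2 effects, Dirichlet clone
frequencies, annotation tables with an HLA-I/EBV association) so that every
stage is testable end to end, chiefly by recovering the generator's known
ground truth. See the vignette `vignettes/hl-tme-analysis.Rmd` for the
models, conventions and design decisions.

## Worked example

The published HLA-I × EBV contingency table (5/11 EBV+ among HLA-I+ cases
vs 7/86 among HLA-I−):

```r
library(hltme)
tab <- contingency_table(matrix(c(5, 7, 6, 79), 2),
                         c("hla_i_pos", "hla_i_neg"),
                         c("ebv_pos", "ebv_neg"))
fisher_exact_2x2(tab)
#> <association_result> fisher_2x2
#>           ebv_pos ebv_neg
#> hla_i_pos       5       6
#> hla_i_neg       7      79
#> odds ratio = 9.4048
#> p-value = 0.0038037
```

EBV positivity is strongly enriched in HLA-I+ disease (odds ratio 9.4,
p = 0.0038). A full synthetic run of all pipeline stages:

```r
report <- run_pipeline(default_run_config(seed = 1, n_cases = 97))
report
#> <run_report> seed 1 - 97 cases
#>   DE: 200 genes; 6 volcano-significant
#>   spatial: 10 paired zone tests over 97 cases
#>   clonality: t-test p = 0.153
#>   assoc hla_i_ebv: p = 0.00509
#>   assoc hla_i_hla_ii: p = 0.1769
#>   assoc hla_i_subtype: p = 0.0004948
#>   exclusions: 6

subset(report$de, volcano_class != "not_significant")[, c(1, 3, 5, 7)]
#>      gene      p_value fold_change    volcano_class
#> 1   CCL17 0.0028574372   1.1626244   up_in_negative
#> 2   CCL22 0.0004364740   0.9496241   up_in_negative
#> 3 TNFRSF8 0.0018765848   0.7503369   up_in_negative
#> 5    CD8B 0.0004733351  -0.9415650 down_in_negative
#> 6   MS4A1 0.0012957462  -0.9659116 down_in_negative
#> 7    CD19 0.0003520189  -0.8625213 down_in_negative
```

The simulated cohort reproduces the structure the analysis is built to
detect: HRSC cytokines (CCL17/TARC, CCL22) and TNFRSF8/CD30 come out higher
in HLA-I− cases (positive fold-change), cytotoxic and B-cell genes (CD8B,
MS4A1, CD19) higher in HLA-I+ cases, the HLA-I × EBV association is
significant while clonality does not differ, and the paired zone tests show
CD8+LAG3+ cells enriched (and plain CD8+ cells depleted) close to HRSCs:

```r
subset(report$zone_tests, scheme == "cd8")[, c(2, 3, 5, 6)]
#>    phenotype          t      p_value mean_difference
#> 6   CD8_only -41.420829 4.811694e-63     -0.20172746
#> 7   CD8_LAG3  34.178151 1.546009e-55      0.16078428
#> 8  CD8_FoxP3   4.954100 3.115773e-06      0.01504150
#> 9    CD8_PD1   7.513470 2.997486e-11      0.02590167
#> 10  CD8_TIM3  -4.415939 2.638207e-05     -0.01172859
```

(`mean_difference` is the mean per-case close-minus-distant fraction.)

Real data enter through `read_cell_table()`, `read_expression_matrix()`,
`read_repertoire()` and `read_sample_annotation()`; see
`?cell_table_dialect` for adapting other cell-table export schemas.

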