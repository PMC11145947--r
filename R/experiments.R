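# Parameter-recovery and calibration experiments: each one simulates data
# with known ground truth and measures how well the corresponding pipeline
# stage recovers it. They are the package's main validation surface, since
# the underlying patient-level data are not publicly deposited.

#' Recovery of a spatial close-enrichment factor
#'
#' Simulates maps in which only the CD8_LAG3 class is enriched near HRSCs by
#' the factor `f`, then measures the close/distant fraction ratio via
#' [zone_composition()], pooling counts over seeds. The generating intensity
#' ratio is `f`; the measured ratio is damped by a few percent because the
#' enriched class inflates the close-zone denominator.
#'
#' @param f true enrichment factor.
#' @param n_seeds replicate maps (seeds `base_seed + 1:n_seeds`).
#' @param base_seed seed offset.
#' @param field_size,immune_density,hrsc_density passed to
#'   [cohort_sim_config()]; the defaults give roughly 10,000 cells per map so
#'   the ratio estimate is dominated by the generating process, not noise.
#' @return list with `ratio` (pooled estimate), `f`, and the pooled close and
#'   distant counts.
#' @export
spatial_enrichment_recovery <- function(f, n_seeds = 20, base_seed = 0,
                                        field_size = 1200,
                                        immune_density = 6000,
                                        hrsc_density = 30) {
  scheme <- phenotype_scheme(list(CD8_LAG3 = list(pos = c("CD8", "LAG3"))),
                             denominator = "all_cells")
  num <- c(close = 0, distant = 0)
  den <- c(close = 0, distant = 0)
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_sim_config(field_size = field_size,
                             immune_density = immune_density,
                             hrsc_density = hrsc_density,
                             close_enrichment = c(CD8_LAG3 = f),
                             seed = base_seed + s)
    m <- simulate_cell_map(cfg, "c", "neg")
    comp <- suppressMessages(zone_composition(m, assign_zones(m), scheme))
    for (z in c("close", "distant")) {
      row <- comp[comp$zone == z, ]
      if (nrow(row)) {
        num[z] <- num[z] + row$n_cells
        den[z] <- den[z] + row$denominator_n
      }
    }
  }
  list(f = f, ratio = (num[["close"]] / den[["close"]]) /
         (num[["distant"]] / den[["distant"]]),
       close = num[["close"]], distant = num[["distant"]])
}

#' Type-I calibration of the paired zone comparison
#'
#' Simulates cohorts with no spatial enrichment at all and measures how often
#' the paired close-vs-distant t-test on the CD8_LAG3 fraction rejects at
#' `alpha`. Under the null this should match `alpha` up to binomial error.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_cases cases (paired observations) per cohort.
#' @param alpha nominal level.
#' @param base_seed seed offset.
#' @param field_size,immune_density,hrsc_density generator settings.
#' @return list with `rejection_rate`, `n_cohorts`, `alpha`, `p_values`.
#' @export
spatial_null_calibration <- function(n_cohorts = 40, n_cases = 8,
                                     alpha = 0.05, base_seed = 0,
                                     field_size = 1000, immune_density = 2000,
                                     hrsc_density = 30) {
  flat <- c(CD8_LAG3 = 1)
  scheme <- phenotype_scheme(list(CD8_LAG3 = list(pos = c("CD8", "LAG3"))),
                             denominator = "all_cells")
  pvals <- vapply(seq_len(n_cohorts), function(co) {
    comp <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
      cfg <- cohort_sim_config(field_size = field_size,
                               immune_density = immune_density,
                               hrsc_density = hrsc_density,
                               close_enrichment = flat,
                               seed = base_seed + co * 1000 + i)
      m <- simulate_cell_map(cfg, paste0("case_", i), "neg")
      suppressMessages(zone_composition(m, assign_zones(m), scheme))
    }))
    compare_zones(comp, "CD8_LAG3")$p_value
  }, numeric(1))
  list(rejection_rate = mean(pvals <= alpha), n_cohorts = n_cohorts,
       alpha = alpha, p_values = pvals)
}

#' Type-I calibration of the differential-expression stage
#'
#' Simulates matrices with no group effects and measures the fraction of
#' genes with `p <= alpha` across seeds; under the null this estimates the
#' type-I error of the per-gene logistic GLM.
#'
#' @param n_seeds simulated matrices.
#' @param n_genes genes per matrix.
#' @param n_per_group samples per HLA group.
#' @param alpha nominal level.
#' @param base_seed seed offset.
#' @return list with `type_i_error`, `n_tests`, `alpha`.
#' @export
de_null_calibration <- function(n_seeds = 20, n_genes = 200,
                                n_per_group = 40, alpha = 0.05,
                                base_seed = 0) {
  ann <- sample_annotation(sprintf("s%03d", seq_len(2 * n_per_group)),
                           hla_i = rep(c("pos", "neg"), each = n_per_group),
                           ebv = "neg")
  hits <- 0L; total <- 0L
  for (s in seq_len(n_seeds)) {
    cfg <- expression_sim_config(n_genes = n_genes, signature_genes = list(),
                                 seed = base_seed + s)
    centered <- normalize_expression(qc_filter_samples(simulate_expression(cfg, ann)))
    res <- suppressWarnings(differential_expression(centered, ann))
    hits <- hits + sum(res$p_value <= alpha)
    total <- total + nrow(res)
  }
  list(type_i_error = hits / total, n_tests = total, alpha = alpha)
}

#' Power to volcano-classify a shifted gene
#'
#' Simulates matrices in which one gene carries a log2 shift on the
#' fold-change scale (elevated in the HLA-negative group) and measures how
#' often it is volcano-classified `up_in_negative` (raw p at most
#' `p_threshold` and fold-change above `fc_threshold`), plus the mean
#' recovered fold-change.
#'
#' @param shift true log2 shift.
#' @param n_seeds simulated matrices.
#' @param n_genes genes per matrix.
#' @param n_per_group samples per HLA group.
#' @param p_threshold,fc_threshold volcano thresholds.
#' @param base_seed seed offset.
#' @return list with `classification_rate`, `mean_fold_change`, `shift`.
#' @export
de_shift_recovery <- function(shift = 1.0, n_seeds = 20, n_genes = 200,
                              n_per_group = 40, p_threshold = 0.05,
                              fc_threshold = 0.6, base_seed = 0) {
  ann <- sample_annotation(sprintf("s%03d", seq_len(2 * n_per_group)),
                           hla_i = rep(c("pos", "neg"), each = n_per_group),
                           ebv = "neg")
  sig <- list(SHIFTED = c(hla = shift, ebv = 0))
  ok <- logical(n_seeds); fc <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- expression_sim_config(n_genes = n_genes, signature_genes = sig,
                                 seed = base_seed + s)
    centered <- normalize_expression(qc_filter_samples(simulate_expression(cfg, ann)))
    res <- suppressWarnings(differential_expression(
      centered, ann, p_threshold = p_threshold, fc_threshold = fc_threshold))
    hit <- res[res$gene == "SHIFTED", ]
    ok[s] <- hit$volcano_class == "up_in_negative"
    fc[s] <- hit$fold_change
  }
  list(classification_rate = mean(ok), mean_fold_change = mean(fc),
       shift = shift)
}

#' Recovery of generator-level HRSC group differences
#'
#' Simulates maps for HLA-I+ and HLA-I- cases under the generator defaults
#' (lower HRSC density and lower TARC intensity in HLA-I+ disease) and tests
#' whether per-case TARC intensity on HRSCs and the CD30+ area fraction
#' separate the groups by unpaired t-test.
#'
#' @param n_per_group maps per HLA group.
#' @param base_seed seed offset.
#' @param field_size field side in micrometers.
#' @return list with the two p-values and the four group means.
#' @export
hrsc_group_recovery <- function(n_per_group = 8, base_seed = 0,
                                field_size = 600) {
  sim_group <- function(status, offset) {
    maps <- lapply(seq_len(n_per_group), function(i) {
      cfg <- cohort_sim_config(field_size = field_size, immune_density = 1000,
                               seed = base_seed + offset + i)
      simulate_cell_map(cfg, paste0(status, i), hla_status = status)
    })
    list(tarc = vapply(maps, function(m) hrsc_marker_intensity(m)$mean,
                       numeric(1)),
         area = vapply(maps, cd30_area_fraction, numeric(1)))
  }
  pos <- sim_group("pos", 0)
  neg <- sim_group("neg", 10000)
  tt_tarc <- stats::t.test(pos$tarc, neg$tarc)
  tt_area <- stats::t.test(pos$area, neg$area)
  list(tarc_p = tt_tarc$p.value, area_p = tt_area$p.value,
       tarc_mean_pos = mean(pos$tarc), tarc_mean_neg = mean(neg$tarc),
       area_mean_pos = mean(pos$area), area_mean_neg = mean(neg$area))
}
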