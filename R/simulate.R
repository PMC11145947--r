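# Synthetic cohort generator. Emulates the statistical structure the
# downstream analyses assume: scattered rare CD30+ HRSCs with near-HRSC
# phenotype enrichment (marked point process), negative-binomial NanoString-
# like counts with group-level log2 effects, Dirichlet clone-frequency skew,
# and annotation tables with an HLA-I/EBV association.

# Immune phenotype classes and their marker signatures. A simulated immune
# cell belongs to exactly one class; the observable marker calls follow from
# the signature.
PHENOTYPE_CLASSES <- list(
  CD3_other = "CD3",
  CD68      = "CD68",
  CD8_only  = c("CD3", "CD8"),
  FoxP3     = c("CD3", "FoxP3"),
  PD1       = c("CD3", "PD1"),
  CD8_LAG3  = c("CD3", "CD8", "LAG3"),
  CD8_PD1   = c("CD3", "CD8", "PD1"),
  CD8_FoxP3 = c("CD3", "CD8", "FoxP3"),
  CD8_TIM3  = c("CD3", "CD8", "TIM3"))

.default_mix <- c(CD3_other = 0.40, CD68 = 0.20, CD8_only = 0.15,
                  FoxP3 = 0.07, PD1 = 0.07, CD8_LAG3 = 0.04, CD8_PD1 = 0.03,
                  CD8_FoxP3 = 0.02, CD8_TIM3 = 0.02)

.default_enrichment <- c(CD68 = 1.8, CD8_LAG3 = 2.5, CD8_PD1 = 1.5,
                         CD8_FoxP3 = 1.5, FoxP3 = 1.5, PD1 = 1.5,
                         CD8_only = 0.8)

#' Configuration of the cell-map simulator
#'
#' Parameters of the marked point process behind [simulate_cell_map()]:
#' HRSCs are a homogeneous Poisson process; immune cells of each phenotype
#' class are an inhomogeneous Poisson process whose intensity is the baseline
#' times the class's enrichment factor within `close_radius` of an HRSC,
#' the baseline beyond `distant_radius`, with linear interpolation between.
#'
#' @param field_size square field side in micrometers.
#' @param hrsc_density HRSCs per square millimeter.
#' @param immune_density immune cells per square millimeter (all classes).
#' @param phenotype_mix named baseline shares of the phenotype classes
#'   (must sum to 1); see `names(PHENOTYPE_CLASSES)` for valid names.
#' @param close_enrichment named multiplicative density factors applied
#'   within `close_radius` of an HRSC; classes not named get factor 1.
#' @param close_radius,distant_radius enrichment radii in micrometers
#'   (defaults 28.33 and 75, the analysis zoning radii).
#' @param hrsc_factor_hla_pos multiplier on `hrsc_density` for HLA-I+ cases
#'   (HLA-I+ disease carries a lower tumor-cell content).
#' @param tarc_meanlog named (`pos`, `neg`) log-scale means of per-HRSC TARC
#'   intensity by HLA-I status (lognormal; EBV+ cases get the midpoint).
#' @param tarc_sdlog lognormal sd of TARC intensity.
#' @param hrsc_area_mean,immune_area_mean mean cell areas in square
#'   micrometers (gamma-distributed, shape 16).
#' @param seed RNG seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(field_size = 1000, hrsc_density = 30,
                              immune_density = 6000,
                              phenotype_mix = .default_mix,
                              close_enrichment = .default_enrichment,
                              close_radius = 28.33, distant_radius = 75,
                              hrsc_factor_hla_pos = 0.5,
                              tarc_meanlog = c(pos = 1.0, neg = 1.8),
                              tarc_sdlog = 0.5,
                              hrsc_area_mean = 350, immune_area_mean = 80,
                              seed = 1) {
  stopifnot(field_size > 0, hrsc_density > 0, immune_density > 0,
            close_radius < distant_radius, all(phenotype_mix > 0),
            all(close_enrichment > 0), hrsc_factor_hla_pos > 0)
  bad <- setdiff(names(phenotype_mix), names(PHENOTYPE_CLASSES))
  if (length(bad)) stop("unknown phenotype class(es): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(close_enrichment), names(PHENOTYPE_CLASSES))
  if (length(bad)) stop("unknown phenotype class(es): ", paste(bad, collapse = ", "))
  if (abs(sum(phenotype_mix) - 1) > 1e-8) stop("phenotype_mix must sum to 1")
  structure(list(field_size = field_size, hrsc_density = hrsc_density,
                 immune_density = immune_density, phenotype_mix = phenotype_mix,
                 close_enrichment = close_enrichment,
                 close_radius = close_radius, distant_radius = distant_radius,
                 hrsc_factor_hla_pos = hrsc_factor_hla_pos,
                 tarc_meanlog = tarc_meanlog, tarc_sdlog = tarc_sdlog,
                 hrsc_area_mean = hrsc_area_mean,
                 immune_area_mean = immune_area_mean, seed = seed),
            class = "cohort_sim_config")
}

.nearest_dist_xy <- function(x, y, hx, hy) {
  if (!length(hx)) return(rep(Inf, length(x)))
  d2 <- outer(x, hx, "-")^2 + outer(y, hy, "-")^2
  sqrt(.rowMins(d2))
}

# radial enrichment profile: factor f inside r_close, 1 beyond r_distant,
# linear in between (avoids a discontinuity at an arbitrary radius)
.enrichment_at <- function(d, f, r_close, r_distant) {
  ifelse(d <= r_close, f,
         ifelse(d > r_distant, 1,
                1 + (f - 1) * (r_distant - d) / (r_distant - r_close)))
}

#' Simulate one cell map
#'
#' HRSCs are placed by a homogeneous Poisson process (density reduced by
#' `hrsc_factor_hla_pos` for HLA-I+ cases); immune cells of each phenotype
#' class by an inhomogeneous Poisson process realized by thinning, enriched
#' (or depleted) near HRSCs per `close_enrichment`. HRSCs carry a lognormal
#' TARC intensity whose mean depends on HLA-I (and EBV) status.
#'
#' @param cfg a [cohort_sim_config()].
#' @param case_id case identifier.
#' @param hla_status `"pos"` or `"neg"` HLA-I status of the case.
#' @param ebv_status `"pos"` or `"neg"` (`"na"` treated as `"neg"`).
#' @return a [cell_map()] with field extent `c(0, field_size, 0, field_size)`.
#' @export
simulate_cell_map <- function(cfg, case_id = "case_1", hla_status = "neg",
                              ebv_status = "neg") {
  stopifnot(inherits(cfg, "cohort_sim_config"),
            hla_status %in% c("pos", "neg", "na"))
  set.seed(cfg$seed)
  fs <- cfg$field_size
  area_mm2 <- (fs / 1000)^2

  hrsc_rate <- cfg$hrsc_density *
    if (hla_status == "pos") cfg$hrsc_factor_hla_pos else 1
  if (hrsc_rate * area_mm2 < 1)
    warning("expected HRSC count below 1 (", format(hrsc_rate * area_mm2),
            "); field may contain no reference cell")
  n_h <- stats::rpois(1, hrsc_rate * area_mm2)
  hx <- stats::runif(n_h, 0, fs)
  hy <- stats::runif(n_h, 0, fs)
  meanlog <- if (ebv_status == "pos") mean(cfg$tarc_meanlog) else
    unname(cfg$tarc_meanlog[if (hla_status == "pos") "pos" else "neg"])

  mk_markers <- function(n, on) {
    m <- matrix(FALSE, n, length(HL_MARKERS),
                dimnames = list(NULL, HL_MARKERS))
    m[, on] <- TRUE
    m
  }

  parts <- list()
  if (n_h > 0)
    parts$hrsc <- data.frame(
      x = hx, y = hy, mk_markers(n_h, "CD30"),
      TARC = stats::rlnorm(n_h, meanlog, cfg$tarc_sdlog),
      area = stats::rgamma(n_h, 16, scale = cfg$hrsc_area_mean / 16),
      phenotype_class = "hrsc")

  for (k in names(cfg$phenotype_mix)) {
    f <- unname(cfg$close_enrichment[k])
    if (is.na(f)) f <- 1
    base <- cfg$immune_density * cfg$phenotype_mix[[k]] / 1e6  # per um^2
    fmax <- max(f, 1)
    n_cand <- stats::rpois(1, base * fmax * fs^2)
    if (n_cand == 0) next
    cx <- stats::runif(n_cand, 0, fs)
    cy <- stats::runif(n_cand, 0, fs)
    if (n_h > 0) {
      d <- .nearest_dist_xy(cx, cy, hx, hy)
      fac <- .enrichment_at(d, f, cfg$close_radius, cfg$distant_radius)
    } else fac <- rep(1, n_cand)
    keep <- stats::runif(n_cand) < fac / fmax
    n_k <- sum(keep)
    if (n_k == 0) next
    parts[[k]] <- data.frame(
      x = cx[keep], y = cy[keep], mk_markers(n_k, PHENOTYPE_CLASSES[[k]]),
      TARC = 0,
      area = stats::rgamma(n_k, 16, scale = cfg$immune_area_mean / 16),
      phenotype_class = k)
  }
  if (!length(parts))
    stop("simulated field contains no cells; increase densities or field size")
  cells <- do.call(rbind, parts)
  rownames(cells) <- NULL
  cell_map(cells, case_id = case_id,
           field_extent = c(0, fs, 0, fs),
           markers = HL_MARKERS, intensities = "TARC")
}

#' Configuration of the expression simulator
#'
#' @param n_genes total number of genes (signature genes included).
#' @param signature_genes named list; each element is `c(hla = , ebv = )`
#'   where `hla` is the log2 shift added to HLA-negative samples (i.e. the
#'   expected fold-change on the analysis scale, negative-group minus
#'   positive-group) and `ebv` the log2 shift added to EBV+ samples.
#' @param baseline_log_mean log2 of the mean count of an unshifted gene.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; NanoString counts are overdispersed relative to Poisson).
#' @param lod limit-of-detection count threshold carried into the matrix.
#' @param n_degraded number of leading samples rendered mostly undetected
#'   (mean scaled by `degraded_scale`), for exercising the LOD QC.
#' @param degraded_scale multiplicative mean reduction of degraded samples.
#' @param seed RNG seed.
#' @return list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 200,
                                  signature_genes = list(
                                    CCL17   = c(hla = 1.2, ebv = 0.3),
                                    CCL22   = c(hla = 1.0, ebv = 0.2),
                                    TNFRSF8 = c(hla = 0.8, ebv = 0),
                                    IL13    = c(hla = 0.7, ebv = 0),
                                    CD8B    = c(hla = -1.0, ebv = 0),
                                    MS4A1   = c(hla = -0.8, ebv = 0),
                                    CD19    = c(hla = -0.6, ebv = 0)),
                                  baseline_log_mean = 7, dispersion = 10,
                                  lod = 20, n_degraded = 0,
                                  degraded_scale = 0.01, seed = 1) {
  stopifnot(dispersion > 0, n_genes >= length(signature_genes),
            n_degraded >= 0, degraded_scale > 0)
  structure(list(n_genes = n_genes, signature_genes = signature_genes,
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion, lod = lod,
                 n_degraded = n_degraded, degraded_scale = degraded_scale,
                 seed = seed),
            class = "expression_sim_config")
}

#' Simulate a NanoString-like count matrix
#'
#' Counts are negative-binomial with per-gene, per-sample log2 means:
#' baseline, plus the signature `hla` shift for HLA-negative samples and the
#' `ebv` shift for EBV+ samples (non-evaluable statuses contribute no shift).
#'
#' @param cfg an [expression_sim_config()].
#' @param annotation a [sample_annotation()]; one sample (column) per row.
#' @param stratifier annotation column driving the `hla` shifts
#'   (default `"hla_i"`).
#' @return an [expression_matrix()] in `raw_counts` state with `lod` set.
#' @export
simulate_expression <- function(cfg, annotation, stratifier = "hla_i") {
  stopifnot(inherits(cfg, "expression_sim_config"),
            inherits(annotation, "sample_annotation"))
  set.seed(cfg$seed)
  n_sig <- length(cfg$signature_genes)
  genes <- c(names(cfg$signature_genes),
             sprintf("gene_%03d", seq_len(cfg$n_genes - n_sig)))
  n_s <- nrow(annotation)
  is_neg <- annotation[[stratifier]] == "neg"
  is_ebv <- annotation$ebv == "pos"

  logmu <- matrix(cfg$baseline_log_mean, cfg$n_genes, n_s,
                  dimnames = list(genes, annotation$sample_id))
  for (k in seq_len(n_sig)) {
    eff <- cfg$signature_genes[[k]]
    logmu[k, is_neg] <- logmu[k, is_neg] + eff[["hla"]]
    logmu[k, is_ebv] <- logmu[k, is_ebv] + eff[["ebv"]]
  }
  mu <- 2^logmu
  if (cfg$n_degraded > 0) {
    deg <- seq_len(min(cfg$n_degraded, n_s))
    mu[, deg] <- mu[, deg] * cfg$degraded_scale
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  expression_matrix(counts, state = "raw_counts", lod = cfg$lod)
}

#' Configuration of the repertoire simulator
#'
#' @param n_clones number of candidate clones.
#' @param skew concentration parameter of the symmetric Dirichlet clone-
#'   frequency model: small values give oligoclonal repertoires, large values
#'   near-uniform ones. The default (0.05 at 2000 clones) gives the highly
#'   polyclonal repertoires typical of the HL microenvironment.
#' @param seed RNG seed.
#' @return list of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(n_clones = 2000, skew = 0.05, seed = 1) {
  stopifnot(n_clones >= 1, skew > 0)
  structure(list(n_clones = n_clones, skew = skew, seed = seed),
            class = "repertoire_sim_config")
}

#' Simulate a TCR repertoire
#'
#' Clone frequencies are drawn from a symmetric Dirichlet with parameter
#' `skew` (gamma draws renormalized); clones whose draw underflows to zero
#' are dropped.
#'
#' @param cfg a [repertoire_sim_config()].
#' @param sample_id sample identifier.
#' @return a [repertoire()].
#' @export
simulate_repertoire <- function(cfg, sample_id = "sample_1") {
  stopifnot(inherits(cfg, "repertoire_sim_config"))
  set.seed(cfg$seed)
  w <- stats::rgamma(cfg$n_clones, shape = cfg$skew)
  if (all(w == 0)) w[1] <- 1  # pathological underflow at extreme skew
  repertoire(sample_id, sprintf("clone_%05d", seq_len(cfg$n_clones)), w)
}

# Deterministic per-case child seeds from one master seed: adding a case
# never perturbs earlier cases. Multipliers keep double arithmetic exact.
.child_seed <- function(master, i) {
  as.integer(((master %% 2147483647) * 69069 + i * 12345) %% 2147483647)
}

#' Simulate a full cohort
#'
#' Draws the annotation first (HLA-I, HLA-II, EBV conditional on HLA-I,
#' subtype conditional on HLA-I, each with a configurable non-evaluable
#' rate), then cell maps, the expression matrix and repertoires conditionally
#' independently given the annotation. All randomness descends from one
#' master seed through per-case child seeds.
#'
#' @param n_cases number of cases.
#' @param cell_cfg a [cohort_sim_config()] (per-case seeds are derived).
#' @param expr_cfg an [expression_sim_config()].
#' @param rep_cfg a [repertoire_sim_config()].
#' @param seed master seed.
#' @param hla_i_prevalence probability an evaluable case is HLA-I+
#'   (default 11/97, the prevalence in central-European adult HL).
#' @param hla_ii_prevalence probability an evaluable case is HLA-II+
#'   (default 53/98).
#' @param ebv_given_hla named (`pos`, `neg`) conditional probabilities of
#'   EBV+ given HLA-I status (defaults 5/11 and 7/86, odds ratio ~9.4).
#' @param subtype_probs list with elements `pos` and `neg`: probabilities of
#'   (nodular_sclerosis, mixed_cellularity, other) given HLA-I status.
#' @param na_rates named non-evaluable rates for `hla_i`, `hla_ii`, `ebv`,
#'   `subtype`.
#' @return list of class `hl_cohort` with elements `annotation`, `cell_maps`
#'   (named list), `expression`, `repertoires` (named list), `seed`.
#' @export
simulate_cohort <- function(n_cases = 97,
                            cell_cfg = cohort_sim_config(),
                            expr_cfg = expression_sim_config(),
                            rep_cfg = repertoire_sim_config(),
                            seed = 1,
                            hla_i_prevalence = 11 / 97,
                            hla_ii_prevalence = 53 / 98,
                            ebv_given_hla = c(pos = 5 / 11, neg = 7 / 86),
                            subtype_probs = list(
                              pos = c(0.375, 0.375, 0.25),
                              neg = c(0.835, 0.152, 0.013)),
                            na_rates = c(hla_i = 0.05, hla_ii = 0.02,
                                         ebv = 0.02, subtype = 0.05)) {
  stopifnot(n_cases >= 2, hla_i_prevalence >= 0, hla_i_prevalence <= 1)
  ids <- sprintf("case_%03d", seq_len(n_cases))
  subtypes <- c("nodular_sclerosis", "mixed_cellularity", "other")

  # Everything about case i descends from child seeds of i only, so growing
  # the cohort never perturbs the cases already drawn.
  draw_case_annotation <- function(i) {
    set.seed(.child_seed(seed, 4L * i))
    hla_i <- if (stats::runif(1) < na_rates[["hla_i"]]) "na" else
      if (stats::runif(1) < hla_i_prevalence) "pos" else "neg"
    hla_ii <- if (stats::runif(1) < na_rates[["hla_ii"]]) "na" else
      if (stats::runif(1) < hla_ii_prevalence) "pos" else "neg"
    p_ebv <- ebv_given_hla[[if (hla_i == "pos") "pos" else "neg"]]
    ebv <- if (stats::runif(1) < na_rates[["ebv"]]) "na" else
      if (stats::runif(1) < p_ebv) "pos" else "neg"
    subtype <- if (stats::runif(1) < na_rates[["subtype"]]) "na" else
      sample(subtypes, 1,
             prob = if (hla_i == "pos") subtype_probs$pos else subtype_probs$neg)
    c(hla_i = hla_i, hla_ii = hla_ii, ebv = ebv, subtype = subtype)
  }
  ann_rows <- t(vapply(seq_len(n_cases), draw_case_annotation, character(4)))
  ann <- sample_annotation(ids, ann_rows[, "hla_i"], ann_rows[, "hla_ii"],
                           ann_rows[, "ebv"], ann_rows[, "subtype"])

  maps <- lapply(seq_len(n_cases), function(i) {
    cfg_i <- cell_cfg
    cfg_i$seed <- .child_seed(seed, 4L * i + 1L)
    simulate_cell_map(cfg_i, case_id = ids[i], hla_status = ann$hla_i[i],
                      ebv_status = ann$ebv[i])
  })
  names(maps) <- ids

  cols <- lapply(seq_len(n_cases), function(i) {
    cfg_i <- expr_cfg
    cfg_i$seed <- .child_seed(seed, 4L * i + 2L)
    # n_degraded counts cohort samples; case i is degraded iff i <= n_degraded
    cfg_i$n_degraded <- as.integer(i <= expr_cfg$n_degraded)
    simulate_expression(cfg_i, ann[i, , drop = FALSE])$values
  })
  expr <- expression_matrix(do.call(cbind, cols), state = "raw_counts",
                            lod = expr_cfg$lod)

  reps <- lapply(seq_len(n_cases), function(i) {
    cfg_i <- rep_cfg
    cfg_i$seed <- .child_seed(seed, 4L * i + 3L)
    simulate_repertoire(cfg_i, sample_id = ids[i])
  })
  names(reps) <- ids

  structure(list(annotation = ann, cell_maps = maps, expression = expr,
                 repertoires = reps, seed = seed),
            class = "hl_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes the four table kinds in the package's interchange formats:
#' `cells.csv`, `expression.tsv`, `annotation.csv` and one
#' `repertoire_<case>.tsv` per case.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(cohort$cell_maps, file.path(dir, "cells.csv"))
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_sample_annotation(cohort$annotation, file.path(dir, "annotation.csv"))
  for (r in cohort$repertoires)
    write_repertoire(r, file.path(dir, paste0("repertoire_", r$sample_id, ".tsv")))
  invisible(dir)
}
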