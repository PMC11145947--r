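small_cell_cfg <- function(seed, ...) {
  cohort_sim_config(field_size = 500, immune_density = 1500,
                    hrsc_density = 40, seed = seed, ...)
}

test_that("identical config and seed reproduce the identical cohort", {
  args <- list(n_cases = 4,
               cell_cfg = small_cell_cfg(1),
               expr_cfg = expression_sim_config(n_genes = 30),
               rep_cfg = repertoire_sim_config(n_clones = 100),
               seed = 77)
  a <- suppressWarnings(do.call(simulate_cohort, args))
  b <- suppressWarnings(do.call(simulate_cohort, args))
  expect_identical(a, b)
})

test_that("adding cases never perturbs earlier cases", {
  mk <- function(n) suppressWarnings(simulate_cohort(
    n, cell_cfg = small_cell_cfg(1),
    expr_cfg = expression_sim_config(n_genes = 30),
    rep_cfg = repertoire_sim_config(n_clones = 100), seed = 5))
  a <- mk(4); b <- mk(6)
  expect_identical(as.data.frame(a$annotation),
                   as.data.frame(b$annotation)[1:4, ])
  expect_identical(a$cell_maps, b$cell_maps[1:4])
  expect_identical(a$expression$values, b$expression$values[, 1:4])
  expect_identical(a$repertoires, b$repertoires[1:4])
})

test_that("HRSC counts scale with the configured density", {
  count_at <- function(density) {
    counts <- vapply(1:30, function(s) {
      m <- simulate_cell_map(cohort_sim_config(field_size = 1000,
                                               hrsc_density = density,
                                               immune_density = 100,
                                               seed = s), "c", "neg")
      sum(m$cells$CD30)
    }, numeric(1))
    sum(counts)
  }
  n1 <- count_at(20)   # Poisson mean 20 per field, 30 fields
  n2 <- count_at(40)
  # totals ~600 and ~1200; ratio within 5 sd of 2
  expect_equal(n2 / n1, 2, tolerance = 0.25)
  expect_equal(n1, 600, tolerance = 0.2)
})

test_that("null enrichment gives equal zone composition up to sampling error", {
  flat <- stats::setNames(rep(1, length(hltme:::.default_mix)),
                          names(hltme:::.default_mix))
  tots <- c(close_n = 0, close_d = 0, dist_n = 0, dist_d = 0)
  for (s in 1:15) {
    cfg <- cohort_sim_config(field_size = 800, immune_density = 3000,
                             hrsc_density = 30, close_enrichment = flat,
                             seed = s)
    m <- simulate_cell_map(cfg, "c", "neg")
    comp <- suppressMessages(
      zone_composition(m, assign_zones(m), tme_marker_scheme()))
    cd68 <- comp[comp$phenotype == "CD68", ]
    cl <- cd68[cd68$zone == "close", ]; di <- cd68[cd68$zone == "distant", ]
    if (nrow(cl) && nrow(di))
      tots <- tots + c(cl$n_cells, cl$denominator_n, di$n_cells,
                       di$denominator_n)
  }
  # two-proportion test must not reject at alpha = 0.01 under the null
  pt <- prop.test(c(tots[["close_n"]], tots[["dist_n"]]),
                  c(tots[["close_d"]], tots[["dist_d"]]))
  expect_gt(pt$p.value, 0.01)
})

test_that("close enrichment is recovered as the close/distant fraction ratio", {
  f <- 3
  enr <- c(CD8_LAG3 = f)
  num <- c(0, 0); den <- c(0, 0)
  for (s in 1:8) {
    cfg <- cohort_sim_config(field_size = 1000, immune_density = 6000,
                             hrsc_density = 30, close_enrichment = enr,
                             seed = 100 + s)
    m <- simulate_cell_map(cfg, "c", "neg")
    comp <- suppressMessages(
      zone_composition(m, assign_zones(m),
                       phenotype_scheme(list(CD8_LAG3 = list(
                         pos = c("CD8", "LAG3"))), "all_cells")))
    for (k in 1:2) {
      z <- c("close", "distant")[k]
      row <- comp[comp$zone == z, ]
      num[k] <- num[k] + row$n_cells; den[k] <- den[k] + row$denominator_n
    }
  }
  ratio <- (num[1] / den[1]) / (num[2] / den[2])
  # generating intensity ratio is f, damped slightly by the enriched class's
  # own contribution to the close-zone denominator
  expect_equal(ratio, f, tolerance = 0.2)
})

test_that("expression simulator hits its negative-binomial targets", {
  ann <- balanced_annotation(50)
  cfg <- expression_sim_config(n_genes = 40, signature_genes = list(),
                               baseline_log_mean = 7, dispersion = 10,
                               seed = 2)
  m <- simulate_expression(cfg, ann)
  expect_equal(mean(m$values), 128, tolerance = 0.05)
  # dispersion -> infinity approaches Poisson (variance ~ mean)
  cfg_pois <- expression_sim_config(n_genes = 200, signature_genes = list(),
                                    dispersion = 1e9, seed = 3)
  mp <- simulate_expression(cfg_pois, ann)
  vmr <- mean(apply(mp$values, 1, var)) / mean(mp$values)
  expect_equal(vmr, 1, tolerance = 0.1)
  # finite dispersion is overdispersed: VMR ~ 1 + mu/size = 13.8
  vmr_nb <- mean(apply(m$values, 1, var)) / mean(m$values)
  expect_gt(vmr_nb, 5)
})

test_that("degraded samples fail the LOD QC they are built for", {
  ann <- balanced_annotation(4)
  cfg <- expression_sim_config(n_genes = 50, n_degraded = 2, seed = 9)
  m <- simulate_expression(cfg, ann)
  kept <- suppressMessages(qc_filter_samples(m))
  expect_equal(attr(kept, "removed"), ann$sample_id[1:2])
})

test_that("repertoire skew orders clonality as designed", {
  clon <- function(skew) vapply(1:20, function(s)
    simpson_clonality(simulate_repertoire(
      repertoire_sim_config(n_clones = 1000, skew = skew, seed = s)))$clonality,
    numeric(1))
  oligo <- clon(0.01); even <- clon(100)
  expect_gt(mean(oligo), mean(even))
  expect_true(all(oligo > even))
  # near-uniform limit: clonality approaches 1/sqrt(R)
  expect_equal(mean(even), 1 / sqrt(1000), tolerance = 0.05)
  # single clone is monoclonal by definition
  one <- simulate_repertoire(repertoire_sim_config(n_clones = 1, seed = 1))
  expect_equal(simpson_clonality(one)$clonality, 1)
})

test_that("annotation marginals follow the configured prevalences", {
  pos <- 0; evaluable <- 0
  for (s in 1:6) {
    co <- suppressWarnings(simulate_cohort(
      97, cell_cfg = cohort_sim_config(field_size = 250, immune_density = 400,
                                       hrsc_density = 40),
      expr_cfg = expression_sim_config(n_genes = 10),
      rep_cfg = repertoire_sim_config(n_clones = 20), seed = s))
    pos <- pos + sum(co$annotation$hla_i == "pos")
    evaluable <- evaluable + sum(co$annotation$hla_i != "na")
  }
  # binomial: 6 x 97 x 0.95 evaluable draws at prevalence 11/97
  p_hat <- pos / evaluable
  se <- sqrt((11 / 97) * (1 - 11 / 97) / evaluable)
  expect_lt(abs(p_hat - 11 / 97), 4 * se)
})

test_that("the configured HLA-EBV association is detectable at cohort size", {
  hits <- 0
  for (s in 1:8) {
    co <- suppressWarnings(simulate_cohort(
      97, cell_cfg = cohort_sim_config(field_size = 250, immune_density = 400,
                                       hrsc_density = 40),
      expr_cfg = expression_sim_config(n_genes = 10),
      rep_cfg = repertoire_sim_config(n_clones = 20), seed = 10 + s))
    p <- tryCatch(
      fisher_exact_2x2(build_contingency(co$annotation, "hla_i", "ebv"))$p_value,
      error = function(e) 1)
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 5)  # significant in the majority of seeds
})
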