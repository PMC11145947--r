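toy_map <- function(x, y, cd30, ...) {
  extra <- list(...)
  cells <- data.frame(x = x, y = y, CD30 = cd30)
  for (nm in names(extra)) cells[[nm]] <- extra[[nm]]
  cell_map(cells, case_id = "toy")
}

test_that("nearest-HRSC distance is the Euclidean minimum over CD30+ cells", {
  m <- toy_map(c(0, 3), c(0, 4), c(TRUE, FALSE))
  expect_equal(nearest_hrsc_distance(m), c(0, 5))

  m2 <- toy_map(c(0, 100, 60), c(0, 0, 0), c(TRUE, TRUE, FALSE))
  expect_equal(nearest_hrsc_distance(m2), c(0, 0, 40))

  no_hrsc <- toy_map(1, 1, FALSE)
  expect_error(nearest_hrsc_distance(no_hrsc), "no reference cells")
})

test_that("distances match the brute-force oracle exactly on random maps", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_cell_map(sample(50:400, 1), sample(1:15, 1))
    expect_identical(nearest_hrsc_distance(m), oracle_nearest_distance(m))
  }
})

test_that("zone boundaries are inclusive at 28.33 um and exclusive at 75 um", {
  m <- toy_map(c(0, 20, 28.33, 50, 75, 75.01, 200),
               rep(0, 7), c(TRUE, rep(FALSE, 6)))
  z <- assign_zones(m)
  expect_equal(as.character(z$zone),
               c("hrsc", "close", "close", "intermediate", "intermediate",
                 "distant", "distant"))
  expect_error(assign_zones(m, close_max = 80, distant_min = 75))
})

test_that("zones partition all non-HRSC cells", {
  set.seed(8)
  for (i in 1:5) {
    m <- random_cell_map(200, 5)
    z <- assign_zones(m)
    expect_false(anyNA(z$zone))
    expect_equal(sum(z$zone == "hrsc"), sum(m$cells$CD30))
    expect_equal(sum(z$zone %in% c("close", "intermediate", "distant")),
                 sum(!m$cells$CD30))
  }
})

test_that("spatial statistics are invariant under rigid transforms", {
  set.seed(13)
  m <- random_cell_map(300, 6)
  z <- assign_zones(m)
  for (i in 1:5) {
    theta <- runif(1, 0, 2 * pi)
    dx <- runif(1, -500, 500); dy <- runif(1, -500, 500)
    cells <- m$cells
    x <- cells$x * cos(theta) - cells$y * sin(theta) + dx
    y <- cells$x * sin(theta) + cells$y * cos(theta) + dy
    cells$x <- x; cells$y <- y
    zt <- assign_zones(cell_map(cells, "t"))
    expect_equal(zt$distance, z$distance, tolerance = 1e-9)
    expect_equal(as.character(zt$zone), as.character(z$zone))
  }
})

test_that("phenotype rules follow marker co-expression with HRSC precedence", {
  m <- toy_map(x = 1:5, y = 0, cd30 = c(TRUE, FALSE, FALSE, FALSE, TRUE),
               CD8 = c(FALSE, TRUE, TRUE, FALSE, TRUE),
               CD3 = c(FALSE, TRUE, TRUE, FALSE, FALSE),
               LAG3 = c(FALSE, FALSE, TRUE, FALSE, FALSE),
               FoxP3 = FALSE, PD1 = FALSE, TIM3 = FALSE,
               CD68 = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  lab <- classify_phenotypes(m, cd8_coexpression_scheme())
  # plain CD8: CD8_only and nothing else
  expect_true(lab[2, "CD8_only"])
  expect_false(any(lab[2, c("CD8_LAG3", "CD8_FoxP3", "CD8_PD1")]))
  # LAG3 co-expression removes CD8_only
  expect_true(lab[3, "CD8_LAG3"])
  expect_false(lab[3, "CD8_only"])
  # CD30+ cells never get immune labels, even when CD8+
  expect_false(any(lab[5, ]))

  bad <- phenotype_scheme(list(X = list(pos = "CD57")))
  expect_error(classify_phenotypes(m, bad), "CD57")
})

test_that("zone composition divides by the scheme denominator", {
  # 1 HRSC at origin; 10 close cells of which 4 CD68+; CD8 denominator case
  m <- toy_map(x = c(0, rep(5, 10), rep(200, 5)), y = 0,
               cd30 = c(TRUE, rep(FALSE, 15)),
               CD68 = c(FALSE, rep(c(TRUE, FALSE), c(4, 6)), rep(FALSE, 5)),
               CD8 = c(FALSE, rep(FALSE, 10), rep(TRUE, 5)),
               LAG3 = c(FALSE, rep(FALSE, 10), TRUE, TRUE, FALSE, FALSE, FALSE),
               FoxP3 = FALSE, PD1 = FALSE, TIM3 = FALSE, CD3 = FALSE)
  z <- assign_zones(m)
  comp <- zone_composition(m, z, tme_marker_scheme())
  close_cd68 <- comp[comp$zone == "close" & comp$phenotype == "CD68", ]
  expect_equal(close_cd68$n_cells, 4L)
  expect_equal(close_cd68$denominator_n, 10L)
  expect_equal(close_cd68$fraction, 0.4)

  cd8 <- suppressMessages(zone_composition(m, z, cd8_coexpression_scheme()))
  dist_lag3 <- cd8[cd8$zone == "distant" & cd8$phenotype == "CD8_LAG3", ]
  expect_equal(dist_lag3$fraction, 2 / 5)
  # close zone has no CD8+ cell: omitted, not divided by zero
  expect_false("close" %in% cd8$zone)
})

test_that("paired zone comparison equals the textbook paired t", {
  tab <- data.frame(case_id = rep(c("a", "b", "c"), each = 2),
                    zone = rep(c("close", "distant"), 3),
                    phenotype = "CD68",
                    n_cells = 1, denominator_n = 10,
                    fraction = c(0.2, 0.1, 0.3, 0.1, 0.25, 0.1))
  res <- compare_zones(tab, "CD68")
  oracle <- oracle_paired_t(c(0.1, 0.2, 0.15))
  expect_equal(res$t, oracle$t)
  expect_equal(res$p_value, oracle$p)
  expect_equal(res$mean_difference, 0.15)

  # negating differences negates t and keeps p
  tab_neg <- tab
  tab_neg$fraction <- c(0.1, 0.2, 0.1, 0.3, 0.1, 0.25)
  res_neg <- compare_zones(tab_neg, "CD68")
  expect_equal(res_neg$t, -res$t)
  expect_equal(res_neg$p_value, res$p_value)

  # identical fractions: no signal
  tab_same <- tab; tab_same$fraction <- 0.2
  same <- compare_zones(tab_same, "CD68")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_zones(tab[1:2, ], "CD68"), ">= 2 cases")
})

test_that("HLA scoring is strict at the 50% boundary", {
  expect_equal(score_hla_status(c(0.6, 0.5, 0.51, 0)),
               c("pos", "neg", "pos", "neg"))
  expect_error(score_hla_status(1.2), "\\[0, 1\\]")
})

test_that("CD30 area fraction is summed HRSC area over field area", {
  cells <- data.frame(x = c(50, 60), y = c(50, 60),
                      CD30 = c(TRUE, FALSE), area = c(100, 999))
  m <- cell_map(cells, "a", field_extent = c(0, 100, 0, 100))
  expect_equal(cd30_area_fraction(m), 1.0)

  none <- cell_map(data.frame(x = 1, y = 1, CD30 = FALSE, area = 10), "b",
                   field_extent = c(0, 100, 0, 100))
  expect_equal(cd30_area_fraction(none), 0)

  cells2 <- cells; cells2$area <- cells$area * 2
  m2 <- cell_map(cells2, "c", field_extent = c(0, 100, 0, 100))
  expect_equal(cd30_area_fraction(m2), 2 * cd30_area_fraction(m))

  expect_error(cd30_area_fraction(cell_map(cells, "d")), "extent")
})

test_that("HRSC marker intensity ignores immune cells", {
  cells <- data.frame(x = 1:4, y = 0, CD30 = c(TRUE, TRUE, FALSE, FALSE),
                      TARC = c(2, 4, 100, 200))
  m <- cell_map(cells, "a")
  res <- hrsc_marker_intensity(m, "TARC")
  expect_equal(res$mean, 3)
  expect_equal(res$median, 3)
  expect_equal(res$n_hrsc, 2)
  expect_error(hrsc_marker_intensity(m, "CCL22"), "CCL22")
})
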