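test_that("LOD QC removes samples at the 50% boundary inclusively", {
  counts <- matrix(1, 10, 3, dimnames = list(paste0("g", 1:10),
                                             c("keep6", "drop5", "drop0")))
  counts[1:6, 1] <- 100   # 6/10 above LOD -> retained
  counts[1:5, 2] <- 100   # exactly 50% -> removed
  m <- expression_matrix(counts, "raw_counts", lod = 10)
  filtered <- suppressMessages(qc_filter_samples(m))
  expect_equal(colnames(filtered$values), "keep6")
  expect_equal(attr(filtered, "removed"), c("drop5", "drop0"))

  # lod = 0 with all counts >= 1 keeps everything
  m0 <- expression_matrix(counts, "raw_counts", lod = 0)
  expect_equal(ncol(qc_filter_samples(m0)$values), 3L)

  all_low <- expression_matrix(matrix(1, 4, 2,
                                      dimnames = list(paste0("g", 1:4),
                                                      c("a", "b"))),
                               "raw_counts", lod = 10)
  expect_error(qc_filter_samples(all_low), "no samples pass QC")
})

test_that("normalization log2-transforms then centers each sample", {
  m <- expression_matrix(matrix(c(1, 3), 2, 1,
                                dimnames = list(c("g1", "g2"), "s1")),
                         "raw_counts")
  centered <- normalize_expression(m, pseudocount = 1)
  # log2(2)=1, log2(4)=2, mean 1.5
  expect_equal(unname(centered$values[, 1]), c(-0.5, 0.5))
  expect_equal(centered$state, "centered")

  single <- expression_matrix(matrix(7, 1, 3,
                                     dimnames = list("g", c("a", "b", "c"))),
                              "raw_counts")
  expect_equal(unname(normalize_expression(single)$values), matrix(0, 1, 3))

  # centering absorbs any per-sample scale factor (pseudocount 0)
  set.seed(4)
  counts <- matrix(rpois(60, 50) + 1, 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 2^5
  a <- normalize_expression(expression_matrix(counts, "raw_counts"), 0)
  b <- normalize_expression(expression_matrix(scaled, "raw_counts"), 0)
  expect_equal(a$values, b$values)
})

test_that("fold-change is negative-group mean minus positive-group mean", {
  ann <- balanced_annotation(2)
  v <- matrix(0, 3, 4,
              dimnames = list(c("flat", "shifted", "balance"), ann$sample_id))
  v["shifted", ] <- c(0.7, 0.7, 1.3, 1.3)  # pos mean 0.7, neg mean 1.3
  v["balance", ] <- -v["shifted", ]        # keeps sample means at zero
  m <- expression_matrix(v, "centered")
  fc <- fold_changes(m, ann)
  expect_equal(unname(fc["flat"]), 0)
  expect_equal(unname(fc["shifted"]), 0.6)

  # swapping group labels negates every fold-change
  ann_sw <- balanced_annotation(2)
  ann_sw$hla_i <- rev(ann_sw$hla_i)
  expect_equal(fold_changes(m, ann_sw), -fc)
})

test_that("Benjamini-Hochberg adjustment is the classical step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
})

test_that("volcano classification applies the printed boundary conventions", {
  res <- data.frame(gene = letters[1:5],
                    p_value = c(0.04, 0.04, 0.04, 0.06, 0.05),
                    fold_change = c(0.7, 0.6, -0.6, 0.7, 0.61))
  cls <- classify_volcano(res)$volcano_class
  expect_equal(as.character(cls),
               c("up_in_negative",     # p<=0.05, FC>0.6
                 "not_significant",    # FC exactly 0.6: strict >
                 "down_in_negative",   # FC exactly -0.6: inclusive <=
                 "not_significant",    # p above threshold
                 "up_in_negative"))    # p exactly 0.05: inclusive <=
})

test_that("per-gene logistic GLM finds no signal in a flat gene", {
  ann <- balanced_annotation(10)
  v <- matrix(0, 3, 20,
              dimnames = list(c("flat", "same", "balance"), ann$sample_id))
  v["same", ] <- rep(c(1, -1), 10)   # identical pattern in both groups
  v["balance", ] <- -v["same", ]     # keeps every sample mean at zero
  m <- expression_matrix(v, "centered")
  res <- suppressWarnings(differential_expression(m, ann))
  expect_equal(res$p_value[res$gene == "flat"], 1)
  expect_gt(res$p_value[res$gene == "same"], 0.9)
  expect_true(all(res$q_value >= res$p_value))
})

test_that("a strong simulated shift is detected and its fold-change recovered", {
  ann <- balanced_annotation(40)
  cfg <- expression_sim_config(n_genes = 50,
                               signature_genes = list(CCL17 = c(hla = 1.0,
                                                                ebv = 0)),
                               seed = 31)
  m <- simulate_expression(cfg, ann)
  centered <- normalize_expression(qc_filter_samples(m))
  res <- suppressWarnings(differential_expression(centered, ann))
  hit <- res[res$gene == "CCL17", ]
  expect_lt(hit$p_value, 0.01)
  expect_equal(hit$fold_change, 1.0, tolerance = 0.2)
  expect_equal(as.character(hit$volcano_class), "up_in_negative")
  # coefficient sign opposes the fold-change sign (higher expression in the
  # negative group pushes the pos-vs-neg logit down)
  expect_lt(hit$estimate * hit$fold_change, 0)
})

test_that("samples with non-evaluable status are dropped with a message", {
  ann <- balanced_annotation(3)
  ann$hla_i[1] <- "na"
  v <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("g1", "g2"), ann$sample_id))
  m <- centered_matrix(v)
  expect_message(differential_expression(m, ann), "non-evaluable")

  tiny <- balanced_annotation(2)
  tiny$hla_i[1:2] <- "na"  # leaves 0 pos samples
  v2 <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), tiny$sample_id))
  expect_error(suppressMessages(differential_expression(centered_matrix(v2),
                                                        tiny)),
               ">= 2 samples")
})

test_that("adjusting for EBV attenuates an EBV-driven association", {
  # EBV strongly associated with HLA-I; one gene responds to EBV only.
  set.seed(17)
  n <- 40
  hla <- rep(c("pos", "neg"), each = n)
  ebv <- ifelse(hla == "pos", ifelse(runif(2 * n) < 0.8, "pos", "neg"),
                ifelse(runif(2 * n) < 0.1, "pos", "neg"))
  ann <- sample_annotation(sprintf("s%03d", 1:(2 * n)), hla_i = hla, ebv = ebv)
  cfg <- expression_sim_config(n_genes = 30,
                               signature_genes = list(EBVG = c(hla = 0,
                                                               ebv = 2.0)),
                               seed = 5)
  centered <- normalize_expression(simulate_expression(cfg, ann))
  plain <- suppressWarnings(differential_expression(centered, ann))
  adj <- suppressWarnings(differential_expression(centered, ann,
                                                  confounder = "ebv"))
  p0 <- plain$p_value[plain$gene == "EBVG"]
  p1 <- adj$p_value[adj$gene == "EBVG"]
  expect_lt(p0, 0.05)   # spurious HLA association without adjustment
  expect_gt(p1, p0)     # attenuated once EBV enters the model
})
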