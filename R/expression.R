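# Bulk differential-expression stage: LOD-based sample QC, log2 + sample-mean
# centering, per-gene logistic GLM of HLA status on expression (optionally
# with an EBV confounder), fold-change on the centered log2 scale,
# Benjamini-Hochberg adjustment and volcano classification.

#' Remove samples with poor gene detection
#'
#' Drops every sample in which 50% or fewer of the genes are detected above
#' the limit of detection (counts strictly greater than `lod`); sample order
#' of the survivors is preserved.
#'
#' @param m an [expression_matrix()] in `raw_counts` state with `lod` set.
#' @return filtered `expression_matrix`; removed sample ids are attached as
#'   attribute `"removed"`.
#' @export
qc_filter_samples <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$state != "raw_counts") stop("QC operates on raw counts")
  if (is.null(m$lod)) stop("limit of detection (lod) is not set")
  lod <- rep_len(m$lod, ncol(m$values))
  frac_detected <- colMeans(sweep(m$values, 2, lod, ">"))
  keep <- frac_detected > 0.5
  if (!any(keep)) stop("no samples pass QC")
  removed <- colnames(m$values)[!keep]
  if (length(removed))
    message(length(removed), " sample(s) removed by LOD QC: ",
            paste(removed, collapse = ", "))
  out <- expression_matrix(m$values[, keep, drop = FALSE], "raw_counts",
                           lod = if (length(m$lod) > 1) m$lod[keep] else m$lod)
  attr(out, "removed") <- removed
  out
}

#' Log2-transform and center counts around the sample mean
#'
#' Values become `log2(count + pseudocount)` minus the mean of that sample
#' over genes, so that every sample has mean zero; state becomes `centered`.
#'
#' @param m an [expression_matrix()] in `raw_counts` state.
#' @param pseudocount added before the log (default 1; NanoString counts can
#'   be zero after background thresholding).
#' @return centered `expression_matrix`.
#' @export
normalize_expression <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$state != "raw_counts") stop("normalize operates on raw counts")
  if (any(m$values < 0)) stop("negative counts")
  lg <- log2(m$values + pseudocount)
  centered <- sweep(lg, 2, colMeans(lg))
  expression_matrix(centered, state = "centered", lod = m$lod)
}

# Align annotation rows to matrix samples and drop status-na samples.
.match_groups <- function(m, ann, stratifier, confounder = NULL) {
  stopifnot(inherits(ann, "sample_annotation"),
            stratifier %in% c("hla_i", "hla_ii"))
  idx <- match(colnames(m$values), ann$sample_id)
  if (anyNA(idx))
    stop("annotation is missing sample(s): ",
         paste(colnames(m$values)[is.na(idx)], collapse = ", "))
  status <- ann[[stratifier]][idx]
  keep <- status != "na"
  if (!is.null(confounder)) keep <- keep & ann[[confounder]][idx] != "na"
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " sample(s) removed (non-evaluable ", stratifier,
            if (!is.null(confounder)) paste0(" or ", confounder), ")")
  list(keep = keep, status = status[keep],
       confounder = if (!is.null(confounder)) ann[[confounder]][idx][keep])
}

#' Per-gene fold-changes between HLA groups
#'
#' The fold-change of a gene is the mean centered-log2 expression of the
#' HLA-negative group minus that of the HLA-positive group (positive values =
#' higher in HLA-negative cases).
#'
#' @param m an [expression_matrix()] in `centered` state.
#' @param ann a [sample_annotation()].
#' @param stratifier `"hla_i"` or `"hla_ii"`.
#' @return named numeric vector, one fold-change per gene.
#' @export
fold_changes <- function(m, ann, stratifier = "hla_i") {
  if (m$state != "centered") stop("fold-changes are defined on centered values")
  g <- .match_groups(m, ann, stratifier)
  v <- m$values[, g$keep, drop = FALSE]
  if (!sum(g$status == "neg") || !sum(g$status == "pos"))
    stop("both HLA groups must be non-empty")
  rowMeans(v[, g$status == "neg", drop = FALSE]) -
    rowMeans(v[, g$status == "pos", drop = FALSE])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving on input positions.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values, `p <= q <= 1`, in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression by per-gene logistic GLM
#'
#' For each gene, fits a binomial GLM (logit link) of HLA status (pos = 1) on
#' that gene's centered expression, optionally with an EBV-status indicator
#' as a second predictor, and reports the two-sided Wald p-value of the gene
#' coefficient. Samples with non-evaluable status (or confounder) are dropped
#' with a message. Fold-changes come from [fold_changes()], q-values from
#' [bh_adjust()], volcano classes from [classify_volcano()].
#'
#' @param m an [expression_matrix()] in `centered` state.
#' @param ann a [sample_annotation()].
#' @param stratifier `"hla_i"` or `"hla_ii"` (the GLM response).
#' @param confounder `NULL` or `"ebv"`.
#' @param p_threshold,fc_threshold volcano thresholds (defaults 0.05 and 0.6).
#' @return data.frame of class `de_result` with columns `gene`, `estimate`
#'   (GLM coefficient), `p_value`, `q_value`, `fold_change`, `volcano_class`,
#'   `separated` (TRUE where the fit reached complete/quasi separation).
#' @export
differential_expression <- function(m, ann, stratifier = "hla_i",
                                    confounder = NULL,
                                    p_threshold = 0.05, fc_threshold = 0.6) {
  if (m$state != "centered")
    stop("differential expression requires centered values; run normalize_expression()")
  if (!is.null(confounder) && !identical(confounder, "ebv"))
    stop("supported confounder: 'ebv' (or NULL)")
  g <- .match_groups(m, ann, stratifier, confounder)
  v <- m$values[, g$keep, drop = FALSE]
  y <- as.integer(g$status == "pos")
  if (sum(y) < 2L || sum(1L - y) < 2L)
    stop("each HLA group needs >= 2 samples (got ", sum(y), " pos / ",
         sum(1L - y), " neg)")
  conf <- if (!is.null(confounder)) as.integer(g$confounder == "pos")

  fit_one <- function(expr) {
    separated <- FALSE
    dat <- if (is.null(conf)) data.frame(y = y, expr = expr)
           else data.frame(y = y, expr = expr, conf = conf)
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (!"expr" %in% rownames(co))
      return(c(est = 0, p = 1, sep = as.numeric(separated)))
    c(est = co["expr", "Estimate"], p = co["expr", "Pr(>|z|)"],
      sep = as.numeric(separated))
  }

  fits <- t(apply(v, 1L, fit_one))
  separated <- fits[, "sep"] > 0
  if (any(separated))
    warning(sum(separated), " gene(s) reached (quasi-)separation; ",
            "Wald p-values for these are unreliable and capped at 1")
  p <- pmin(fits[, "p"], 1)
  fc <- fold_changes(m, ann, stratifier)
  res <- data.frame(gene = rownames(v), estimate = fits[, "est"],
                    p_value = unname(p), q_value = bh_adjust(unname(p)),
                    fold_change = unname(fc[rownames(v)]),
                    separated = unname(separated),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- classify_volcano(res, p_threshold, fc_threshold)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Volcano classification of DE results
#'
#' A gene is `up_in_negative` if `p <= p_threshold` and `fold_change >
#' fc_threshold` (strict), `down_in_negative` if `p <= p_threshold` and
#' `fold_change <= -fc_threshold` (inclusive), else `not_significant`.
#' Classification uses the raw p-value; q-values are reported alongside.
#'
#' @param results data.frame with `p_value` and `fold_change` columns.
#' @param p_threshold,fc_threshold thresholds (defaults 0.05, 0.6 on the log2
#'   scale).
#' @return `results` with a `volcano_class` factor column added/replaced.
#' @export
classify_volcano <- function(results, p_threshold = 0.05, fc_threshold = 0.6) {
  stopifnot(all(c("p_value", "fold_change") %in% names(results)))
  sig <- results$p_value <= p_threshold
  cls <- ifelse(sig & results$fold_change > fc_threshold, "up_in_negative",
                ifelse(sig & results$fold_change <= -fc_threshold,
                       "down_in_negative", "not_significant"))
  results$volcano_class <- factor(cls, levels = c("up_in_negative",
                                                  "down_in_negative",
                                                  "not_significant"))
  results
}

#' Volcano plot of DE results
#'
#' @param results a [differential_expression()] result.
#' @param p_threshold,fc_threshold thresholds drawn as guide lines.
#' @return a ggplot object.
#' @importFrom rlang .data
#' @export
plot_volcano <- function(results, p_threshold = 0.05, fc_threshold = 0.6) {
  stopifnot(all(c("p_value", "fold_change", "volcano_class") %in% names(results)))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$fold_change,
                               y = -log10(.data$p_value),
                               colour = .data$volcano_class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up_in_negative = "#c0392b",
                                            down_in_negative = "#2471a3",
                                            not_significant = "grey60")) +
    ggplot2::labs(x = "fold-change (mean log2, HLA- minus HLA+)",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}
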