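# Simpson's clonality of TCR-beta repertoires. Following the Adaptive
# Biotechnologies convention, clonality is the square root of Simpson's index
# (sum of squared clone frequencies): 0 = perfectly even, 1 = monoclonal.
# The unrooted index is reported alongside.

#' Simpson's clonality of a repertoire
#'
#' @param rep a [repertoire()] (frequencies sum to one).
#' @return list with `sample_id`, `simpson_index` (sum of squared
#'   frequencies), `clonality` (its square root) and `richness` (clone count).
#' @examples
#' r <- repertoire("s1", paste0("c", 1:4), rep(25, 4))
#' simpson_clonality(r)$clonality  # 1/sqrt(4) = 0.5
#' @export
simpson_clonality <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  p <- rep$frequencies
  if (!length(p)) stop("empty repertoire")
  idx <- sum(p^2)
  list(sample_id = rep$sample_id, simpson_index = idx,
       clonality = sqrt(idx), richness = length(p))
}

#' Clonality of a list of repertoires
#'
#' @param reps list of [repertoire()] objects.
#' @return data.frame with one row per sample: `sample_id`, `simpson_index`,
#'   `clonality`, `richness`.
#' @export
clonality_table <- function(reps) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  rows <- lapply(reps, function(r) as.data.frame(simpson_clonality(r)))
  do.call(rbind, rows)
}

#' Compare clonality between HLA groups
#'
#' Unpaired two-sided t-test of Simpson's clonality between HLA-positive and
#' HLA-negative samples; samples with non-evaluable status are dropped.
#'
#' @param results a [clonality_table()] data.frame.
#' @param ann a [sample_annotation()].
#' @param stratifier `"hla_i"` or `"hla_ii"`.
#' @return list with `t`, `df`, `p_value`, `mean_pos`, `mean_neg`,
#'   `n_pos`, `n_neg`.
#' @export
compare_clonality <- function(results, ann, stratifier = "hla_i") {
  stopifnot(inherits(ann, "sample_annotation"),
            stratifier %in% c("hla_i", "hla_ii"))
  idx <- match(results$sample_id, ann$sample_id)
  if (anyNA(idx))
    stop("annotation is missing sample(s): ",
         paste(results$sample_id[is.na(idx)], collapse = ", "))
  status <- ann[[stratifier]][idx]
  pos <- results$clonality[status == "pos"]
  neg <- results$clonality[status == "neg"]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each group needs >= 2 samples after dropping na (got ",
         length(pos), " pos / ", length(neg), " neg)")
  if (stats::sd(pos) == 0 && stats::sd(neg) == 0) {
    # degenerate groups: identical -> no evidence; constant but different ->
    # infinitely strong evidence on the t scale
    same <- mean(pos) == mean(neg)
    return(list(t = if (same) 0 else Inf * sign(mean(pos) - mean(neg)),
                df = length(pos) + length(neg) - 2,
                p_value = if (same) 1 else 0,
                mean_pos = mean(pos), mean_neg = mean(neg),
                n_pos = length(pos), n_neg = length(neg)))
  }
  tt <- stats::t.test(pos, neg)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_pos = mean(pos), mean_neg = mean(neg),
       n_pos = length(pos), n_neg = length(neg))
}
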