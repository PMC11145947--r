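#' @keywords internal
"_PACKAGE"

# Marker panel shared across the package. CD30 identifies HRSCs; the rest are
# immune-phenotype markers from the multiplex panels.
HL_MARKERS <- c("CD30", "CD8", "CD3", "CD68", "LAG3", "FoxP3", "PD1", "TIM3")

ANNOTATION_LEVELS <- list(
  hla_i   = c("pos", "neg", "na"),
  hla_ii  = c("pos", "neg", "na"),
  ebv     = c("pos", "neg", "na"),
  subtype = c("nodular_sclerosis", "mixed_cellularity", "other", "na")
)

#' Construct a cell map
#'
#' A cell map holds the QuPath-style cell detections of one case: centroid
#' coordinates in micrometers, boolean marker positivity calls, optional
#' per-cell marker intensities and optional cell areas. It is the substrate of
#' all spatial operations.
#'
#' @param cells data.frame with numeric columns `x`, `y` (micrometers), one
#'   logical column per marker (must include `CD30`), optionally numeric
#'   intensity columns (any name, e.g. `TARC`) and an optional numeric
#'   `area` column (square micrometers).
#' @param case_id single case identifier.
#' @param field_extent optional numeric vector `c(xmin, xmax, ymin, ymax)`
#'   giving the imaged field; all cells must lie inside it.
#' @param markers character vector naming the logical marker columns. Defaults
#'   to the logical columns of `cells`.
#' @param intensities character vector naming the intensity columns. Defaults
#'   to numeric columns other than `x`, `y`, `area`.
#' @return object of class `cell_map`: a list with elements `case_id`, `cells`,
#'   `markers`, `intensities`, `field_extent`.
#' @examples
#' cm <- cell_map(
#'   data.frame(x = c(0, 10), y = c(0, 0), CD30 = c(TRUE, FALSE),
#'              CD8 = c(FALSE, TRUE)),
#'   case_id = "case_1")
#' n_cells(cm)
#' @export
cell_map <- function(cells, case_id, field_extent = NULL,
                     markers = NULL, intensities = NULL) {
  stopifnot(is.data.frame(cells), length(case_id) == 1L)
  cells <- as.data.frame(cells)
  if (!all(c("x", "y") %in% names(cells)))
    stop("cell table must contain 'x' and 'y' coordinate columns")
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("cell coordinates must be finite")
  if (is.null(markers))
    markers <- names(cells)[vapply(cells, is.logical, logical(1))]
  if (!"CD30" %in% markers)
    stop("marker map must contain CD30 (HRSC identification)")
  for (m in markers) {
    if (!is.logical(cells[[m]])) stop("marker column '", m, "' must be logical")
    if (anyNA(cells[[m]])) stop("marker column '", m, "' contains NA calls")
  }
  if (is.null(intensities)) {
    num <- names(cells)[vapply(cells, is.numeric, logical(1))]
    intensities <- setdiff(num, c("x", "y", "area"))
  }
  for (i in intensities) {
    v <- cells[[i]]
    if (any(v[!is.na(v)] < 0)) stop("intensity column '", i, "' has negative values")
  }
  if (!is.null(cells$area) && any(cells$area[!is.na(cells$area)] < 0))
    stop("cell areas must be nonnegative")
  if (!is.null(field_extent)) {
    stopifnot(length(field_extent) == 4L)
    if (nrow(cells) > 0 &&
        (any(cells$x < field_extent[1]) || any(cells$x > field_extent[2]) ||
         any(cells$y < field_extent[3]) || any(cells$y > field_extent[4])))
      stop("cells lie outside the stated field extent")
  }
  structure(list(case_id = as.character(case_id), cells = cells,
                 markers = markers, intensities = intensities,
                 field_extent = field_extent),
            class = "cell_map")
}

#' @rdname cell_map
#' @param x a `cell_map`.
#' @export
n_cells <- function(x) nrow(x$cells)

#' @export
print.cell_map <- function(x, ...) {
  cat("<cell_map> case", x$case_id, "-", n_cells(x), "cells,",
      sum(x$cells$CD30), "CD30+ (HRSC)\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  if (length(x$intensities))
    cat("  intensities:", paste(x$intensities, collapse = ", "), "\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' Genes-by-samples matrix of NanoString-like counts, carrying a transformation
#' state so that downstream stages can insist on their required preprocessing:
#' `raw_counts` (nonnegative counts), `log2` (log2 of counts + pseudocount), or
#' `centered` (log2 values centered to mean zero within each sample).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param state one of `"raw_counts"`, `"log2"`, `"centered"`.
#' @param lod limit-of-detection count threshold used by sample QC; a single
#'   number or one per sample.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, state = c("raw_counts", "log2", "centered"),
                              lod = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("gene symbols (rownames) are required")
  if (is.null(colnames(values))) stop("sample ids (colnames) are required")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  if (state == "raw_counts" && any(values < 0))
    stop("raw counts must be nonnegative")
  if (state == "centered") {
    cm <- colMeans(values)
    if (any(abs(cm) > 1e-9))
      stop("state 'centered' requires per-sample means of 0 (max |mean| = ",
           format(max(abs(cm))), ")")
  }
  if (!is.null(lod)) {
    stopifnot(length(lod) == 1L || length(lod) == ncol(values))
  }
  structure(list(values = values, state = state, lod = lod),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$values), "genes x", ncol(x$values),
      "samples, state =", x$state,
      if (!is.null(x$lod)) paste0(", lod = ", paste(unique(x$lod), collapse = "/")),
      "\n")
  invisible(x)
}

#' Construct a sample annotation table
#'
#' Per-sample HLA-I, HLA-II, EBV status and histologic subtype. `"na"` is a
#' first-class level (not evaluable) and is dropped case-wise by each analysis
#' that stratifies on the respective variable.
#'
#' @param sample_id character vector of unique sample ids.
#' @param hla_i,hla_ii,ebv each `"pos"`, `"neg"` or `"na"`, recycled if scalar.
#' @param subtype `"nodular_sclerosis"`, `"mixed_cellularity"`, `"other"` or
#'   `"na"`, recycled if scalar.
#' @return data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, hla_i = "na", hla_ii = "na",
                              ebv = "na", subtype = "na") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  out <- data.frame(sample_id = as.character(sample_id),
                    hla_i = rep_len(as.character(hla_i), n),
                    hla_ii = rep_len(as.character(hla_ii), n),
                    ebv = rep_len(as.character(ebv), n),
                    subtype = rep_len(as.character(subtype), n),
                    stringsAsFactors = FALSE)
  for (v in names(ANNOTATION_LEVELS)) {
    bad <- setdiff(unique(out[[v]]), ANNOTATION_LEVELS[[v]])
    if (length(bad))
      stop("invalid value(s) for ", v, ": ", paste(bad, collapse = ", "))
  }
  class(out) <- c("sample_annotation", "data.frame")
  out
}

#' Construct a TCR repertoire
#'
#' Clone-level productive frequencies for one sample. Zero-count clones are
#' dropped and frequencies are renormalized to sum to one.
#'
#' @param sample_id sample identifier.
#' @param clone_ids character vector of clone identifiers.
#' @param frequencies positive weights (counts or frequencies); renormalized.
#' @return object of class `repertoire` with elements `sample_id`, `clone_ids`,
#'   `frequencies`.
#' @export
repertoire <- function(sample_id, clone_ids, frequencies) {
  stopifnot(length(clone_ids) == length(frequencies))
  keep <- frequencies > 0
  if (any(frequencies < 0)) stop("clone frequencies must be nonnegative")
  clone_ids <- as.character(clone_ids)[keep]
  frequencies <- frequencies[keep]
  if (!length(frequencies)) stop("empty repertoire")
  frequencies <- frequencies / sum(frequencies)
  structure(list(sample_id = as.character(sample_id),
                 clone_ids = clone_ids, frequencies = frequencies),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("<repertoire>", x$sample_id, "-", length(x$frequencies), "clones\n")
  invisible(x)
}

#' Construct a contingency table
#'
#' r x c nonnegative integer counts with row/column labels, the input of
#' [fisher_exact_2x2()] and [chi_square_rxc()].
#'
#' @param counts integer matrix (r >= 2, c >= 2) of nonnegative counts.
#' @param row_labels,col_labels optional dimnames.
#' @return object of class `contingency_table` (an integer matrix).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) <= 0) stop("grand total must be positive")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  class(counts) <- c("contingency_table", class(counts))
  counts
}
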