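# Tabular IO for the four input kinds. Delimiter is inferred from the file
# extension (.csv -> comma, anything else -> tab); header row required; UTF-8.

.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = .delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8")
}

.write_table <- function(df, path) {
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}

# Accepts "1"/"0", "true"/"false", "pos"/"neg" (any case) and native logicals.
.parse_bool <- function(x, column) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "pos", "t", "yes")] <- TRUE
  out[s %in% c("0", "false", "neg", "f", "no")] <- FALSE
  if (anyNA(out))
    stop("column '", column, "': unparseable boolean value(s): ",
         paste(utils::head(unique(s[is.na(out)]), 3), collapse = ", "))
  out
}

#' Default column-name mapping for cell tables
#'
#' Maps the on-disk schema (`case_id`, `x_um`, `y_um`, `<MARKER>_pos`,
#' `<MARKER>_intensity`, `area_um2`) to the in-memory [cell_map()] fields.
#' Override entries to adapt other export schemas (e.g. raw QuPath column
#' names).
#'
#' @param case_id,x,y,area names of the respective columns.
#' @param marker_suffix suffix identifying boolean positivity-call columns.
#' @param intensity_suffix suffix identifying numeric intensity columns.
#' @return named list usable as the `dialect` of [read_cell_table()].
#' @export
cell_table_dialect <- function(case_id = "case_id", x = "x_um", y = "y_um",
                               area = "area_um2", marker_suffix = "_pos",
                               intensity_suffix = "_intensity") {
  list(case_id = case_id, x = x, y = y, area = area,
       marker_suffix = marker_suffix, intensity_suffix = intensity_suffix)
}

#' Read cell-detection tables into cell maps
#'
#' Reads a CSV/TSV of cell detections (one row per cell, possibly several
#' cases per file) and partitions it into one [cell_map()] per case. Marker
#' columns are parsed as booleans ("1"/"0", "true"/"false", "pos"/"neg");
#' unmapped numeric columns are preserved as intensities.
#'
#' @param path CSV or TSV file.
#' @param dialect column-name mapping, see [cell_table_dialect()].
#' @return named list of `cell_map`, one per distinct case id, in order of
#'   first appearance.
#' @export
read_cell_table <- function(path, dialect = cell_table_dialect()) {
  df <- .read_table(path)
  for (col in c("case_id", "x", "y")) {
    if (!dialect[[col]] %in% names(df))
      stop("cell table is missing required column '", dialect[[col]], "'")
  }
  marker_cols <- grep(paste0(dialect$marker_suffix, "$"), names(df), value = TRUE)
  markers <- sub(paste0(dialect$marker_suffix, "$"), "", marker_cols)
  if (!"CD30" %in% markers)
    stop("cell table is missing required column 'CD30", dialect$marker_suffix, "'")
  intensity_cols <- grep(paste0(dialect$intensity_suffix, "$"), names(df), value = TRUE)
  intens <- sub(paste0(dialect$intensity_suffix, "$"), "", intensity_cols)

  for (col in c(dialect$x, dialect$y)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric coordinate in column '", col, "' at data row(s) ",
           paste(utils::head(which(is.na(v)), 3), collapse = ", "))
    df[[col]] <- v
  }

  ids <- unique(as.character(df[[dialect$case_id]]))
  maps <- lapply(ids, function(id) {
    rows <- df[as.character(df[[dialect$case_id]]) == id, , drop = FALSE]
    cells <- data.frame(x = rows[[dialect$x]], y = rows[[dialect$y]])
    for (k in seq_along(markers))
      cells[[markers[k]]] <- .parse_bool(rows[[marker_cols[k]]], marker_cols[k])
    for (k in seq_along(intens))
      cells[[intens[k]]] <- as.numeric(rows[[intensity_cols[k]]])
    if (dialect$area %in% names(rows)) cells$area <- as.numeric(rows[[dialect$area]])
    cell_map(cells, case_id = id, markers = markers, intensities = intens)
  })
  stats::setNames(maps, ids)
}

#' Write cell maps to a cell table
#'
#' Inverse of [read_cell_table()]; all maps are concatenated into one file.
#'
#' @param maps a `cell_map` or list of them.
#' @param path output CSV/TSV path.
#' @param dialect column-name mapping, see [cell_table_dialect()].
#' @export
write_cell_table <- function(maps, path, dialect = cell_table_dialect()) {
  if (inherits(maps, "cell_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    df <- data.frame(case_id = rep(m$case_id, n_cells(m)),
                     x = m$cells$x, y = m$cells$y)
    names(df) <- c(dialect$case_id, dialect$x, dialect$y)
    for (mk in m$markers)
      df[[paste0(mk, dialect$marker_suffix)]] <- as.integer(m$cells[[mk]])
    for (it in m$intensities)
      df[[paste0(it, dialect$intensity_suffix)]] <- m$cells[[it]]
    if (!is.null(m$cells$area)) df[[dialect$area]] <- m$cells$area
    df
  })
  .write_table(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' TSV with gene symbols in the first column and one column per sample.
#' The result is in `raw_counts` state.
#'
#' @param path TSV file.
#' @param lod optional limit-of-detection threshold to attach.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, lod = NULL) {
  df <- .read_table(path)
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(values < 0)) stop("negative counts in expression matrix")
  rownames(values) <- genes
  expression_matrix(values, state = "raw_counts", lod = lod)
}

#' @rdname read_expression_matrix
#' @param m an `expression_matrix`.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  .write_table(df, path)
  invisible(path)
}

#' Read a TCR clone table
#'
#' TSV with columns `clone_id` and `count` (or `frequency`), one clone per
#' row (productive rearrangements only, Adaptive-export-like subset).
#' Zero-count clones are dropped; frequencies are renormalized.
#'
#' @param path TSV file.
#' @param sample_id sample identifier; default is the file name without
#'   extension.
#' @return a [repertoire()].
#' @export
read_repertoire <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- .read_table(path)
  wcol <- intersect(c("count", "frequency"), names(df))
  if (!"clone_id" %in% names(df) || !length(wcol))
    stop("repertoire table needs columns 'clone_id' and 'count' or 'frequency'")
  w <- as.numeric(df[[wcol[1]]])
  if (all(w == 0)) stop("empty repertoire")
  repertoire(sample_id, df$clone_id, w)
}

#' @rdname read_repertoire
#' @param rep a `repertoire`.
#' @export
write_repertoire <- function(rep, path) {
  .write_table(data.frame(clone_id = rep$clone_ids, frequency = rep$frequencies),
               path)
  invisible(path)
}

#' Read / write sample annotations
#'
#' CSV with columns `sample_id`, `hla_i`, `hla_ii`, `ebv`, `subtype`;
#' `"na"` marks a non-evaluable status.
#'
#' @param path CSV file.
#' @return a [sample_annotation()].
#' @export
read_sample_annotation <- function(path) {
  df <- .read_table(path)
  need <- c("sample_id", "hla_i", "hla_ii", "ebv", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  sample_annotation(df$sample_id, df$hla_i, df$hla_ii, df$ebv, df$subtype)
}

#' @rdname read_sample_annotation
#' @param ann a `sample_annotation`.
#' @export
write_sample_annotation <- function(ann, path) {
  .write_table(as.data.frame(ann), path)
  invisible(path)
}
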