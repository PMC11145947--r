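# Spatial zoning of multiplexed cell maps around HRSCs.
#
# The zoning radii follow the published image-analysis convention: "close" is
# at most 28.33 um from the nearest HRSC (inclusive), "distant" is strictly
# beyond 75 um; everything in between is "intermediate" and excluded from the
# close/distant contrasts. HRSCs are the CD30+ detections.

ZONE_LEVELS <- c("hrsc", "close", "intermediate", "distant")

#' Distance of every cell to the nearest HRSC
#'
#' Euclidean centroid-to-centroid distance from each cell to the nearest
#' CD30+ cell of the same map. CD30+ cells themselves get distance 0.
#'
#' @param map a [cell_map()] containing at least one CD30+ cell.
#' @return numeric vector of distances (micrometers), one per cell, in cell
#'   order.
#' @export
nearest_hrsc_distance <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  hrsc <- map$cells$CD30
  if (!any(hrsc)) stop("no reference cells: map contains no CD30+ cell")
  hx <- map$cells$x[hrsc]
  hy <- map$cells$y[hrsc]
  d2 <- outer(map$cells$x, hx, "-")^2 + outer(map$cells$y, hy, "-")^2
  d <- sqrt(.rowMins(d2))
  d[hrsc] <- 0
  d
}

.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Assign close / intermediate / distant zones
#'
#' Labels every cell of a map by its distance to the nearest HRSC: CD30+
#' cells are `hrsc`; other cells are `close` if the distance is at most
#' `close_max` (inclusive), `distant` if strictly greater than `distant_min`,
#' and `intermediate` otherwise.
#'
#' @param map a [cell_map()].
#' @param close_max close-zone radius in micrometers (default 28.33).
#' @param distant_min distant-zone inner radius in micrometers (default 75).
#' @return object of class `zone_assignment`: list with `distance` (numeric),
#'   `zone` (factor with levels hrsc/close/intermediate/distant), the radii,
#'   and `counts` (per-zone cell counts).
#' @export
assign_zones <- function(map, close_max = 28.33, distant_min = 75) {
  stopifnot(close_max < distant_min, close_max > 0)
  d <- nearest_hrsc_distance(map)
  zone <- ifelse(map$cells$CD30, "hrsc",
                 ifelse(d <= close_max, "close",
                        ifelse(d > distant_min, "distant", "intermediate")))
  zone <- factor(zone, levels = ZONE_LEVELS)
  structure(list(distance = d, zone = zone, close_max = close_max,
                 distant_min = distant_min, counts = table(zone)),
            class = "zone_assignment")
}

#' @export
print.zone_assignment <- function(x, ...) {
  cat("<zone_assignment> close <=", x$close_max, "um, distant >",
      x$distant_min, "um\n")
  print(x$counts)
  invisible(x)
}

#' Define a phenotype-labelling scheme
#'
#' A scheme is an ordered set of rules mapping marker-call combinations to
#' phenotype labels, plus the denominator used by [zone_composition()].
#' Labels are not required to partition the cells: a cell may satisfy several
#' rules (e.g. CD8_LAG3 and CD8_PD1) and fractions are per-label.
#'
#' @param rules named list; each element is a list with character vectors
#'   `pos` (markers that must be positive) and `neg` (markers that must be
#'   negative).
#' @param denominator `"all_cells"` (all non-HRSC cells in the zone) or
#'   `"cd8_cells"` (CD8+ non-HRSC cells in the zone).
#' @return object of class `phenotype_scheme`.
#' @seealso [tme_marker_scheme()], [cd8_coexpression_scheme()]
#' @export
phenotype_scheme <- function(rules, denominator = c("all_cells", "cd8_cells")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  rules <- lapply(rules, function(r) {
    list(pos = as.character(r$pos %||% character()),
         neg = as.character(r$neg %||% character()))
  })
  structure(list(rules = rules, denominator = denominator),
            class = "phenotype_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canned scheme: major TME populations as fractions of all cells
#'
#' One single-marker label per TME population (CD68 macrophages, CD8 T cells,
#' LAG3+, FoxP3+ and PD1+ cells), with all non-HRSC cells as denominator —
#' the zone-composition readout of the five-marker panel.
#'
#' @return a [phenotype_scheme()].
#' @export
tme_marker_scheme <- function() {
  phenotype_scheme(
    list(CD68  = list(pos = "CD68"),
         CD8   = list(pos = "CD8"),
         LAG3  = list(pos = "LAG3"),
         FoxP3 = list(pos = "FoxP3"),
         PD1   = list(pos = "PD1")),
    denominator = "all_cells")
}

#' Canned scheme: CD8+ co-expression phenotypes
#'
#' CD8+ cells lacking LAG3, FoxP3 and PD1 ("CD8_only") or co-expressing the
#' respective checkpoint/Treg marker, as fractions of all CD8+ cells. A
#' CD8_TIM3 label is included for the TIM3 co-expression readout.
#'
#' @param include_tim3 include the CD8_TIM3 label (default TRUE).
#' @return a [phenotype_scheme()].
#' @export
cd8_coexpression_scheme <- function(include_tim3 = TRUE) {
  rules <- list(
    CD8_only  = list(pos = "CD8", neg = c("LAG3", "FoxP3", "PD1")),
    CD8_LAG3  = list(pos = c("CD8", "LAG3")),
    CD8_FoxP3 = list(pos = c("CD8", "FoxP3")),
    CD8_PD1   = list(pos = c("CD8", "PD1")))
  if (include_tim3) rules$CD8_TIM3 <- list(pos = c("CD8", "TIM3"))
  phenotype_scheme(rules, denominator = "cd8_cells")
}

#' Label cells with phenotypes
#'
#' Applies a [phenotype_scheme()] to a map. CD30+ cells (HRSCs) are excluded
#' from every immune label.
#'
#' @param map a [cell_map()].
#' @param scheme a [phenotype_scheme()].
#' @return logical matrix, cells x labels.
#' @export
classify_phenotypes <- function(map, scheme) {
  stopifnot(inherits(map, "cell_map"), inherits(scheme, "phenotype_scheme"))
  used <- unique(unlist(lapply(scheme$rules, function(r) c(r$pos, r$neg))))
  missing <- setdiff(used, map$markers)
  if (length(missing))
    stop("scheme references marker(s) absent from the map: ",
         paste(missing, collapse = ", "))
  not_hrsc <- !map$cells$CD30
  out <- vapply(scheme$rules, function(r) {
    lab <- not_hrsc
    for (m in r$pos) lab <- lab & map$cells[[m]]
    for (m in r$neg) lab <- lab & !map$cells[[m]]
    lab
  }, logical(n_cells(map)))
  if (n_cells(map) == 1L) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, names(scheme$rules)))
  out
}

#' Phenotype composition per zone
#'
#' For each zone and phenotype label, the fraction of labelled cells relative
#' to the scheme's denominator population in that zone (all non-HRSC cells,
#' or all CD8+ non-HRSC cells). Zones with an empty denominator are omitted
#' with a message.
#'
#' @param map a [cell_map()].
#' @param zones a [assign_zones()] result computed on the same map.
#' @param scheme a [phenotype_scheme()].
#' @return data.frame with columns `case_id`, `zone`, `phenotype`, `n_cells`,
#'   `denominator_n`, `fraction`.
#' @export
zone_composition <- function(map, zones, scheme) {
  stopifnot(inherits(zones, "zone_assignment"),
            length(zones$zone) == n_cells(map))
  labels <- classify_phenotypes(map, scheme)
  denom_cells <- if (scheme$denominator == "cd8_cells") {
    if (!"CD8" %in% map$markers) stop("cd8_cells denominator requires a CD8 marker")
    !map$cells$CD30 & map$cells$CD8
  } else !map$cells$CD30
  out <- list()
  for (z in c("close", "intermediate", "distant")) {
    in_zone <- zones$zone == z
    dn <- sum(denom_cells & in_zone)
    if (dn == 0L) {
      message("case ", map$case_id, ": zone '", z,
              "' has empty denominator, omitted")
      next
    }
    n <- colSums(labels[in_zone, , drop = FALSE])
    out[[z]] <- data.frame(case_id = map$case_id, zone = z,
                           phenotype = colnames(labels), n_cells = as.integer(n),
                           denominator_n = dn, fraction = n / dn,
                           row.names = NULL)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(case_id = character(), zone = character(),
               phenotype = character(), n_cells = integer(),
               denominator_n = integer(), fraction = numeric())
  rownames(res) <- NULL
  res
}

#' Paired comparison of a phenotype between two zones
#'
#' Classical paired t-test on the per-case difference of a phenotype's
#' fraction between two zones (default close minus distant). Cases missing
#' either zone are dropped.
#'
#' @param tables a [zone_composition()] table (rows from several cases).
#' @param phenotype label to compare.
#' @param zones length-2 character vector; difference is `zones[1] - zones[2]`.
#' @return list with `t`, `df`, `p_value`, `mean_difference`, `n_pairs`.
#' @export
compare_zones <- function(tables, phenotype, zones = c("close", "distant")) {
  stopifnot(length(zones) == 2L)
  sub <- tables[tables$phenotype == phenotype & tables$zone %in% zones, ]
  if (!nrow(sub)) stop("no rows for phenotype '", phenotype, "'")
  a <- sub[sub$zone == zones[1], c("case_id", "fraction")]
  b <- sub[sub$zone == zones[2], c("case_id", "fraction")]
  merged <- merge(a, b, by = "case_id", suffixes = c("_1", "_2"))
  if (nrow(merged) < 2L)
    stop("need >= 2 cases with both '", zones[1], "' and '", zones[2],
         "' fractions (got ", nrow(merged), ")")
  diffs <- merged$fraction_1 - merged$fraction_2
  if (stats::sd(diffs) == 0) {
    # degenerate paired t: all differences identical
    if (all(diffs == 0))
      return(list(t = 0, df = nrow(merged) - 1L, p_value = 1,
                  mean_difference = 0, n_pairs = nrow(merged)))
    stop("zero variance of nonzero paired differences; t undefined")
  }
  tt <- stats::t.test(merged$fraction_1, merged$fraction_2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(diffs),
       n_pairs = nrow(merged))
}

#' Score HLA status from the fraction of positive HRSCs
#'
#' A case is HLA-positive if strictly more than 50% of its HRSCs show
#' unambiguous membrane staining.
#'
#' @param fraction_positive_hrsc fraction(s) in \[0, 1\].
#' @return character vector, `"pos"` or `"neg"`.
#' @export
score_hla_status <- function(fraction_positive_hrsc) {
  if (any(fraction_positive_hrsc < 0 | fraction_positive_hrsc > 1))
    stop("fraction must be in [0, 1]")
  ifelse(fraction_positive_hrsc > 0.5, "pos", "neg")
}

#' Percent of field area covered by CD30+ HRSCs
#'
#' Whole-slide-image style tumor-content readout: 100 x (summed CD30+ cell
#' area) / field area.
#'
#' @param map a [cell_map()] with cell areas and a field extent.
#' @return percentage (0-100).
#' @export
cd30_area_fraction <- function(map) {
  if (is.null(map$cells$area)) stop("cell areas are required")
  if (is.null(map$field_extent)) stop("field extent is required")
  fe <- map$field_extent
  field_area <- (fe[2] - fe[1]) * (fe[4] - fe[3])
  hrsc <- map$cells$CD30
  if (!any(hrsc)) return(0)
  100 * sum(map$cells$area[hrsc]) / field_area
}

#' Per-case marker intensity on HRSCs
#'
#' Mean and median of a marker's per-cell intensity over CD30+ cells only
#' (e.g. TARC/CCL17 from CD30-TARC double staining); immune cells are ignored.
#'
#' @param map a [cell_map()].
#' @param marker intensity column name (default `"TARC"`).
#' @return list with `case_id`, `marker`, `mean`, `median`, `n_hrsc`.
#' @export
hrsc_marker_intensity <- function(map, marker = "TARC") {
  if (!marker %in% map$intensities)
    stop("map carries no '", marker, "' intensity")
  hrsc <- map$cells$CD30
  if (!any(hrsc)) stop("no HRSC in map")
  v <- map$cells[[marker]][hrsc]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no '", marker, "' intensity on HRSCs")
  list(case_id = map$case_id, marker = marker,
       mean = mean(v), median = stats::median(v), n_hrsc = length(v))
}
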