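# End-to-end orchestration: simulate (or load) a cohort, QC + normalize,
# differential expression with and without the EBV confounder, spatial
# zoning and composition, repertoire clonality, and Table-1-style
# association statistics, collected into one reproducible report.

#' Default pipeline configuration
#'
#' @param seed master seed (used for every source of randomness).
#' @param n_cases cohort size when simulating.
#' @param output_dir optional directory; when set, stage tables are written
#'   as TSV as they complete and a volcano plot as PNG.
#' @return nested list understood by [run_pipeline()]. Sections: `input`
#'   (paths to `cells`, `expression`, `annotation`, `repertoire_dir`; all
#'   `NULL` means simulate), `simulation` (`n_cases` plus the three
#'   simulator configs), `zoning` (`close_max`, `distant_min`), `de`
#'   (`stratifier`, `confounder`, `p_threshold`, `fc_threshold`,
#'   `pseudocount`), `report` (`output_dir`).
#' @export
default_run_config <- function(seed = 1, n_cases = 97, output_dir = NULL) {
  list(
    seed = seed,
    input = list(cells = NULL, expression = NULL, annotation = NULL,
                 repertoire_dir = NULL),
    simulation = list(n_cases = n_cases,
                      cell_cfg = cohort_sim_config(),
                      expr_cfg = expression_sim_config(),
                      rep_cfg = repertoire_sim_config()),
    zoning = list(close_max = 28.33, distant_min = 75),
    de = list(stratifier = "hla_i", confounder = "ebv",
              p_threshold = 0.05, fc_threshold = 0.6, pseudocount = 1),
    report = list(output_dir = output_dir))
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [default_run_config()]; sections are merged key-wise.
#'
#' @param path YAML file with any subset of the config sections.
#' @param ... passed to [default_run_config()] for the remaining defaults.
#' @return config list.
#' @export
read_run_config <- function(path, ...) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(...), user)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_stage <- function(df, output_dir, file) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, file.path(output_dir, file), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: acquire data (simulate from the master seed, or load
#' the paths in `config$input`); LOD sample QC and log2/centering
#' normalization; differential expression for the configured stratifier,
#' without and (if configured) with the EBV confounder; spatial zoning and
#' phenotype composition with paired close-vs-distant tests for the
#' all-cells marker scheme and the CD8 co-expression scheme; Simpson's
#' clonality with an HLA group comparison; and the association tests
#' (HLA-I x EBV Fisher, HLA-I x HLA-II Fisher, HLA-I x subtype chi-square).
#' Rerunning with the same config reproduces every table.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @return object of class `run_report`: list with `config`, `annotation`,
#'   `de`, `de_adjusted`, `composition` (both schemes), `zone_tests`,
#'   `clonality`, `clonality_test`, `associations`, `exclusions`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$report$output_dir
  exclusions <- data.frame(stage = character(), item = character(),
                           reason = character())
  note_excl <- function(stage, item, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(stage = stage, item = item, reason = reason))
  }

  # -- data ------------------------------------------------------------
  dat <- .stage("data", {
    inp <- config$input
    if (is.null(inp$cells) && is.null(inp$expression)) {
      sim <- config$simulation
      simulate_cohort(n_cases = sim$n_cases, cell_cfg = sim$cell_cfg,
                      expr_cfg = sim$expr_cfg, rep_cfg = sim$rep_cfg,
                      seed = config$seed)
    } else {
      reps <- if (!is.null(inp$repertoire_dir)) {
        files <- list.files(inp$repertoire_dir, pattern = "\\.tsv$",
                            full.names = TRUE)
        lapply(files, read_repertoire)
      }
      structure(list(annotation = read_sample_annotation(inp$annotation),
                     cell_maps = read_cell_table(inp$cells),
                     expression = read_expression_matrix(inp$expression,
                                                         lod = inp$lod),
                     repertoires = reps, seed = config$seed),
                class = "hl_cohort")
    }
  })
  ann <- dat$annotation
  .write_stage(as.data.frame(ann), out_dir, "annotation.tsv")

  # -- expression ------------------------------------------------------
  de_cfg <- config$de
  de_out <- .stage("expression_de", {
    qc <- qc_filter_samples(dat$expression)
    for (s in attr(qc, "removed"))
      note_excl("qc", s, "<=50% of genes above limit of detection")
    centered <- normalize_expression(qc, pseudocount = de_cfg$pseudocount)
    strat <- ann[[de_cfg$stratifier]][match(colnames(centered$values),
                                            ann$sample_id)]
    for (s in colnames(centered$values)[strat == "na"])
      note_excl("de", s, paste0("non-evaluable ", de_cfg$stratifier))
    de <- suppressMessages(differential_expression(
      centered, ann, stratifier = de_cfg$stratifier, confounder = NULL,
      p_threshold = de_cfg$p_threshold, fc_threshold = de_cfg$fc_threshold))
    de_adj <- if (!is.null(de_cfg$confounder) &&
                  !identical(de_cfg$confounder, "none"))
      suppressMessages(differential_expression(
        centered, ann, stratifier = de_cfg$stratifier,
        confounder = de_cfg$confounder,
        p_threshold = de_cfg$p_threshold, fc_threshold = de_cfg$fc_threshold))
    list(de = de, de_adj = de_adj)
  })
  .write_stage(de_out$de, out_dir, "de_results.tsv")
  if (!is.null(de_out$de_adj))
    .write_stage(de_out$de_adj, out_dir, "de_results_adjusted.tsv")

  # -- spatial ---------------------------------------------------------
  spatial <- .stage("spatial_zoning", {
    schemes <- list(all_cells = tme_marker_scheme(),
                    cd8 = cd8_coexpression_scheme())
    comp <- list()
    for (m in dat$cell_maps) {
      if (!any(m$cells$CD30)) {
        note_excl("spatial", m$case_id, "no HRSC in field")
        next
      }
      z <- assign_zones(m, config$zoning$close_max, config$zoning$distant_min)
      for (sn in names(schemes)) {
        tab <- suppressMessages(zone_composition(m, z, schemes[[sn]]))
        if (nrow(tab)) tab$scheme <- sn
        comp[[paste(m$case_id, sn)]] <- tab
      }
    }
    comp <- do.call(rbind, comp)
    rownames(comp) <- NULL
    tests <- list()
    for (sn in names(schemes)) {
      sub <- comp[comp$scheme == sn, ]
      for (ph in names(schemes[[sn]]$rules)) {
        res <- tryCatch(compare_zones(sub, ph), error = function(e) NULL)
        if (is.null(res)) next
        tests[[paste(sn, ph)]] <- data.frame(
          scheme = sn, phenotype = ph, t = res$t, df = res$df,
          p_value = res$p_value, mean_difference = res$mean_difference,
          n_pairs = res$n_pairs)
      }
    }
    tests <- do.call(rbind, tests)
    rownames(tests) <- NULL
    list(composition = comp, tests = tests)
  })
  .write_stage(spatial$composition, out_dir, "zone_composition.tsv")
  .write_stage(spatial$tests, out_dir, "zone_tests.tsv")

  # -- clonality -------------------------------------------------------
  clon <- .stage("repertoire_clonality", {
    if (is.null(dat$repertoires)) list(table = NULL, test = NULL) else {
      ct <- clonality_table(dat$repertoires)
      tst <- tryCatch(compare_clonality(ct, ann, de_cfg$stratifier),
                      error = function(e) NULL)
      list(table = ct, test = tst)
    }
  })
  if (!is.null(clon$table)) .write_stage(clon$table, out_dir, "clonality.tsv")

  # -- associations ----------------------------------------------------
  assoc <- .stage("association_stats", {
    res <- list()
    res$hla_i_ebv <- tryCatch(
      fisher_exact_2x2(build_contingency(ann, "hla_i", "ebv")),
      error = function(e) NULL)
    res$hla_i_hla_ii <- tryCatch(
      fisher_exact_2x2(build_contingency(ann, "hla_i", "hla_ii")),
      error = function(e) NULL)
    res$hla_i_subtype <- tryCatch(
      chi_square_rxc(build_contingency(ann, "hla_i", "subtype")),
      error = function(e) NULL)
    res[!vapply(res, is.null, logical(1))]
  })
  if (!is.null(out_dir) && length(assoc)) {
    adf <- do.call(rbind, lapply(names(assoc), function(nm) {
      a <- assoc[[nm]]
      data.frame(comparison = nm, method = a$method, p_value = a$p_value,
                 odds_ratio = if (!is.null(a$odds_ratio)) a$odds_ratio else NA,
                 statistic = if (!is.null(a$statistic)) a$statistic else NA,
                 df = if (!is.null(a$df)) a$df else NA)
    }))
    .write_stage(adf, out_dir, "associations.tsv")
  }
  if (!is.null(out_dir)) {
    .write_stage(exclusions, out_dir, "exclusions.tsv")
    ggplot2::ggsave(file.path(out_dir, "volcano.png"),
                    plot_volcano(de_out$de, de_cfg$p_threshold,
                                 de_cfg$fc_threshold),
                    width = 6, height = 5, dpi = 150)
  }

  structure(list(config = config, annotation = ann,
                 de = de_out$de, de_adjusted = de_out$de_adj,
                 composition = spatial$composition,
                 zone_tests = spatial$tests,
                 clonality = clon$table, clonality_test = clon$test,
                 associations = assoc, exclusions = exclusions),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$config$seed, "-", nrow(x$annotation), "cases\n")
  cat("  DE:", nrow(x$de), "genes;",
      sum(x$de$volcano_class != "not_significant"), "volcano-significant\n")
  if (!is.null(x$zone_tests))
    cat("  spatial:", nrow(x$zone_tests), "paired zone tests over",
        length(unique(x$composition$case_id)), "cases\n")
  if (!is.null(x$clonality_test))
    cat("  clonality: t-test p =", format(x$clonality_test$p_value, digits = 3),
        "\n")
  for (nm in names(x$associations))
    cat("  assoc ", nm, ": p = ",
        format(x$associations[[nm]]$p_value, digits = 4), "\n", sep = "")
  cat("  exclusions:", nrow(x$exclusions), "\n")
  invisible(x)
}
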