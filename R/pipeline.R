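#' Pipeline configuration
#'
#' Assembles and validates the full set of analysis parameters: input paths
#' and sample layout (or a synthetic-data block when no inputs are given),
#' classification thresholds, test levels, and imputation settings. Every
#' threshold that shapes a result is held here so each number in the output
#' tables is traceable to a config value echoed in the run manifest.
#'
#' @param tissue tissue label.
#' @param seed integer seed used for every source of randomness in a run.
#' @param inputs named list of proteinGroups TSV paths per group
#'   (`A`, `B`, `C`, `D`; any subset), or `NULL` to simulate.
#' @param samples named list: group -> character vector of sample column
#'   suffixes. Required when `inputs` is given.
#' @param annotation optional path to a matrisome annotation TSV.
#' @param thresholds list: `fast_pulse` (default 80), `fast_chase` (20),
#'   `stable_retention` (0.8), `alpha` (0.05), `fc` (1.5).
#' @param imputation list: `k` (KNN neighbours, 3), `min_missing` (censored
#'   scheme replicate threshold, 3), `min_evidence` (uniform scheme iBAQ
#'   replicate threshold, 2).
#' @param synthetic list of overrides passed to [synthetic_config()] when
#'   simulating.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue = "synthetic", seed = 1,
                            inputs = NULL, samples = NULL, annotation = NULL,
                            thresholds = list(), imputation = list(),
                            synthetic = list()) {
  thresholds <- utils::modifyList(
    list(fast_pulse = 80, fast_chase = 20, stable_retention = 0.8,
         alpha = 0.05, fc = 1.5), thresholds)
  imputation <- utils::modifyList(
    list(k = 3, min_missing = 3, min_evidence = 2), imputation)
  stopifnot(thresholds$fast_pulse > 0, thresholds$fast_pulse < 100,
            thresholds$fast_chase > 0, thresholds$fast_chase < 100,
            thresholds$stable_retention > 0,
            thresholds$alpha > 0, thresholds$alpha < 1,
            thresholds$fc >= 1,
            imputation$k >= 1, imputation$min_missing >= 1,
            imputation$min_evidence >= 1)
  if (!is.null(inputs) && is.null(samples))
    stop("config key 'samples' is required when 'inputs' is given")
  structure(list(tissue = tissue, seed = as.integer(seed), inputs = inputs,
                 samples = samples, annotation = annotation,
                 thresholds = thresholds, imputation = imputation,
                 synthetic = synthetic),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields;
#'   unspecified fields keep their defaults.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a simulated dataset as proteinGroups-dialect files
#'
#' @param sim output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (grp in names(sim$tables))
    write_table(sim$tables[[grp]],
                file.path(dir, paste0("proteinGroups_", grp, ".tsv")))
  write_table(sim$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full turnover analysis pipeline
#'
#' Executes all stages in order — load (or simulate), decoy/contaminant
#' filtering, censoring-aware pulse-chase imputation, per-group incorporation
#' summaries, turnover classification, young-vs-older differential testing,
#' matrisome reporting — writing one TSV per result plus a YAML run manifest
#' that echoes the configuration and the row counts at every step. Output is
#' deterministic given config and seed. Any stage error aborts the run naming
#' the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`tables`,
#'   `incorporation`, `turnover`, `class_summary`, `differential`,
#'   `category`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  th <- config$thresholds
  im <- config$imputation

  tables <- run_stage("load", {
    if (is.null(config$inputs)) {
      scfg <- do.call(synthetic_config,
                      utils::modifyList(list(tissue = config$tissue),
                                        config$synthetic))
      sim <- generate_dataset(scfg, seed = config$seed)
      write_table(sim$truth, file.path(out_dir, "ground_truth.tsv"))
      sim$tables
    } else {
      out <- list()
      for (grp in names(config$inputs)) {
        spec <- sample_spec(config$samples[[grp]], grp, config$tissue)
        out[[grp]] <- read_protein_groups(config$inputs[[grp]], spec)
      }
      out
    }
  })
  counts$read <- vapply(tables, function(t) nrow(t$proteins), integer(1))

  tables <- run_stage("filter", lapply(tables, filter_quantifiable))
  counts$filtered <- vapply(tables, function(t) nrow(t$proteins), integer(1))

  audits <- empty_audit()
  if (all(c("A", "B") %in% names(tables))) {
    cen <- run_stage("censored_imputation",
                     impute_censored_pulse(tables$A, tables$B,
                                           min_missing = im$min_missing))
    tables$A <- cen$table_a
    tables$B <- cen$table_b
    audits <- rbind(audits, cen$audit)
    counts$censored_imputed <- nrow(cen$audit)
  }

  incorporation <- run_stage("incorporation", {
    do.call(rbind, lapply(names(tables), function(grp)
      summarize_group(tables[[grp]], grp)))
  })
  write_table(incorporation, file.path(out_dir, "incorporation.tsv"))
  counts$summarized <- nrow(incorporation)

  turnover <- cls_sum <- NULL
  if (all(c("A", "B") %in% names(tables))) {
    turnover <- run_stage("turnover", {
      prof <- retention_profile(incorporation[incorporation$group == "A", ],
                                incorporation[incorporation$group == "B", ])
      call <- classify_turnover(prof$percent_A, prof$percent_B,
                                fast_pulse = th$fast_pulse,
                                fast_chase = th$fast_chase,
                                stable_retention = th$stable_retention)
      cbind(protein_id = prof$protein_id, call, stringsAsFactors = FALSE)
    })
    cls_sum <- class_summary(turnover)
    write_table(turnover, file.path(out_dir, "turnover.tsv"))
    write_table(cls_sum, file.path(out_dir, "class_summary.tsv"))
    counts$classified <- nrow(turnover)
  }

  differential <- NULL
  if (all(c("C", "D") %in% names(tables))) {
    differential <- run_stage("differential",
      differential_table(tables$C, tables$D, seed = config$seed,
                         k = im$k, alpha = th$alpha, fc_threshold = th$fc,
                         min_valid = 2))
    write_table(differential, file.path(out_dir, "differential.tsv"))
    audits <- rbind(audits, attr(differential, "audit"))
    counts$differential_tested <- nrow(differential)
    counts$differential_significant <-
      as.list(attr(differential, "counts")[c("increased", "decreased")])
  }

  category <- NULL
  if (!is.null(config$annotation)) {
    if (!file.exists(config$annotation))
      stop("stage 'report' failed: annotation file not found at config key ",
           "'annotation': ", config$annotation, call. = FALSE)
    category <- run_stage("report", {
      ann_tab <- read_matrisome_annotation(config$annotation)
      base <- if (!is.null(turnover)) turnover else
        stop("matrisome report needs groups A and B")
      gene <- tables$A$proteins$gene_name[
        match(base$protein_id, tables$A$proteins$protein_id)]
      ann <- annotate_matrisome(gene, ann_tab, fallback_keys = base$protein_id)
      cs <- category_summary(base, ann, summaries = incorporation)
      write_table(cs$class_by_category,
                  file.path(out_dir, "category_class_counts.tsv"))
      write_table(cs$top_retained, file.path(out_dir, "category_top_retained.tsv"))
      cs
    })
  }

  write_table(audits, file.path(out_dir, "imputation_audit.tsv"))
  manifest <- list(package_version = as.character(utils::packageVersion("silacTurnover")),
                   tissue = config$tissue, seed = config$seed,
                   thresholds = th, imputation = im, counts = counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(tables = tables, incorporation = incorporation,
                 turnover = turnover, class_summary = cls_sum,
                 differential = differential, category = category,
                 manifest = manifest))
}
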