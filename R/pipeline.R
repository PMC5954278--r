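#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_all()]. The
#' defaults are the study parameters used throughout the package: Spearman
#' cutoff 0.5 with per-gene Bonferroni-adjusted p <= 0.01 for edges,
#' raw enrichment p < 0.05 for annotation transfer, E-value <= 1e-5 for
#' reciprocal best hits, and retention of the 75% most variable genes.
#'
#' @param expression,biotype Paths to the expression matrix TSV and the
#'   two-column biotype TSV (required).
#' @param tissues,grouping,terms,hits_forward,hits_reverse,tf_a,tf_b,gene_models,chrom_sizes
#'   Optional input paths; stages without their inputs are skipped.
#' @param rho_cutoff,alpha,p_threshold,e_max,keep_fraction Analysis
#'   parameters (defaults above).
#' @param seed Integer seed used by the stochastic evaluation steps.
#' @param out_dir Output directory.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, biotype, out_dir,
                            tissues = NULL, grouping = NULL, terms = NULL,
                            hits_forward = NULL, hits_reverse = NULL,
                            tf_a = NULL, tf_b = NULL,
                            gene_models = NULL, chrom_sizes = NULL,
                            rho_cutoff = 0.5, alpha = 0.01,
                            p_threshold = 0.05, e_max = 1e-5,
                            keep_fraction = 0.75, seed = 1) {
  cfg <- list(
    inputs = list(expression = expression, biotype = biotype,
                  tissues = tissues, grouping = grouping, terms = terms,
                  hits_forward = hits_forward, hits_reverse = hits_reverse,
                  tf_a = tf_a, tf_b = tf_b, gene_models = gene_models,
                  chrom_sizes = chrom_sizes),
    params = list(rho_cutoff = rho_cutoff, alpha = alpha,
                  p_threshold = p_threshold, e_max = e_max,
                  keep_fraction = keep_fraction, seed = as.integer(seed)),
    out_dir = out_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may have top-level keys `inputs`, `params` and `out_dir`
#' mirroring the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(y$inputs, y$params, list(out_dir = y$out_dir))
  do.call(pipeline_config, args)
}

stage_log <- function(stage, ...) {
  inform(paste0("[", stage, "] ", paste0(..., collapse = "")))
}

#' Run the full analysis pipeline
#'
#' Stages: read + normalize + variance-filter expression; build the
#' co-expression network and its statistics; annotate lncRNAs by neighbor
#' enrichment (when a term table is given); reciprocal-best-hit orthology,
#' TSI and TF-family IoU (when hit/TF tables are given); subtype
#' classification and structure summaries (when gene models are given).
#' Every output is a TSV/JSON file under `config$out_dir`, listed in
#' `manifest.json` together with the parameters and input checksums; a
#' rerun with the same config and inputs is byte-identical.
#'
#' @param config A `"pipeline_config"`.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$inputs
  par <- config$params
  for (nm in names(inp)) {
    if (!is.null(inp[[nm]]) && !file.exists(inp[[nm]])) {
      stop_lncnet(paste0("input validation failed at stage '", nm,
                         "': file not found: ", inp[[nm]]),
                  class = "lncnet_validation_error")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  emit <- function(name, obj) {
    path <- file.path(config$out_dir, name)
    if (is.data.frame(obj)) {
      readr::write_tsv(obj, path, progress = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    outputs[[name]] <<- path
    path
  }

  stage_log("expression", "reading ", inp$expression)
  expr <- read_expression(inp$expression, inp$biotype, inp$tissues)
  if (!is.null(inp$grouping)) {
    grouping <- readr::read_tsv(inp$grouping,
                                col_names = c("sample_id", "group_id"),
                                show_col_types = FALSE, progress = FALSE)
    expr <- merge_replicates(expr, grouping)
  }
  norm <- upper_quartile_normalize(expr)
  emit("scaling_factors.tsv", scaling_factors(norm))
  filtered <- variance_filter(norm, keep_fraction = par$keep_fraction)
  emit("normalized_expression.tsv", select(filtered, -"biotype"))
  stage_log("expression", nrow(filtered), " genes x ",
            length(sample_columns(filtered)), " samples after filtering")

  stage_log("network", "building network (rho >= ", par$rho_cutoff,
            ", alpha = ", par$alpha, ")")
  net <- build_network(filtered, rho_cutoff = par$rho_cutoff,
                       alpha = par$alpha)
  emit("edges.tsv", net$edges)
  stats_row <- network_stats(net)
  emit("network_stats.json", as.list(stats_row))
  emit("edge_categories.tsv", classify_edges(net))
  emit("degree_histogram.tsv", degree_histogram(net))

  if (!is.null(inp$terms)) {
    stage_log("annotate", "neighbor enrichment, p < ", par$p_threshold)
    ann <- read_annotations(inp$terms)
    lnc_ann <- annotate_all_lncrnas(net, ann, p_threshold = par$p_threshold)
    emit("lncrna_annotations.tsv", lnc_ann)
    emit("annotation_summary.tsv", attr(lnc_ann, "summary"))
  }

  if (!is.null(inp$hits_forward) && !is.null(inp$hits_reverse)) {
    stage_log("conserve", "reciprocal best hits, E <= ", par$e_max)
    fwd <- read_blast_hits(inp$hits_forward)
    rev <- read_blast_hits(inp$hits_reverse)
    pairs <- reciprocal_best_hits(fwd, rev, e_max = par$e_max)
    emit("ortholog_pairs.tsv", pairs)
    if (!is.null(attr(expr, "tissues"))) {
      prof <- tissue_profiles(norm)
      emit("tsi.tsv", tsi_table(prof))
    }
    if (!is.null(inp$tf_a) && !is.null(inp$tf_b)) {
      tf_a <- readr::read_tsv(inp$tf_a, col_names = c("gene_id", "tf_family"),
                              show_col_types = FALSE, progress = FALSE)
      tf_b <- readr::read_tsv(inp$tf_b, col_names = c("gene_id", "tf_family"),
                              show_col_types = FALSE, progress = FALSE)
      emit("tf_iou.tsv", tf_iou_table(pairs, tf_a, tf_b))
    }
  }

  if (!is.null(inp$gene_models)) {
    stage_log("features", "subtype classification and summaries")
    models <- read_gene_models_gff3(inp$gene_models)
    chrom_sizes <- if (!is.null(inp$chrom_sizes)) {
      readr::read_tsv(inp$chrom_sizes, show_col_types = FALSE, progress = FALSE)
    } else NULL
    lnc_models <- filter(models, .data$biotype == "lncRNA")
    cod_models <- filter(models, .data$biotype == "coding")
    if (nrow(lnc_models) > 0 && nrow(cod_models) > 0) {
      emit("subtypes.tsv", classify_subtype(lnc_models, cod_models, chrom_sizes))
    }
    emit("structure_summaries.tsv", structure_summaries(models))
    if (!is.null(chrom_sizes)) {
      emit("chromosome_density.tsv",
           chromosome_density(models, chrom_sizes))
    }
  }

  manifest <- list(
    params = par,
    inputs = purrr::map(purrr::compact(inp),
                        function(p) unname(tools::md5sum(p))),
    outputs = purrr::map(outputs, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("done", length(outputs), " outputs under ", config$out_dir)
  invisible(manifest)
}

#' End-to-end demonstration on a synthetic bundle
#'
#' Generates a small synthetic dataset with known ground truth, writes it
#' to disk, runs [run_all()] on the files, and prints a recovery summary:
#' within-module edge recall, coding-gene annotation sensitivity versus the
#' random-neighbor baseline, lncRNA term recovery, reciprocal-best-hit
#' recovery and subtype accuracy.
#'
#' @param seed Integer seed.
#' @param dir Working directory (default a fresh temporary directory).
#' @param config Optional [synthetic_config()]; defaults to
#'   `synthetic_config(seed = seed)`.
#' @param quiet Suppress stage logs.
#' @return Invisibly, a list with `dir`, the recovery `summary` tibble and
#'   the pipeline manifest.
#' @export
run_demo <- function(seed = 1, dir = tempfile("lncnet_demo_"),
                     config = NULL, quiet = FALSE) {
  config <- config %||% synthetic_config(seed = seed)
  paths <- write_synthetic_bundle(config, dir)
  pcfg <- pipeline_config(
    expression = paths$expression, biotype = paths$biotype,
    tissues = paths$tissues, terms = paths$terms,
    hits_forward = paths$hits_forward, hits_reverse = paths$hits_reverse,
    tf_a = paths$tf_a, tf_b = paths$tf_b,
    gene_models = paths$gene_models, chrom_sizes = paths$chrom_sizes,
    seed = seed, out_dir = file.path(dir, "out")
  )
  manifest <- if (quiet) {
    suppressMessages(run_all(pcfg))
  } else {
    run_all(pcfg)
  }

  expr <- generate_expression(config)
  truth <- ground_truth(expr)
  norm <- upper_quartile_normalize(expr)
  net <- build_network(norm)
  ann <- generate_annotations(truth, config)
  lnc_ann <- annotate_all_lncrnas(net, ann)
  perf <- evaluate_prediction(net, ann, min_neighbors = 5, n_random = 25,
                              seed = seed)
  pairs <- reciprocal_best_hits(
    read_blast_hits(paths$hits_forward),
    read_blast_hits(paths$hits_reverse)
  )
  layout <- generate_genome_layout(config)
  sub <- classify_subtype(filter(layout, .data$biotype == "lncRNA"),
                          filter(layout, .data$biotype == "coding"))
  summary <- tibble(
    metric = c("edge_recall", "prediction_sensitivity",
               "random_baseline_sensitivity", "lncRNA_term_recovery",
               "rbh_recovery", "subtype_accuracy"),
    value = c(
      edge_recall(net, truth),
      perf$sensitivity, perf$random_sensitivity,
      annotation_recovery(lnc_ann, truth),
      rbh_recovery(pairs, attr(generate_hit_tables(truth, config), "truth")),
      subtype_accuracy(sub, ground_truth(layout)$subtypes)
    )
  )
  if (!quiet) print(summary)
  invisible(list(dir = dir, summary = summary, manifest = manifest))
}
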