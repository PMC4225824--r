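#' Pipeline configuration
#'
#' Bundles the inputs and every stage parameter of the end-to-end workflow
#' with defaults matching the emulated chondrogenesis study: 2-fold
#' differential-expression change (with BH-adjusted p <= 1e-10 for mRNAs,
#' fold change only for the weakly replicated miRNAs), at least 2
#' supporting target-prediction databases, Pearson correlation < -0.8,
#' allowedError sweep over 0.001 and 0.01..0.05 (step 0.005), 100
#' resampling runs at noise sd 0.05, and a 0.5 edge-stability threshold.
#'
#' @param mirna_raw,mrna_raw [grn_raw()] replicate tables (or file paths to
#'   long TSVs).
#' @param prediction target-prediction table (data frame or path).
#' @param tf_list character vector of TF-annotated gene ids (or path).
#' @param literature_edges literature edge table (data frame or path, may
#'   be `NULL`).
#' @param markers character vector of marker-gene ids.
#' @param input_targets optional stimulus prior (see
#'   [build_prior_matrix()]).
#' @param fc_threshold fold-change criterion applied to both datasets.
#' @param p_threshold adjusted p-value threshold for the mRNA dataset.
#' @param min_db minimum supporting databases per predicted pair.
#' @param r_threshold Pearson-correlation threshold (strict `<`).
#' @param correlate_standardized correlate standardized series instead of
#'   the replicate-averaged differences (default `FALSE`).
#' @param grid allowedError sweep grid.
#' @param j_cap optional model-error ceiling for [select_model()].
#' @param n_runs,sd,stability_threshold robustness-stage parameters.
#' @param config an [inference_config()] for the structure search.
#' @param seed global integer seed.
#' @param out_dir optional directory; when set, every intermediate artifact
#'   is written there.
#' @param verbose print stage progress.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_raw, mrna_raw, prediction, tf_list,
                            literature_edges = NULL, markers = character(),
                            input_targets = NULL, fc_threshold = 2,
                            p_threshold = 1e-10, min_db = 2L,
                            r_threshold = -0.8,
                            correlate_standardized = FALSE,
                            grid = default_grid(), j_cap = NULL,
                            n_runs = 100L, sd = 0.05,
                            stability_threshold = 0.5,
                            config = inference_config(), seed = 1L,
                            out_dir = NULL, verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) reader(x) else x
}

#' Run the full inference pipeline
#'
#' Executes the complete workflow: differential-expression filtering of
#' both datasets, replicate averaging, TF-annotation and multi-database
#' target-prediction filtering, correlation-based pair selection, node
#' assembly with marker genes, prior-knowledge construction,
#' standardisation, the allowedError sweep with trade-off model selection,
#' noise-resampling validation, and pruning of unstable connections. Any
#' stage failure aborts with a stage-tagged message; artifacts computed
#' before the failure are still written when `out_dir` is set.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `grn_pipeline` with the selected nodes, candidate
#'   pair report (Table-1 format), prior matrix, standardized data, sweep,
#'   selected model, edge-frequency table and final pruned model.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (isTRUE(cfg$verbose)) message("[mirdynet] ", ...)
  out <- list()
  emit <- function(name, writer, x) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      writer(x, file.path(cfg$out_dir, name))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("stage '", name, "': ", conditionMessage(e))
    })
  }

  mirna_raw <- stage("read", resolve_input(cfg$mirna_raw, read_expression_long))
  mrna_raw <- stage("read", resolve_input(cfg$mrna_raw, read_expression_long))
  prediction <- stage("read", resolve_input(cfg$prediction, read_prediction_table))
  tf_list <- stage("read", resolve_input(cfg$tf_list, read_tf_list))
  literature <- stage("read", resolve_input(cfg$literature_edges,
                                            read_literature_edges))

  say("differential-expression filtering")
  demirs <- stage("de_filter", de_filter(mirna_raw, cfg$fc_threshold,
                                         p_threshold = NULL))
  degs <- stage("de_filter", de_filter(mrna_raw, cfg$fc_threshold,
                                       p_threshold = cfg$p_threshold))
  out$demirs <- demirs
  out$degs <- degs

  say("averaging replicates")
  mirna_avg <- stage("average", average_replicates(mirna_raw))
  mrna_avg <- stage("average", average_replicates(mrna_raw))

  say("node selection")
  detfs <- stage("tf_filter", select_tf_genes(degs$component, tf_list))
  cand <- stage("candidate_targets", candidate_targets(prediction, cfg$min_db))
  cand <- cand[cand$miRNA %in% demirs$component & cand$gene %in% detfs, ,
               drop = FALSE]
  corr_mirna <- if (cfg$correlate_standardized) standardize_ts(mirna_avg) else mirna_avg
  corr_mrna <- if (cfg$correlate_standardized) standardize_ts(mrna_avg) else mrna_avg
  cand <- stage("correlate", correlate_pairs(cand, corr_mirna, corr_mrna))
  pairs <- stage("correlation_filter",
                 filter_negative_pairs(cand, cfg$r_threshold))
  out$pair_report <- pairs
  markers <- intersect(cfg$markers, rownames(mrna_avg))
  if (length(markers) < length(cfg$markers)) {
    warn_("marker gene(s) absent from the mRNA data: ",
          paste(setdiff(cfg$markers, markers), collapse = ", "))
  }
  if (nrow(pairs) == 0L && length(markers) == 0L) {
    stop_("stage 'assemble_nodes': no nodes selected")
  }
  nodes <- stage("assemble_nodes", assemble_nodes(pairs, markers))
  out$nodes <- nodes

  say("prior knowledge: ", length(nodes), " nodes")
  lit_nodes <- if (!is.null(literature)) {
    literature[literature$source %in% names(nodes) &
                 literature$target %in% names(nodes), , drop = FALSE]
  }
  prior <- stage("prior", build_prior_matrix(nodes, predicted_pairs = pairs,
                                             literature_edges = lit_nodes,
                                             input_targets = cfg$input_targets))
  out$prior <- prior
  emit("prior_matrix.tsv", write_prior_matrix, prior)
  emit("pair_report.tsv", function(x, p)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE),
    pairs)

  say("standardising time series")
  ts_all <- stage("standardize", {
    parts <- list()
    m_ids <- intersect(rownames(mirna_avg), names(nodes))
    g_ids <- intersect(rownames(mrna_avg), names(nodes))
    if (length(m_ids)) parts <- c(parts, list(ts_subset(mirna_avg, m_ids)))
    if (length(g_ids)) parts <- c(parts, list(ts_subset(mrna_avg, g_ids)))
    avg <- do.call(ts_bind, parts)
    missing_nodes <- setdiff(names(nodes), rownames(avg))
    if (length(missing_nodes)) {
      stop_("no expression series for node(s): ",
            paste(missing_nodes, collapse = ", "))
    }
    avg <- ts_subset(avg, names(nodes))
    attr(avg, "classes") <- nodes
    standardize_ts(avg)
  })
  out$data <- ts_all
  emit("standardized_timeseries.tsv", write_ts_matrix, ts_all)

  say("allowedError sweep (", length(cfg$grid), " models)")
  sweep <- stage("sweep", sweep_allowed_error(ts_all, prior = prior,
                                              grid = cfg$grid,
                                              config = cfg$config))
  out$sweep <- sweep
  emit("sweep_report.tsv", function(x, p)
    utils::write.table(x$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE), sweep)
  selected <- stage("select", select_model(sweep, j_cap = cfg$j_cap))
  selected <- stage("refine", refine_model_fit(selected, ts_all))
  out$selected <- selected
  emit("selected_model.json", write_model_json, selected)

  say("robustness: ", cfg$n_runs, " resampling runs")
  cfg_sel <- cfg$config
  cfg_sel$allowed_error <- selected$metadata$selected_allowed_error %||%
    cfg_sel$allowed_error
  freqs <- stage("robustness",
                 edge_frequencies(ts_all, prior = prior, config = cfg_sel,
                                  reference = selected, n_runs = cfg$n_runs,
                                  sd = cfg$sd, seed = cfg$seed))
  out$edge_frequencies <- freqs
  emit("edge_frequencies.tsv", write_edge_frequencies, freqs)

  say("pruning unstable connections")
  final <- stage("prune", prune_unstable(selected, freqs, ts_all,
                                         threshold = cfg$stability_threshold,
                                         config = cfg_sel))
  final <- stage("refine", refine_model_fit(final, ts_all))
  out$final <- final
  emit("final_model.json", write_model_json, final)
  emit("final_model.sif", write_sif, final)
  say("done: ", n_edges(final), " stable connections")
  structure(out, class = "grn_pipeline")
}

#' @export
print.grn_pipeline <- function(x, ...) {
  cat("grn_pipeline result\n")
  cat(sprintf("  nodes: %d (%s)\n", length(x$nodes),
              paste(sprintf("%d %s", table(x$nodes), names(table(x$nodes))),
                    collapse = ", ")))
  cat(sprintf("  selected model: allowedError = %g, J = %.4g, %d connections\n",
              x$selected$metadata$selected_allowed_error,
              x$selected$metadata$J, x$selected$metadata$n_edges))
  cat(sprintf("  final model after pruning: %d connections\n",
              n_edges(x$final)))
  invisible(x)
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper around the synthetic-data module: samples a ground
#' truth, simulates the replicate dataset and emits the prediction table,
#' TF list, literature edges (the signed true TF interactions, emulating
#' text-mined knowledge) and marker list, i.e. every artifact
#' [run_pipeline()] consumes, with known answers attached.
#'
#' @param n_mirna,n_tf,n_marker node counts.
#' @param seed integer seed.
#' @param noise_sd replicate noise (standardized scale).
#' @param n_decoys decoy prediction pairs.
#' @param prior_coverage,prior_error passed to [emit_prior()].
#' @param ... further arguments to [sample_network()].
#' @return list with `truth`, `dataset`, `prediction`, `tf_list`,
#'   `literature`, `markers`, `prior`.
#' @export
synthetic_bundle <- function(n_mirna = 4L, n_tf = 4L, n_marker = 3L,
                             seed = 1L, noise_sd = 0.05, n_decoys = 50L,
                             prior_coverage = 1, prior_error = 0, ...) {
  net <- sample_network(n_mirna, n_tf, n_marker, seed = seed, ...)
  truth <- ground_truth(net, noise_sd = noise_sd, seed = seed + 1L)
  dataset <- simulate_dataset(truth)
  classes <- net$classes
  ed <- model_edges(net)
  tf_ed <- ed[ed$type == "node" & classes[ed$source] == "TF", , drop = FALSE]
  literature <- data.frame(source = tf_ed$source, target = tf_ed$target,
                           sign = ifelse(tf_ed$weight > 0, "activation",
                                         "inhibition"),
                           stringsAsFactors = FALSE)
  list(truth = truth,
       dataset = dataset,
       prediction = emit_prediction_table(net, n_decoys = n_decoys,
                                          seed = seed + 2L),
       tf_list = names(classes)[classes == "TF"],
       literature = literature,
       markers = names(classes)[classes == "marker"],
       prior = emit_prior(net, coverage = prior_coverage,
                          error_rate = prior_error, seed = seed + 3L))
}
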