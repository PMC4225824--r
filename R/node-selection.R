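#' Select transcription-factor genes among differentially expressed genes
#'
#' Intersects a list of differentially expressed gene ids with a
#' transcription-factor annotation list (e.g. genes annotated with
#' sequence-specific DNA-binding transcription-factor activity),
#' preserving the input order.
#'
#' @param degs character vector of differentially expressed gene ids.
#' @param tf_annotation character vector of annotated TF gene ids.
#' @return the ids of `degs` that are annotated TFs, in input order.
#' @export
select_tf_genes <- function(degs, tf_annotation) {
  degs[degs %in% tf_annotation]
}

#' Candidate miRNA-target pairs supported by multiple databases
#'
#' Collapses a (miRNA, gene, database) prediction table to one candidate
#' pair per (miRNA, gene) and keeps pairs recorded in at least `min_db`
#' distinct databases -- interactions found by several independent
#' prediction approaches are more trustworthy than single-database hits.
#'
#' @param table data frame with columns `miRNA`, `gene`, `database`.
#' @param min_db minimum number of supporting databases (>= 1).
#' @return data frame with columns `miRNA`, `gene`, `databases`
#'   (comma-separated, sorted), `n_db`.
#' @export
candidate_targets <- function(table, min_db = 2L) {
  stopifnot(all(c("miRNA", "gene", "database") %in% names(table)),
            is_count(min_db), min_db >= 1L)
  table <- unique(as.data.frame(table)[c("miRNA", "gene", "database")])
  if (!nrow(table)) {
    return(data.frame(miRNA = character(), gene = character(),
                      databases = character(), n_db = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(table$miRNA, table$gene, sep = "\r")
  grp <- split(table$database, key)
  first <- table[!duplicated(key), c("miRNA", "gene")]
  first <- first[order(first$miRNA, first$gene, method = "radix"), ,
                 drop = FALSE]
  k <- paste(first$miRNA, first$gene, sep = "\r")
  out <- data.frame(miRNA = first$miRNA, gene = first$gene,
                    databases = vapply(grp[k], function(d)
                      paste(sort(unique(d), method = "radix"),
                            collapse = ","), ""),
                    n_db = vapply(grp[k], function(d)
                      length(unique(d)), 0L),
                    stringsAsFactors = FALSE)
  out <- out[out$n_db >= min_db, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between miRNA and target time series
#'
#' Computes the Pearson product-moment correlation between the
#' replicate-averaged expression series of each candidate (miRNA, gene)
#' pair. A functional repressive interaction is expected to show strong
#' negative correlation. Pairs involving a zero-variance series have no
#' defined correlation and are dropped with a warning.
#'
#' @param pairs candidate pairs ([candidate_targets()] output).
#' @param mirna_ts,mrna_ts [grn_ts()] matrices containing the miRNA and
#'   gene series on a common time grid.
#' @return `pairs` with a `pearson_r` column appended.
#' @export
correlate_pairs <- function(pairs, mirna_ts, mrna_ts) {
  stopifnot(inherits(mirna_ts, "grn_ts"), inherits(mrna_ts, "grn_ts"))
  if (!isTRUE(all.equal(ts_times(mirna_ts), ts_times(mrna_ts)))) {
    stop_("miRNA and mRNA series are on different time grids")
  }
  missing_m <- setdiff(pairs$miRNA, rownames(mirna_ts))
  missing_g <- setdiff(pairs$gene, rownames(mrna_ts))
  if (length(missing_m) || length(missing_g)) {
    stop_("series missing for: ",
          paste(c(missing_m, missing_g), collapse = ", "))
  }
  r <- numeric(nrow(pairs))
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- unclass_ts(mirna_ts)[pairs$miRNA[i], ]
    y <- unclass_ts(mrna_ts)[pairs$gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn_("zero-variance series for pair ", pairs$miRNA[i], " / ",
            pairs$gene[i], "; pair dropped")
      keep[i] <- FALSE
    } else {
      r[i] <- stats::cor(x, y)
    }
  }
  out <- pairs[keep, , drop = FALSE]
  out$pearson_r <- r[keep]
  rownames(out) <- NULL
  out
}

#' Keep strongly negatively correlated pairs
#'
#' Retains candidate pairs with Pearson correlation strictly smaller than
#' the threshold (default -0.8): only pairs whose anticorrelated dynamics
#' are compatible with repression by the miRNA enter the network.
#'
#' @param pairs data frame with a `pearson_r` column.
#' @param r_threshold correlation threshold; strict `<` comparison.
#' @return the filtered pairs.
#' @export
filter_negative_pairs <- function(pairs, r_threshold = -0.8) {
  stopifnot("pearson_r" %in% names(pairs))
  out <- pairs[pairs$pearson_r < r_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the network node set
#'
#' Collects the endpoints of the selected miRNA-target pairs (miRNAs and
#' TF genes) and the curated marker genes into a deduplicated, classed
#' node list. A node claimed by two classes is an error.
#'
#' @param selected_pairs data frame with columns `miRNA`, `gene`.
#' @param markers character vector of marker-gene ids.
#' @return named character vector of classes (`"miRNA"`, `"TF"`,
#'   `"marker"`), names = node ids.
#' @export
assemble_nodes <- function(selected_pairs, markers = character()) {
  mirnas <- unique(as.character(selected_pairs$miRNA))
  tfs <- unique(as.character(selected_pairs$gene))
  markers <- unique(as.character(markers))
  ids <- c(mirnas, tfs, markers)
  cls <- rep(c("miRNA", "TF", "marker"),
             c(length(mirnas), length(tfs), length(markers)))
  dup <- duplicated(ids)
  if (any(dup)) {
    clash <- unique(ids[dup])
    stop_("node claimed in two classes: ", paste(clash, collapse = ", "))
  }
  stats::setNames(cls, ids)
}

PRIOR_CODES <- c(0, 10, -10, 1)

#' Build the prior-knowledge interaction matrix
#'
#' Codes regulatory hypotheses over the selected nodes for the structure
#' search: no connection 0, activation 10, inhibition -10, activation or
#' inhibition of unknown sign 1, not available NA. Rows are targets,
#' columns are regulators plus the stimulus. Rules applied, in order:
#' marker genes are pure targets, so their regulator columns are 0;
#' predicted miRNA-target interactions are coded -10 (miRNAs degrade their
#' targets); literature interactions are coded by their sign (`activation`
#' 10, `inhibition` -10, `unknown` 1); stimulus-column entries are set for
#' the listed input targets. Everything else stays NA.
#'
#' @param nodes named class vector from [assemble_nodes()].
#' @param predicted_pairs data frame with columns `miRNA`, `gene` (may be
#'   `NULL`).
#' @param literature_edges data frame with columns `source`, `target`,
#'   `sign` (`"activation"`, `"inhibition"` or `"unknown"`); may be `NULL`.
#' @param input_targets character vector of nodes known to respond to the
#'   stimulus (coded 1, sign unknown), or a data frame with columns
#'   `target`, `sign`; may be `NULL`.
#' @param input_name stimulus column name.
#' @return coded prior matrix.
#' @export
build_prior_matrix <- function(nodes, predicted_pairs = NULL,
                               literature_edges = NULL, input_targets = NULL,
                               input_name = "stimulus") {
  ids <- names(nodes)
  prior <- matrix(NA_real_, length(ids), length(ids) + 1L,
                  dimnames = list(ids, c(ids, input_name)))
  prior[, ids[nodes == "marker"]] <- 0
  set_entry <- function(target, source, code) {
    if (!target %in% ids || !(source %in% ids || source == input_name)) {
      stop_("edge endpoint missing from node set: ", source, " -> ", target)
    }
    prior[target, source] <<- code
  }
  if (!is.null(predicted_pairs) && nrow(predicted_pairs)) {
    for (i in seq_len(nrow(predicted_pairs))) {
      set_entry(predicted_pairs$gene[i], predicted_pairs$miRNA[i], -10)
    }
  }
  if (!is.null(literature_edges) && nrow(literature_edges)) {
    code <- c(activation = 10, inhibition = -10, unknown = 1)
    for (i in seq_len(nrow(literature_edges))) {
      s <- as.character(literature_edges$sign[i])
      if (!s %in% names(code)) stop_("unknown literature edge sign: ", s)
      set_entry(literature_edges$target[i], literature_edges$source[i],
                code[[s]])
    }
  }
  if (!is.null(input_targets)) {
    if (is.data.frame(input_targets)) {
      code <- c(activation = 10, inhibition = -10, unknown = 1)
      for (i in seq_len(nrow(input_targets))) {
        set_entry(input_targets$target[i], input_name,
                  code[[as.character(input_targets$sign[i])]])
      }
    } else {
      for (t in input_targets) set_entry(t, input_name, 1)
    }
  }
  prior
}

#' Validate a prior-knowledge matrix against a node set
#' @param prior coded matrix.
#' @param nodes node ids (rows must match; columns = nodes plus one input).
#' @param input_name stimulus column name.
#' @return the validated matrix, invisibly.
#' @export
validate_prior <- function(prior, nodes, input_name = "stimulus") {
  if (!is.matrix(prior)) stop_("prior must be a matrix")
  if (!setequal(rownames(prior), nodes)) stop_("prior rows must match the node set")
  if (!setequal(colnames(prior), c(nodes, input_name))) {
    stop_("prior columns must be the node set plus '", input_name, "'")
  }
  bad <- which(!is.na(prior) & !prior %in% PRIOR_CODES, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("illegal prior code ", prior[bad[1L, , drop = FALSE]],
          " at row '", rownames(prior)[bad[1L, 1L]],
          "', column '", colnames(prior)[bad[1L, 2L]], "'")
  }
  invisible(prior[nodes, c(nodes, input_name), drop = FALSE])
}
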