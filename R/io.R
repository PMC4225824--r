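#' Read and write the package's tabular formats
#'
#' All tables are plain TSV with a header row. Long expression tables have
#' columns `component`, `class`, `time`, `replicate`, `value`; wide
#' time-series matrices have a `component` column, an optional `class`
#' column and one column per time point (times as header); prediction
#' tables have `miRNA`, `gene`, `database`; literature-edge tables have
#' `source`, `target`, `sign`; prior matrices are coded 0/10/-10/1/NA with
#' rows as targets and columns as regulators plus the stimulus (stated in
#' a comment header); edge-frequency tables have `source`, `target`,
#' `type`, `count`, `frequency`. Writers and readers round-trip exactly.
#'
#' @param path file path.
#' @param x object to write.
#' @name grn_io
NULL

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_(what, " '", path, "': missing column(s) ",
          paste(miss, collapse = ", "))
  }
  df
}

#' @rdname grn_io
#' @export
read_expression_long <- function(path) {
  grn_raw(read_tsv_checked(path, c("component", "class", "time",
                                   "replicate", "value"),
                           "expression table"))
}

#' @rdname grn_io
#' @export
write_expression_long <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_ts_matrix <- function(path) {
  df <- read_tsv_checked(path, "component", "time-series matrix")
  has_class <- "class" %in% names(df)
  tcols <- setdiff(names(df), c("component", "class"))
  times <- suppressWarnings(as.numeric(tcols))
  if (anyNA(times)) stop_("time-series matrix '", path,
                          "': non-numeric time columns")
  first <- readLines(path, n = 1L)
  standardized <- grepl("standardized: TRUE", first, fixed = TRUE)
  m <- as.matrix(df[tcols])
  rownames(m) <- df$component
  grn_ts(m, times,
         classes = if (has_class) stats::setNames(df$class, df$component),
         standardized = standardized)
}

#' @rdname grn_io
#' @export
write_ts_matrix <- function(x, path) {
  stopifnot(inherits(x, "grn_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# grn_ts; standardized: ", is_standardized(x),
                    "; rows: components; columns: times (h)"), con)
  df <- data.frame(component = rownames(x), stringsAsFactors = FALSE)
  cls <- ts_classes(x)
  if (!is.null(cls)) df$class <- unname(cls[rownames(x)])
  df <- cbind(df, as.data.frame(unclass_ts(x), check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_prediction_table <- function(path) {
  df <- read_tsv_checked(path, c("miRNA", "gene", "database"),
                         "prediction table")
  dup <- duplicated(df[c("miRNA", "gene", "database")])
  if (any(dup)) {
    stop_("prediction table '", path, "': duplicate (miRNA, gene, database) ",
          "triple at line ", which(dup)[1L] + 1L)
  }
  df
}

#' @rdname grn_io
#' @export
write_prediction_table <- function(x, path) {
  utils::write.table(x[c("miRNA", "gene", "database")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_tf_list <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' @rdname grn_io
#' @export
write_tf_list <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_literature_edges <- function(path) {
  df <- read_tsv_checked(path, c("source", "target", "sign"),
                         "literature edge table")
  bad <- !df$sign %in% c("activation", "inhibition", "unknown")
  if (any(bad)) {
    stop_("literature edge table '", path, "': illegal sign '",
          df$sign[which(bad)[1L]], "' at line ", which(bad)[1L] + 1L)
  }
  df
}

#' @rdname grn_io
#' @export
write_literature_edges <- function(x, path) {
  utils::write.table(x[c("source", "target", "sign")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_prior_matrix <- function(path) {
  df <- read_tsv_checked(path, "target", "prior matrix")
  regs <- setdiff(names(df), "target")
  m <- as.matrix(df[regs])
  if (!is.numeric(m)) stop_("prior matrix '", path, "': non-numeric entries")
  storage.mode(m) <- "double"
  rownames(m) <- df$target
  bad <- which(!is.na(m) & !m %in% PRIOR_CODES, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("prior matrix '", path, "': illegal code ", m[bad[1L, , drop = FALSE]],
          " at row '", rownames(m)[bad[1L, 1L]], "' (line ", bad[1L, 1L] + 2L,
          "), column '", colnames(m)[bad[1L, 2L]], "'")
  }
  m
}

#' @rdname grn_io
#' @export
write_prior_matrix <- function(x, path) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# prior-knowledge matrix; rows: targets; columns: regulators (+ stimulus); codes: 0 none, 10 activation, -10 inhibition, 1 unknown sign, NA unspecified", con)
  df <- data.frame(target = rownames(x), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
write_model_json <- function(x, path) {
  stopifnot(inherits(x, "grn_model"))
  ed <- model_edges(x)
  obj <- list(
    nodes = data.frame(id = x$nodes, class = unname(x$classes),
                       stringsAsFactors = FALSE),
    input = x$input,
    edges = ed[c("source", "target", "weight", "type")],
    self_decay = as.list(stats::setNames(diag(x$A), x$nodes)),
    metadata = x$metadata[intersect(names(x$metadata),
                                    c("J", "J_fit", "allowed_error",
                                      "selected_allowed_error", "n_edges",
                                      "prior_integrated",
                                      "stability_threshold"))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes$id
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(A) <- unlist(obj$self_decay)[nodes]
  b <- stats::setNames(numeric(n), nodes)
  ed <- obj$edges
  if (!is.null(ed) && NROW(ed)) {
    for (i in seq_len(nrow(ed))) {
      if (ed$type[i] == "input") {
        b[ed$target[i]] <- ed$weight[i]
      } else {
        A[ed$target[i], ed$source[i]] <- ed$weight[i]
      }
    }
  }
  grn_model(A, b, classes = stats::setNames(obj$nodes$class, nodes),
            input = obj$input, metadata = as.list(obj$metadata))
}

#' @rdname grn_io
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, "grn_model"))
  ed <- model_edges(x)
  rel <- ifelse(ed$weight > 0, "activates", "inhibits")
  writeLines(paste(ed$source, rel, ed$target, sep = "\t"), path)
  invisible(path)
}

#' @rdname grn_io
#' @export
write_edge_frequencies <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("source", "target", "type",
                                        "count", "frequency")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
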