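#' Time-series expression-change matrix
#'
#' The central data container of the package: a components-by-times matrix
#' of expression changes between a stimulated and an unstimulated (control)
#' state, usually on the log2 scale before standardisation. Rows are network
#' components (miRNAs, transcription-factor genes, marker genes), columns
#' are sampling times in hours, starting at the moment of stimulation
#' (t = 0).
#'
#' @param values numeric matrix with one named row per component and one
#'   column per time point.
#' @param times numeric vector of sampling times (hours); strictly
#'   increasing, first element 0.
#' @param classes optional named character vector assigning a class
#'   (`"miRNA"`, `"TF"`, `"marker"`, ...) to each component.
#' @param standardized logical; `TRUE` once each row has been centered on
#'   its first value and scaled by its maximum absolute value (see
#'   [standardize_ts()]).
#'
#' @return an object of class `grn_ts` (a numeric matrix with `times`,
#'   `classes` and `standardized` attributes).
#' @seealso [standardize_ts()], [average_replicates()]
#' @export
grn_ts <- function(values, times, classes = NULL, standardized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("expression values must be numeric")
  if (is.null(rownames(values))) stop_("components must be named (rownames)")
  if (anyDuplicated(rownames(values))) stop_("duplicated component ids")
  times <- as.numeric(times)
  if (length(times) == 0L) stop_("empty series")
  if (ncol(values) != length(times)) {
    stop_("number of columns (", ncol(values), ") does not match number of times (",
          length(times), ")")
  }
  if (is.unsorted(times, strictly = TRUE)) stop_("times must be strictly increasing")
  if (times[1L] != 0) stop_("first time point must be 0")
  if (!is.null(classes)) {
    classes <- classes[rownames(values)]
    if (anyNA(names(classes)) || anyNA(classes)) {
      stop_("classes must cover every component")
    }
  }
  colnames(values) <- as.character(times)
  structure(values,
            class = c("grn_ts", "matrix", "array"),
            times = times, classes = classes,
            standardized = isTRUE(standardized))
}

#' @export
print.grn_ts <- function(x, ...) {
  cat(sprintf("grn_ts: %d components x %d time points (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "unstandardized"))
  print(unclass_ts(x), ...)
  invisible(x)
}

unclass_ts <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' @rdname grn_ts
#' @param x a `grn_ts` object.
#' @export
ts_times <- function(x) attr(x, "times")

#' @rdname grn_ts
#' @export
ts_classes <- function(x) attr(x, "classes")

#' @rdname grn_ts
#' @export
is_standardized <- function(x) isTRUE(attr(x, "standardized"))

#' Subset the components of a time-series matrix
#'
#' Keeps the full time grid; selects rows (components) by name or index.
#'
#' @param x a `grn_ts` object.
#' @param components character or integer vector of components to keep.
#' @return a `grn_ts` with the selected rows.
#' @export
ts_subset <- function(x, components) {
  stopifnot(inherits(x, "grn_ts"))
  m <- unclass_ts(x)[components, , drop = FALSE]
  if (anyNA(m)) stop_("unknown component in subset")
  grn_ts(m, ts_times(x), classes = ts_classes(x)[rownames(m)],
         standardized = is_standardized(x))
}

#' Stack two time-series matrices sharing a time grid
#'
#' Used to combine the miRNA and mRNA matrices into the single matrix the
#' network model consumes.
#'
#' @param ... `grn_ts` objects on the identical time grid.
#' @return a single `grn_ts`.
#' @export
ts_bind <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L, all(vapply(parts, inherits, TRUE, "grn_ts")))
  tms <- lapply(parts, ts_times)
  if (!all(vapply(tms, function(t) isTRUE(all.equal(t, tms[[1L]])), TRUE))) {
    stop_("time grids differ")
  }
  std <- vapply(parts, is_standardized, TRUE)
  if (length(unique(std)) != 1L) stop_("cannot mix standardized and unstandardized matrices")
  cls <- do.call(c, lapply(parts, ts_classes))
  grn_ts(do.call(rbind, lapply(parts, unclass_ts)), tms[[1L]],
         classes = if (!is.null(cls)) cls, standardized = std[1L])
}

#' Raw replicate expression set
#'
#' Validates a long-format table of per-replicate expression changes
#' (stimulated minus control, log2 scale): one row per
#' (component, time, replicate) with columns `component`, `class`, `time`,
#' `replicate`, `value`. Every component must be measured at every time
#' point of its grid (at least one replicate), times must start at 0.
#'
#' @param df a data frame with the columns above.
#' @return the validated data frame, classed `grn_raw`.
#' @export
grn_raw <- function(df) {
  req <- c("component", "class", "time", "replicate", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$component <- as.character(df$component)
  df$class <- as.character(df$class)
  df$time <- as.numeric(df$time)
  df$value <- as.numeric(df$value)
  if (!nrow(df)) stop_("empty expression set")
  if (anyNA(df$value) || anyNA(df$time)) stop_("missing values in expression set")
  times <- sort(unique(df$time))
  if (times[1L] != 0) stop_("first time point must be 0")
  cells <- table(df$component, factor(df$time, levels = times))
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop_("ragged replicate table: component ", rownames(cells)[bad[1L]],
          " has no replicate at t = ", colnames(cells)[bad[2L]])
  }
  cls <- tapply(df$class, df$component, function(z) unique(z))
  if (any(lengths(cls) != 1L)) stop_("inconsistent class labels within a component")
  structure(df, class = c("grn_raw", "data.frame"))
}

#' Average replicates into a time-series matrix
#'
#' Arithmetic mean of the replicate values at each (component, time) cell,
#' in the spirit of averaging microarray replicates before modelling.
#'
#' @param raw a [grn_raw()] replicate set.
#' @return an unstandardized [grn_ts()] (components in order of first
#'   appearance, times sorted).
#' @export
average_replicates <- function(raw) {
  raw <- grn_raw(raw)
  comps <- unique(raw$component)
  times <- sort(unique(raw$time))
  m <- tapply(raw$value, list(factor(raw$component, levels = comps),
                              factor(raw$time, levels = times)), mean)
  m <- matrix(m, nrow = length(comps), dimnames = list(comps, as.character(times)))
  classes <- vapply(split(raw$class, factor(raw$component, levels = comps)),
                    function(z) z[[1L]], "")
  grn_ts(m, times, classes = classes, standardized = FALSE)
}

#' Standardize a time-series matrix
#'
#' Two-step per-component standardisation used before dynamic modelling:
#' the first value is subtracted from the series (so every trajectory
#' starts at 0, the unstimulated reference), and the centered series is
#' divided by its maximum absolute value, so values vary within -1 and 1.
#' A constant series has no dynamic information and maps to all zeros
#' rather than raising an error. The operation is idempotent.
#'
#' @param ts a [grn_ts()] matrix.
#' @return the standardized `grn_ts`.
#' @export
standardize_ts <- function(ts) {
  stopifnot(inherits(ts, "grn_ts"))
  if (ncol(ts) == 0L) stop_("empty series")
  m <- unclass_ts(ts)
  m <- m - m[, 1L]
  mx <- apply(abs(m), 1L, max)
  scale <- ifelse(mx > 0, mx, 1)
  m <- m / scale
  m[mx == 0, ] <- 0
  grn_ts(m, ts_times(ts), classes = ts_classes(ts), standardized = TRUE)
}
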