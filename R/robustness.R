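#' Perturb a standardized time-series matrix with Gaussian noise
#'
#' Adds i.i.d. Gaussian noise (mean 0, standard deviation `sd`) to every
#' non-initial entry -- the initial value is the unstimulated reference and
#' stays 0 -- and re-standardizes so the model contract (first value 0,
#' max |x| = 1) still holds. Uses the ambient RNG state; seed outside for
#' reproducibility.
#'
#' @param data standardized [grn_ts()].
#' @param sd noise standard deviation on the standardized scale
#'   (default 0.05).
#' @param restandardize set `FALSE` to inspect the raw perturbation (used
#'   for calibration checks).
#' @return a perturbed [grn_ts()].
#' @export
perturb_data <- function(data, sd = 0.05, restandardize = TRUE) {
  stopifnot(inherits(data, "grn_ts"), is_scalar_num(sd), sd >= 0)
  if (!is_standardized(data)) stop_("data must be standardized")
  m <- unclass_ts(data)
  if (sd > 0 && ncol(m) > 1L) {
    noise <- matrix(stats::rnorm(nrow(m) * (ncol(m) - 1L), 0, sd),
                    nrow(m), ncol(m) - 1L)
    m[, -1L] <- m[, -1L] + noise
  }
  out <- grn_ts(m, ts_times(data), classes = ts_classes(data),
                standardized = FALSE)
  if (restandardize) standardize_ts(out) else out
}

#' Edge occurrence frequencies under noise resampling
#'
#' Validates a reference model by repeatedly perturbing the time-series
#' data ([perturb_data()]), re-running the inference, and recording how
#' often each connection of the reference model is recovered. By default a
#' connection counts as recovered when it is inferred with the same
#' direction and sign; set `match_sign = FALSE` to require presence only.
#' Runs whose inference fails are excluded from the denominator with a
#' warning.
#'
#' @param data standardized [grn_ts()] (standardized internally if not).
#' @param prior optional prior-knowledge matrix passed to
#'   [infer_network()].
#' @param config an [inference_config()].
#' @param reference the [grn_model()] whose connections are scored.
#' @param n_runs number of resampling runs (>= 1; 100 in the emulated
#'   protocol).
#' @param sd perturbation standard deviation (0.05 in the emulated
#'   protocol).
#' @param seed integer master seed for the noise draws.
#' @param match_sign require sign agreement for a connection to count.
#' @param input a [step_input()].
#' @return data frame of class `edge_freq` with columns `source`, `target`,
#'   `type`, `count`, `frequency`; attributes `n_runs` (effective run
#'   count) and `runs` (per-run edge lists, for auditing).
#' @export
edge_frequencies <- function(data, prior = NULL, config = inference_config(),
                             reference, n_runs = 100L, sd = 0.05, seed = 1L,
                             match_sign = TRUE, input = step_input()) {
  stopifnot(inherits(reference, "grn_model"), is_count(n_runs), n_runs >= 1L)
  if (!is_standardized(data)) data <- standardize_ts(data)
  ref_edges <- model_edges(reference)
  seeds <- derive_seeds(seed, n_runs)
  run_edges <- vector("list", n_runs)
  failed <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    pert <- perturb_data(data, sd = sd)
    fit <- tryCatch(infer_network(pert, prior = prior, config = config,
                                  input = input),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    run_edges[[r]] <- model_edges(fit)
  }
  if (failed > 0L) warn_(failed, " of ", n_runs, " resampling runs failed")
  eff_runs <- as.integer(n_runs) - failed
  key <- function(e, signed) {
    if (signed) paste(e$source, e$target, sign(e$weight)) else
      paste(e$source, e$target)
  }
  ref_keys <- key(ref_edges, match_sign)
  counts <- integer(nrow(ref_edges))
  for (re in run_edges) {
    if (is.null(re)) next
    counts <- counts + as.integer(ref_keys %in% key(re, match_sign))
  }
  out <- data.frame(source = ref_edges$source, target = ref_edges$target,
                    type = ref_edges$type, count = counts,
                    frequency = if (eff_runs > 0) counts / eff_runs else NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("edge_freq", "data.frame"),
            n_runs = eff_runs, runs = run_edges)
}

#' Prune unstable connections and refit
#'
#' Removes the connections of a model whose resampling frequency falls
#' below the stability threshold (default 0.5: connections re-inferred in
#' at least half the runs are considered stable and reliable), then
#' re-estimates the parameters of the surviving structure on the
#' unperturbed data (fixed regulator sets, no further structure search).
#'
#' @param model the reference [grn_model()].
#' @param freqs an [edge_frequencies()] table covering every model
#'   connection.
#' @param data standardized [grn_ts()] used for the refit.
#' @param threshold stability threshold in `[0, 1]`; connections with
#'   frequency strictly below it are discarded.
#' @param input a [step_input()].
#' @param config an [inference_config()] (decay profiling range).
#' @return the pruned, refitted [grn_model()]; `metadata$pruned_edges`
#'   lists the removed connections.
#' @export
prune_unstable <- function(model, freqs, data, threshold = 0.5,
                           input = step_input(), config = inference_config()) {
  stopifnot(inherits(model, "grn_model"), is_scalar_num(threshold))
  if (!is_standardized(data)) data <- standardize_ts(data)
  ed <- model_edges(model)
  fkey <- paste(freqs$source, freqs$target)
  ekey <- paste(ed$source, ed$target)
  miss <- setdiff(ekey, fkey)
  if (length(miss)) {
    stop_("missing frequency for connection(s): ", paste(miss, collapse = "; "))
  }
  ed$frequency <- freqs$frequency[match(ekey, fkey)]
  keep <- ed[ed$frequency >= threshold, , drop = FALSE]
  dropped <- ed[ed$frequency < threshold, , drop = FALSE]
  nodes <- model$nodes
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  b <- stats::setNames(numeric(length(nodes)), nodes)
  errs <- stats::setNames(numeric(length(nodes)), nodes)
  for (nd in nodes) {
    regs <- keep$source[keep$target == nd]
    fit <- fit_parameters(nd, regs, data, input = input, config = config)
    A[nd, nd] <- fit$self
    if (length(fit$coefficients)) A[nd, names(fit$coefficients)] <- fit$coefficients
    b[nd] <- fit$b
    errs[nd] <- fit$e
  }
  out <- grn_model(A, b, classes = model$classes, input = model$input,
                   metadata = model$metadata)
  out$metadata$pruned_edges <- dropped[c("source", "target", "frequency")]
  out$metadata$stability_threshold <- threshold
  out$metadata$J_fit <- mean(errs)
  out$metadata$n_edges <- n_edges(out)
  out$metadata$J <- tryCatch(
    model_error(simulate_grn(out, ts_times(data), input = input), data),
    error = function(e) Inf)
  out
}
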