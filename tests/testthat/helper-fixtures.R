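# Shared fixtures and independent oracles, all built in code.

paper_times <- c(0, 3, 6, 12, 24, 48, 72, 120, 192)

# small handcrafted two-node repression motif: stimulus -> TF, miRNA -| TF
motif_model <- function() {
  A <- matrix(c(-0.05, 0,
                -0.08, -0.06), 2, 2, byrow = TRUE,
              dimnames = list(c("miR01", "TF01"), c("miR01", "TF01")))
  grn_model(A, b = c(miR01 = 0.1, TF01 = 0.12),
            classes = c(miR01 = "miRNA", TF01 = "TF"))
}

# random stable model for property loops: negative-dominant diagonal
random_stable_model <- function(n, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  A <- matrix(stats::runif(n * n, -0.04, 0.04), n, n,
              dimnames = list(nodes, nodes))
  diag(A) <- -stats::runif(n, 0.05, 0.2)
  ev <- max(Re(eigen(A, only.values = TRUE)$values))
  if (ev >= -1e-3) diag(A) <- diag(A) - (ev + 0.05)
  b <- stats::setNames(stats::runif(n, -0.1, 0.1), nodes)
  grn_model(A, b)
}

# long-format replicate table from a value array [component, time, replicate]
long_from_array <- function(vals, times, classes) {
  comps <- dimnames(vals)[[1]]
  rows <- expand.grid(component = comps, time = times,
                      replicate = seq_len(dim(vals)[3]),
                      stringsAsFactors = FALSE)
  rows$class <- classes[rows$component]
  rows$value <- vals[cbind(match(rows$component, comps),
                           match(rows$time, times), rows$replicate)]
  grn_raw(rows[c("component", "class", "time", "replicate", "value")])
}

# independent oracle: Pearson correlation from the covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# standardized data bundle for inference tests
standardized_synth_data <- function(net, noise_sd = 0, seed = 1) {
  truth <- ground_truth(net, noise_sd = noise_sd, seed = seed)
  ds <- simulate_dataset(truth)
  parts <- Filter(Negate(is.null),
                  list(if (!is.null(ds$mirna)) average_replicates(ds$mirna),
                       if (!is.null(ds$mrna)) average_replicates(ds$mrna)))
  ts <- standardize_ts(do.call(ts_bind, parts))
  ts <- ts_subset(ts, net$nodes)
  attr(ts, "classes") <- net$classes
  ts
}
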