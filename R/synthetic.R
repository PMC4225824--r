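#' Sample a ground-truth sparse regulatory network
#'
#' Draws a random, stable, class-consistent sparse linear-ODE network over
#' miRNA, transcription-factor (TF) and marker-gene nodes, mirroring the
#' shape of an 11-node chondrogenesis network (4 miRNAs, 4 TFs, 3 markers,
#' ~19 interactions). Class rules: marker genes are pure targets (they
#' regulate nothing); every outgoing miRNA interaction is inhibitory
#' (miRNAs act by degrading their target mRNAs); TF interactions carry
#' either sign. Every node receives a negative intrinsic self-decay term so
#' step responses saturate, and the interaction matrix is resampled /
#' diagonally shifted until all eigenvalues have negative real part.
#' Networks are resampled until every node is reachable from the stimulus,
#' so all components actually respond to the treatment.
#'
#' @param n_mirna,n_tf,n_marker node counts per class.
#' @param density fraction of admissible regulator-target pairs realised as
#'   node-to-node interactions (admissible: regulator is a miRNA or TF,
#'   target is any other node). The default gives ~13 node-to-node
#'   interactions on an 11-node network.
#' @param seed integer seed; the draw is fully seed-deterministic.
#' @param n_input number of stimulus-to-node input interactions (default
#'   `max(1, round(0.55 * n))`, ~6 of 11 nodes).
#' @param edge_cap maximum number of interactions (input + node-to-node);
#'   default `2 * n`.
#' @param decay_range range of self-decay magnitudes (per hour). The
#'   default spans time constants of roughly 10-50 h, matching saturation
#'   within a 192 h sampling window.
#' @param weight_range range of interaction-weight magnitudes (per hour).
#' @param input_range range of input-weight magnitudes (per hour).
#' @param response_scale typical log2 response amplitude: input weights are
#'   rescaled so the median steady-state |x| of responding nodes equals
#'   this (2 = a 4-fold change), so simulated components clear a 2-fold
#'   differential-expression filter.
#' @return a [grn_model()] with `metadata$truth = TRUE`.
#' @export
sample_network <- function(n_mirna, n_tf, n_marker, density = 13 / 80,
                           seed = 1L, n_input = NULL, edge_cap = NULL,
                           decay_range = c(0.02, 0.1),
                           weight_range = c(0.02, 0.08),
                           input_range = c(0.05, 0.15),
                           response_scale = 2) {
  stopifnot(is_count(n_mirna), is_count(n_tf), is_count(n_marker),
            is_scalar_num(density), density > 0, density <= 1)
  n <- n_mirna + n_tf + n_marker
  if (n == 0L) stop_("empty network")
  nodes <- c(if (n_mirna) sprintf("miR%02d", seq_len(n_mirna)),
             if (n_tf) sprintf("TF%02d", seq_len(n_tf)),
             if (n_marker) sprintf("MG%02d", seq_len(n_marker)))
  classes <- stats::setNames(rep(c("miRNA", "TF", "marker"),
                                 c(n_mirna, n_tf, n_marker)), nodes)
  regulators <- nodes[classes != "marker"]
  pairs <- expand.grid(source = regulators, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  n_input <- n_input %||% max(1L, round(0.55 * n))
  stopifnot(is_count(n_input), n_input >= 1L, n_input <= n)
  edge_cap <- edge_cap %||% (2L * n)
  n_off <- min(round(density * nrow(pairs)), max(0L, edge_cap - n_input))

  set.seed(seed)
  for (try in seq_len(200L)) {
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    diag(A) <- -stats::runif(n, decay_range[1L], decay_range[2L])
    if (n_off > 0 && nrow(pairs) > 0) {
      pick <- pairs[sample.int(nrow(pairs), min(n_off, nrow(pairs))), ,
                    drop = FALSE]
      w <- stats::runif(nrow(pick), weight_range[1L], weight_range[2L])
      sgn <- ifelse(classes[pick$source] == "miRNA", -1,
                    sample(c(-1, 1), nrow(pick), replace = TRUE))
      A[cbind(match(pick$target, nodes), match(pick$source, nodes))] <- sgn * w
    }
    b <- numeric(n)
    hit <- sample.int(n, n_input)
    b[hit] <- sample(c(-1, 1), n_input, replace = TRUE) *
      stats::runif(n_input, input_range[1L], input_range[2L])
    names(b) <- nodes
    # stabilise: shift the diagonal if any eigenvalue strays right
    ev <- max(Re(eigen(A, only.values = TRUE)$values))
    if (ev >= -1e-4) diag(A) <- diag(A) - (ev + 0.01)
    if (all_reachable(A, b)) break
    if (try == 200L) stop_("could not sample a stimulus-connected network")
  }

  model <- grn_model(A, b, classes = classes,
                     metadata = list(truth = TRUE, seed = seed))
  if (is.finite(response_scale) && response_scale > 0) {
    xstar <- tryCatch(as.numeric(solve(A, -b)), error = function(e) b)
    amp <- stats::median(abs(xstar[xstar != 0]))
    if (is.finite(amp) && amp > 0) model$b <- b * response_scale / amp
  }
  model
}

# every node reachable from the stimulus through b and A
all_reachable <- function(A, b) {
  n <- nrow(A)
  reach <- b != 0
  repeat {
    new <- reach | (abs(A[, reach, drop = FALSE]) %*% rep(1, sum(reach)) > 0)
    new <- as.vector(new) | reach
    if (all(new == reach)) break
    reach <- new
  }
  all(reach)
}

#' Ground-truth study conditions
#'
#' Bundles a true network with the sampling design of the emulated
#' experiment: 9 sampling times over 192 h, 3 replicates per time point for
#' mRNA components and 2 for miRNAs, and Gaussian replicate noise of
#' standard deviation 0.05 on the standardized scale.
#'
#' @param network a true [grn_model()].
#' @param times sampling times (h), starting at 0.
#' @param noise_sd replicate noise standard deviation in standardized
#'   units (applied to each series relative to its own amplitude).
#' @param replicates_mrna,replicates_mirna replicate counts per time point.
#' @param seed integer seed for the noise draw.
#' @return an object of class `grn_truth`.
#' @export
ground_truth <- function(network, times = c(0, 3, 6, 12, 24, 48, 72, 120, 192),
                         noise_sd = 0.05, replicates_mrna = 3L,
                         replicates_mirna = 2L, seed = 1L) {
  stopifnot(inherits(network, "grn_model"), noise_sd >= 0,
            is_count(replicates_mrna), replicates_mrna >= 1L,
            is_count(replicates_mirna), replicates_mirna >= 1L)
  times <- as.numeric(times)
  if (times[1L] != 0) stop_("times must start at 0")
  structure(list(network = network, times = times, noise_sd = noise_sd,
                 replicates_mrna = replicates_mrna,
                 replicates_mirna = replicates_mirna, seed = seed),
            class = "grn_truth")
}

#' Simulate a replicate expression dataset from a ground truth
#'
#' Forward-simulates the true ODE network under a unit step stimulus and
#' emits raw replicate tables: the noiseless trajectory plus i.i.d.
#' Gaussian noise per replicate. Noise is calibrated on the standardized
#' scale: each component's noise standard deviation is
#' `noise_sd * max|trajectory|`, so after standardisation the perturbation
#' has the nominal magnitude. Trajectories start at 0
#' (stimulated-minus-control encoding). Identical seeds reproduce the
#' tables exactly.
#'
#' @param truth a [ground_truth()].
#' @param input stimulus, default unit step at 0.
#' @return list with elements `mirna` and `mrna` ([grn_raw()] long tables,
#'   classes `"miRNA"` and `"gene"`), and `trajectories` (the noiseless
#'   [grn_ts()]).
#' @export
simulate_dataset <- function(truth, input = step_input()) {
  stopifnot(inherits(truth, "grn_truth"))
  traj <- tryCatch(
    simulate_grn(truth$network, truth$times, input = input),
    error = function(e) stop_("divergent simulation: ", conditionMessage(e)))
  classes <- truth$network$classes
  set.seed(truth$seed)
  emit <- function(ids, n_rep, label) {
    if (!length(ids)) return(NULL)
    rows <- expand.grid(replicate = seq_len(n_rep), time = truth$times,
                        component = ids, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    base <- unclass_ts(traj)[cbind(match(rows$component, rownames(traj)),
                                   match(rows$time, ts_times(traj)))]
    sds <- apply(abs(unclass_ts(traj)), 1L, max)
    sds <- ifelse(sds > 0, sds, 1) * truth$noise_sd
    noise <- if (truth$noise_sd > 0) {
      stats::rnorm(nrow(rows), 0, sds[rows$component])
    } else 0
    grn_raw(data.frame(component = rows$component, class = label,
                       time = rows$time, replicate = rows$replicate,
                       value = base + noise, stringsAsFactors = FALSE))
  }
  mirna_ids <- names(classes)[classes == "miRNA"]
  mrna_ids <- names(classes)[classes != "miRNA"]
  list(mirna = emit(mirna_ids, truth$replicates_mirna, "miRNA"),
       mrna = emit(mrna_ids, truth$replicates_mrna, "gene"),
       trajectories = traj)
}

#' Emit a miRNA target-prediction table from a true network
#'
#' Emulates the union of several target-prediction databases: every true
#' miRNA-to-gene interaction of the network is recorded in at least two
#' randomly chosen databases (so a two-database filter has perfect recall
#' on true interactions by construction), while `n_decoys` non-interacting
#' (miRNA, gene) pairs are recorded in 1 to k databases, emulating the low
#' specificity of sequence-based predictions.
#'
#' @param network true [grn_model()].
#' @param n_decoys number of decoy pairs (>= 0).
#' @param databases database names (>= 2).
#' @param seed integer seed.
#' @return data frame with columns `miRNA`, `gene`, `database` (no
#'   duplicate triples).
#' @export
emit_prediction_table <- function(network, n_decoys = 50L,
                                  databases = c("tarbase", "miranda", "mirbase",
                                                "mirtarget2", "targetscan"),
                                  seed = 1L) {
  stopifnot(inherits(network, "grn_model"), length(databases) >= 2L)
  if (!is_count(n_decoys)) stop_("n_decoys must be a non-negative count")
  classes <- network$classes
  mirnas <- names(classes)[classes == "miRNA"]
  genes <- names(classes)[classes != "miRNA"]
  ed <- model_edges(network)
  true_pairs <- ed[ed$type == "node" & classes[ed$source] == "miRNA" &
                     classes[ed$target] != "miRNA", c("source", "target")]
  set.seed(seed)
  rows <- list()
  if (nrow(true_pairs)) {
    for (i in seq_len(nrow(true_pairs))) {
      k <- sample(2:length(databases), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        miRNA = true_pairs$source[i], gene = true_pairs$target[i],
        database = sample(databases, k), stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0 && length(mirnas) && length(genes)) {
    all_pairs <- expand.grid(miRNA = mirnas, gene = genes,
                             stringsAsFactors = FALSE)
    is_true <- paste(all_pairs$miRNA, all_pairs$gene) %in%
      paste(true_pairs$source, true_pairs$target)
    decoy_pool <- all_pairs[!is_true, , drop = FALSE]
    n_take <- min(n_decoys, nrow(decoy_pool))
    if (n_take < n_decoys) warn_("only ", n_take, " decoy pairs available")
    if (n_take > 0) {
      pick <- decoy_pool[sample.int(nrow(decoy_pool), n_take), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        k <- sample.int(length(databases), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          miRNA = pick$miRNA[i], gene = pick$gene[i],
          database = sample(databases, k), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(miRNA = character(), gene = character(),
               database = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Emit a prior-knowledge matrix from a true network
#'
#' Encodes a fraction `coverage` of the true interactions with their
#' correct sign (activation 10, inhibition -10) and corrupts a fraction
#' `error_rate` of the encoded entries (sign flip, or relocation to a
#' random false interaction). Marker-gene columns (markers as regulators)
#' are always coded 0 -- markers are pure targets by class knowledge. All
#' remaining entries are NA (not available). Self-decay diagonal terms are
#' intrinsic to the model, not interactions, and stay NA.
#'
#' @param network true [grn_model()].
#' @param coverage,error_rate fractions in `[0, 1]`.
#' @param seed integer seed.
#' @return prior-knowledge matrix (rows = targets, columns = regulators
#'   plus the stimulus) with entries in 0, 10, -10, 1, NA.
#' @export
emit_prior <- function(network, coverage = 1, error_rate = 0, seed = 1L) {
  stopifnot(inherits(network, "grn_model"),
            coverage >= 0, coverage <= 1, error_rate >= 0, error_rate <= 1)
  nodes <- network$nodes
  classes <- network$classes
  prior <- matrix(NA_real_, length(nodes), length(nodes) + 1L,
                  dimnames = list(nodes, c(nodes, network$input)))
  prior[, classes == "marker"] <- 0
  ed <- model_edges(network)
  set.seed(seed)
  n_enc <- round(coverage * nrow(ed))
  if (n_enc > 0) {
    enc <- ed[sample.int(nrow(ed), n_enc), , drop = FALSE]
    for (i in seq_len(nrow(enc))) {
      prior[enc$target[i], enc$source[i]] <- 10 * sign(enc$weight[i])
    }
    n_bad <- round(error_rate * n_enc)
    if (n_bad > 0) {
      bad <- enc[sample.int(nrow(enc), n_bad), , drop = FALSE]
      for (i in seq_len(nrow(bad))) {
        if (stats::runif(1) < 0.5) {                     # sign flip in place
          prior[bad$target[i], bad$source[i]] <-
            -prior[bad$target[i], bad$source[i]]
        } else {                                         # relocate: false edge
          prior[bad$target[i], bad$source[i]] <- NA_real_
          free <- which(is.na(prior), arr.ind = TRUE)
          free <- free[free[, 1L] != free[, 2L], , drop = FALSE]
          if (nrow(free)) {
            j <- free[sample.int(nrow(free), 1L), ]
            prior[j[1L], j[2L]] <- sample(c(-10, 10), 1L)
          }
        }
      }
    }
  }
  prior
}

#' Score edge recovery of an inferred network against the truth
#'
#' Confusion-matrix metrics over interactions (input and node-to-node;
#' intrinsic self-decay terms are present in both models by construction
#' and excluded). Precision is 1 by convention when no interaction was
#' inferred; sign accuracy is computed over correctly recovered
#' interactions only (vacuously 1 when there are none).
#'
#' @param inferred,truth [grn_model()] objects over the same node set.
#' @return list with `precision`, `recall`, `f1`, `sign_accuracy`, `tp`,
#'   `fp`, `fn`.
#' @export
score_recovery <- function(inferred, truth) {
  stopifnot(inherits(inferred, "grn_model"), inherits(truth, "grn_model"))
  if (!setequal(inferred$nodes, truth$nodes)) stop_("node-set mismatch")
  key <- function(e) paste(e$source, e$target, sep = "\r")
  ei <- model_edges(inferred)
  et <- model_edges(truth)
  tp_keys <- intersect(key(ei), key(et))
  tp <- length(tp_keys)
  fp <- nrow(ei) - tp
  fn <- nrow(et) - tp
  precision <- if (nrow(ei) == 0L) 1 else tp / nrow(ei)
  recall <- if (nrow(et) == 0L) 1 else tp / nrow(et)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  sign_acc <- if (tp == 0L) 1 else {
    wi <- ei$weight[match(tp_keys, key(ei))]
    wt <- et$weight[match(tp_keys, key(et))]
    mean(sign(wi) == sign(wt))
  }
  list(precision = precision, recall = recall, f1 = f1,
       sign_accuracy = sign_acc, tp = tp, fp = fp, fn = fn)
}
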