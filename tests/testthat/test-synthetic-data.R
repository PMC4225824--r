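test_that("an empty node set is rejected", {
  expect_error(sample_network(0, 0, 0, density = 0.5), "empty network")
})

test_that("the default-shaped network has 11 nodes and 19 interactions", {
  net <- sample_network(4, 4, 3, density = 13 / 80, n_input = 6, seed = 1)
  expect_length(net$nodes, 11L)
  expect_identical(n_edges(net), 19L)
  cen <- edge_census(net)
  expect_identical(cen$input, 6L)
  expect_identical(cen$node, 13L)
  # markers regulate nothing
  ed <- model_edges(net)
  expect_false(any(net$classes[ed$source[ed$type == "node"]] == "marker"))
  # stable dynamics
  expect_lt(max(Re(eigen(net$A, only.values = TRUE)$values)), 0)
})

test_that("class rules hold under an exhaustive edge scan", {
  for (seed in c(7, 8, 9)) {
    net <- sample_network(1, 1, 0, density = 1, seed = seed)
    A <- net$A
    cls <- net$classes
    for (i in seq_len(nrow(A))) {
      for (j in seq_len(ncol(A))) {
        if (i == j) {
          expect_lt(A[i, j], 0)             # negative self-decay everywhere
        } else if (A[i, j] != 0) {
          expect_false(cls[j] == "marker")  # markers are pure targets
          if (cls[j] == "miRNA") expect_lt(A[i, j], 0)  # miRNAs repress
        }
      }
    }
  }
})

test_that("generators are seed-deterministic", {
  n1 <- sample_network(4, 4, 3, seed = 3)
  n2 <- sample_network(4, 4, 3, seed = 3)
  expect_identical(n1$A, n2$A)
  expect_identical(n1$b, n2$b)
  d1 <- simulate_dataset(ground_truth(n1, noise_sd = 0.05, seed = 11))
  d2 <- simulate_dataset(ground_truth(n2, noise_sd = 0.05, seed = 11))
  expect_identical(d1$mirna$value, d2$mirna$value)
  expect_identical(d1$mrna$value, d2$mrna$value)
  p1 <- emit_prediction_table(n1, n_decoys = 20, seed = 5)
  p2 <- emit_prediction_table(n2, n_decoys = 20, seed = 5)
  expect_identical(p1, p2)
  expect_identical(emit_prior(n1, 0.5, 0.2, seed = 6),
                   emit_prior(n2, 0.5, 0.2, seed = 6))
})

test_that("noiseless replicates equal the ODE trajectory exactly", {
  net <- sample_network(2, 2, 1, seed = 4)
  ds <- simulate_dataset(ground_truth(net, noise_sd = 0))
  traj <- ds$trajectories
  for (tab in list(ds$mirna, ds$mrna)) {
    got <- tab$value
    want <- unclass(traj)[cbind(match(tab$component, rownames(traj)),
                                match(tab$time, ts_times(traj)))]
    expect_equal(got, unname(want))
  }
})

test_that("replicate means converge to the trajectory (law of large numbers)", {
  A <- matrix(-1, 1, 1, dimnames = list("g1", "g1"))
  net <- grn_model(A, b = c(g1 = 1), classes = c(g1 = "TF"))
  times <- c(0, 1, 2, 4)
  truth <- ground_truth(net, times = times, noise_sd = 0.05,
                        replicates_mrna = 1000L, seed = 21)
  ds <- simulate_dataset(truth)
  avg <- average_replicates(ds$mrna)
  closed_form <- 1 - exp(-times)          # x(t) = (b/-a)(1 - e^{at})
  sd_raw <- 0.05 * max(abs(closed_form))
  tol <- 3 * sd_raw / sqrt(1000)
  expect_true(all(abs(unclass(avg)["g1", ] - closed_form) < tol))
})

test_that("an unstable network aborts the simulation", {
  A <- matrix(0.5, 1, 1, dimnames = list("g1", "g1"))
  net <- grn_model(A, b = c(g1 = 1), classes = c(g1 = "TF"))
  truth <- ground_truth(net, times = c(0, 10, 20, 40, 80, 160), noise_sd = 0)
  expect_error(simulate_dataset(truth), "divergent simulation")
})

test_that("prediction tables contain every true miRNA-target pair in >= 2 databases", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 2)
  tab <- emit_prediction_table(net, n_decoys = 0, seed = 9)
  ed <- model_edges(net)
  true_pairs <- ed[ed$type == "node" & net$classes[ed$source] == "miRNA" &
                     net$classes[ed$target] != "miRNA", ]
  expect_setequal(paste(tab$miRNA, tab$gene),
                  paste(true_pairs$source, true_pairs$target))
  per_pair <- table(paste(tab$miRNA, tab$gene))
  expect_true(all(per_pair >= 2))
  expect_false(anyDuplicated(tab) > 0)
})

test_that("a network without miRNA targets yields a decoy-only table", {
  net <- sample_network(2, 2, 1, density = 0.2, seed = 30)
  # strip all miRNA-outgoing interactions
  net$A[, net$nodes[net$classes == "miRNA"]] <- 0
  diag(net$A) <- -0.05
  tab <- emit_prediction_table(net, n_decoys = 5, seed = 3)
  expect_true(nrow(tab) >= 5)
  ed <- model_edges(net)
  expect_false(any(paste(tab$miRNA, tab$gene) %in% paste(ed$source, ed$target)))
})

test_that("a two-database filter recovers all true pairs; decoy leak-through is countable", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 2)
  tab <- emit_prediction_table(net, n_decoys = 20, seed = 13)
  hits <- candidate_targets(tab, min_db = 2)
  ed <- model_edges(net)
  true_keys <- paste(ed$source, ed$target)[ed$type == "node" &
                                           net$classes[ed$source] == "miRNA" &
                                           net$classes[ed$target] != "miRNA"]
  expect_true(all(true_keys %in% paste(hits$miRNA, hits$gene)))
  # brute-force leak-through count from the emitted table itself
  keys <- paste(tab$miRNA, tab$gene)
  n_db <- vapply(split(tab$database, keys),
                 function(d) length(unique(d)), 0L)
  decoy_keys <- setdiff(names(n_db), true_keys)
  leak <- sum(n_db[decoy_keys] >= 2)
  got_decoys <- sum(!paste(hits$miRNA, hits$gene) %in% true_keys)
  expect_identical(got_decoys, leak)
})

test_that("full-coverage error-free priors match the truth on encoded entries", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 6)
  prior <- emit_prior(net, coverage = 1, error_rate = 0, seed = 1)
  ed <- model_edges(net)
  for (i in seq_len(nrow(ed))) {
    expect_identical(unname(prior[ed$target[i], ed$source[i]]),
                     10 * sign(ed$weight[i]))
  }
  # non-edge, non-marker-column entries are NA
  marker_cols <- net$nodes[net$classes == "marker"]
  off <- prior
  off[cbind(ed$target, ed$source)] <- NA
  off <- off[, setdiff(colnames(off), marker_cols)]
  expect_true(all(is.na(off) | row(off) == 0))
})

test_that("zero coverage encodes nothing except class knowledge", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 6)
  prior <- emit_prior(net, coverage = 0, seed = 1)
  marker_cols <- net$nodes[net$classes == "marker"]
  expect_true(all(prior[, marker_cols] == 0))
  expect_true(all(is.na(prior[, setdiff(colnames(prior), marker_cols)])))
})

test_that("corrupted prior entries are countable by brute force", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 6)
  prior <- emit_prior(net, coverage = 0.5, error_rate = 0.2, seed = 17)
  ed <- model_edges(net)
  truth_code <- matrix(NA_real_, length(net$nodes), length(net$nodes) + 1L,
                       dimnames = dimnames(prior))
  truth_code[cbind(ed$target, ed$source)] <- 10 * sign(ed$weight)
  marker_cols <- net$nodes[net$classes == "marker"]
  signed <- !is.na(prior) & prior != 0
  signed[, marker_cols] <- FALSE
  # entries disagreeing with the truth (wrong sign or false edge)
  bad <- sum(signed & (is.na(truth_code) | truth_code != prior))
  n_enc <- round(0.5 * nrow(ed))
  n_corrupt <- round(0.2 * n_enc)
  # each corruption perturbs at most one encoded entry plus one false edge
  expect_lte(bad, 2 * n_corrupt)
  expect_gte(bad, 1)
  # encoded count is close to the nominal number (relocations can reduce it)
  expect_lte(abs(sum(signed) - n_enc), n_corrupt)
})

test_that("recovery scoring equals brute-force confusion counts", {
  net <- sample_network(4, 4, 3, density = 13 / 80, seed = 2)
  expect_equal(score_recovery(net, net)[c("precision", "recall", "f1",
                                          "sign_accuracy")],
               list(precision = 1, recall = 1, f1 = 1, sign_accuracy = 1))

  empty <- grn_model(matrix(0, 11, 11,
                            dimnames = list(net$nodes, net$nodes)),
                     b = 0, classes = net$classes)
  sc <- score_recovery(empty, net)
  expect_identical(sc$precision, 1)     # convention: no false positives
  expect_identical(sc$recall, 0)

  # random 3-node comparison against hand-counted confusion entries
  set.seed(99)
  nodes <- c("a", "b", "c")
  mk <- function() {
    A <- matrix(sample(c(-1, 0, 1), 9, replace = TRUE), 3, 3,
                dimnames = list(nodes, nodes))
    diag(A) <- -1
    grn_model(A, b = stats::setNames(sample(c(-1, 0, 1), 3, TRUE), nodes))
  }
  for (rep in 1:10) {
    m1 <- mk(); m2 <- mk()
    sc <- score_recovery(m1, m2)
    tp <- fp <- 0; sign_hits <- 0
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      if (m1$A[i, j] != 0) {
        if (m2$A[i, j] != 0) {
          tp <- tp + 1
          sign_hits <- sign_hits + (sign(m1$A[i, j]) == sign(m2$A[i, j]))
        } else fp <- fp + 1
      }
    }
    for (i in 1:3) {
      if (m1$b[i] != 0) {
        if (m2$b[i] != 0) {
          tp <- tp + 1
          sign_hits <- sign_hits + (sign(m1$b[i]) == sign(m2$b[i]))
        } else fp <- fp + 1
      }
    }
    fn <- n_edges(m2) - tp
    expect_identical(sc$tp, as.integer(tp))
    expect_identical(sc$fp, as.integer(fp))
    expect_identical(sc$fn, as.integer(fn))
    if (tp > 0) expect_equal(sc$sign_accuracy, unname(sign_hits) / tp)
  }
  expect_error(score_recovery(net, mk()), "node-set mismatch")
})

test_that("noiseless data refit with the true structure recovers the parameters", {
  net <- sample_network(3, 3, 2, density = 0.25, seed = 12)
  ts <- standardized_synth_data(net, noise_sd = 0)
  # the standardized system is D^-1 A D with input D^-1 b (D = row scales)
  traj <- simulate_grn(net, paper_times)
  s <- apply(abs(unclass(traj)), 1, max)[net$nodes]
  A_t <- diag(1 / s) %*% net$A %*% diag(s)
  dimnames(A_t) <- dimnames(net$A)
  b_t <- net$b / s
  cfg <- inference_config()
  rts <- mirdynet:::spline_refine(ts, 10)
  for (nd in net$nodes) {
    regs <- colnames(A_t)[A_t[nd, ] != 0 & colnames(A_t) != nd]
    if (b_t[nd] != 0) regs <- c(regs, "stimulus")
    fit <- suppressWarnings(
      fit_parameters(nd, regs, ts, config = cfg, regressor_ts = rts))
    expect_lt(abs(fit$self - A_t[nd, nd]), 1e-3)
    for (r in setdiff(regs, "stimulus")) {
      expect_lt(abs(fit$coefficients[[r]] - A_t[nd, r]), 1e-3)
    }
    if (b_t[nd] != 0) expect_lt(abs(fit$b - b_t[nd]), 1e-3)
    expect_lt(fit$e, 1e-4)
  }
})
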