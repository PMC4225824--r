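#' Linear-ODE gene regulatory network model
#'
#' A network over N components whose expression changes x_i(t) follow
#' \deqn{\dot x_i(t) = \sum_j a_{ij} x_j(t) + b_i u(t)}
#' where `A = (a_ij)` holds the interaction weights (effect of regulator j
#' on target i, per hour), `b` the input weights of the external stimulus
#' u(t), and a positive weight denotes activation, a negative weight
#' inhibition, zero no connection. The diagonal `a_ii` is interpreted as an
#' intrinsic self-decay/self-regulation term and is not counted as a
#' network interaction (see [edge_census()]).
#'
#' @param A numeric N x N matrix, rows = targets, columns = regulators,
#'   with identical row and column names (the node ids).
#' @param b numeric vector of input weights, one per node (recycled scalar
#'   0 allowed); names must match the nodes.
#' @param classes named character vector of node classes
#'   (`"miRNA"`, `"TF"`, `"marker"`).
#' @param input name of the external stimulus (default `"stimulus"`).
#' @param metadata free-form list (fit error J, allowedError used, ...).
#' @return an object of class `grn_model`.
#' @export
grn_model <- function(A, b = NULL, classes = NULL, input = "stimulus",
                      metadata = list()) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A)) stop_("A must be square")
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
  }
  if (!identical(rownames(A), colnames(A))) stop_("row/column names of A differ")
  nodes <- rownames(A)
  if (is.null(b)) b <- numeric(n)
  if (length(b) == 1L) b <- rep(b, n)
  if (is.null(names(b))) names(b) <- nodes
  b <- b[nodes]
  if (anyNA(b)) stop_("input weights must cover every node")
  if (!all(is.finite(A)) || !all(is.finite(b))) stop_("non-finite model parameters")
  if (is.null(classes)) {
    classes <- stats::setNames(rep("gene", n), nodes)
  } else {
    classes <- classes[nodes]
    if (anyNA(classes)) stop_("classes must cover every node")
  }
  structure(list(nodes = nodes, classes = classes, A = A, b = b,
                 input = input, metadata = metadata),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cen <- edge_census(x)
  cat(sprintf("grn_model: %d nodes (%s), %d interactions (%d input, %d node-node), %d self-decay terms\n",
              length(x$nodes),
              paste(sprintf("%d %s", table(x$classes), names(table(x$classes))),
                    collapse = ", "),
              cen$total, cen$input, cen$node, cen$self))
  if (!is.null(x$metadata$J)) cat(sprintf("model error J = %.4g\n", x$metadata$J))
  invisible(x)
}

#' Interaction edges of a model
#'
#' Enumerates the network interactions: nonzero off-diagonal entries of A
#' (node-to-node) and nonzero entries of b (input-to-node). Self-decay
#' diagonal terms are not edges.
#'
#' @param model a [grn_model()].
#' @return data frame with columns `source`, `target`, `weight`, `type`
#'   (`"node"` or `"input"`).
#' @export
model_edges <- function(model) {
  stopifnot(inherits(model, "grn_model"))
  A <- model$A
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  node_df <- data.frame(source = colnames(A)[idx[, 2L]],
                        target = rownames(A)[idx[, 1L]],
                        weight = A[idx], type = rep("node", nrow(idx)),
                        stringsAsFactors = FALSE)
  inp <- which(model$b != 0)
  inp_df <- data.frame(source = rep(model$input, length(inp)),
                       target = model$nodes[inp],
                       weight = unname(model$b[inp]),
                       type = rep("input", length(inp)),
                       stringsAsFactors = FALSE)
  # canonical, locale-independent ordering: input edges first (by target
  # node index), then node edges by source index, then target index
  idx_of <- function(x) match(x, model$nodes)
  inp_df <- inp_df[order(idx_of(inp_df$target)), , drop = FALSE]
  node_df <- node_df[order(idx_of(node_df$source), idx_of(node_df$target)), ,
                     drop = FALSE]
  out <- rbind(inp_df, node_df)
  rownames(out) <- NULL
  out
}

#' Number of interactions in a model
#' @inheritParams model_edges
#' @return integer count of input plus node-to-node interactions.
#' @export
n_edges <- function(model) nrow(model_edges(model))

#' Census of model interactions
#'
#' Counts the interactions of a model and groups the node-to-node ones by
#' regulator-class/target-class pair (e.g. `"miRNA->TF"`), the grouping
#' used to summarise inferred chondrogenesis networks. Intrinsic
#' self-decay terms (nonzero diagonal) are not interactions; they are
#' reported separately under `self` and excluded from `total`.
#'
#' @param model a [grn_model()] with classes assigned.
#' @return list with `total`, `input`, `node`, `self`, and `by_class`
#'   (named integer vector over observed class pairs).
#' @export
edge_census <- function(model) {
  stopifnot(inherits(model, "grn_model"))
  ed <- model_edges(model)
  nd <- ed[ed$type == "node", , drop = FALSE]
  pair <- if (nrow(nd)) {
    paste0(model$classes[nd$source], "->", model$classes[nd$target])
  } else character()
  by_class <- if (length(pair)) {
    tab <- table(pair)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  n_self <- sum(diag(model$A) != 0)
  list(total = nrow(ed),
       input = sum(ed$type == "input"),
       node = nrow(nd),
       self = n_self,
       by_class = by_class)
}

#' Stepwise-constant stimulus function
#'
#' The external stimulus u(t) is a stepwise-constant function; the default
#' encodes a sustained treatment switched on at t = 0 (u = 1 for t >= 0,
#' 0 before).
#'
#' @param breaks increasing breakpoint times.
#' @param values value of u on `[breaks[k], breaks[k+1])`.
#' @return an object of class `grn_input`.
#' @export
step_input <- function(breaks = 0, values = 1) {
  breaks <- as.numeric(breaks)
  values <- as.numeric(values)
  stopifnot(length(breaks) == length(values), length(breaks) >= 1L,
            !is.unsorted(breaks, strictly = TRUE), all(is.finite(values)))
  structure(list(breaks = breaks, values = values), class = "grn_input")
}

#' Evaluate a stimulus function
#' @param input a [step_input()].
#' @param t numeric times.
#' @return u(t), 0 before the first breakpoint.
#' @export
input_at <- function(input, t) {
  stopifnot(inherits(input, "grn_input"))
  idx <- findInterval(t, input$breaks)
  out <- c(0, input$values)[idx + 1L]
  out
}

#' Simulate a network model under a step stimulus
#'
#' Solves \eqn{\dot x = A x + b\,u(t)} with x(0) = 0 (trajectories are
#' stimulated-minus-control differences, so the unstimulated state is the
#' origin) and returns the state at the requested times. Within each
#' constant-u segment the default method evaluates the exact
#' matrix-exponential propagator of the augmented system, so no step-size
#' or tolerance tuning is involved; `method = "lsoda"` integrates the same
#' system with a generic stiff solver for cross-checking.
#'
#' @param model a [grn_model()].
#' @param times sorted sampling times starting at 0 (hours).
#' @param input a [step_input()]; default: unit step at t = 0.
#' @param method `"expm"` (exact propagator, default) or `"lsoda"`
#'   (deSolve).
#' @param bound divergence guard: an error is raised if any |x| exceeds it.
#' @return an unstandardized [grn_ts()] of the simulated trajectories.
#' @export
simulate_grn <- function(model, times, input = step_input(),
                         method = c("expm", "lsoda"), bound = 1e6) {
  stopifnot(inherits(model, "grn_model"))
  method <- match.arg(method)
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop_("times must be strictly increasing")
  if (times[1L] != 0) stop_("times must start at 0")
  if (!all(is.finite(model$A)) || !all(is.finite(model$b))) {
    stop_("non-finite model parameters")
  }
  n <- length(model$nodes)
  if (method == "expm") {
    x <- matrix(0, n, length(times), dimnames = list(model$nodes, NULL))
    # split [0, max(t)] at stimulus breakpoints so u is constant per segment
    grid <- sort(unique(c(times, input$breaks[input$breaks >= 0 &
                                              input$breaks <= max(times)])))
    state <- numeric(n)
    keep <- match(times, grid)
    out <- matrix(0, n, length(grid))
    for (k in seq_along(grid)[-1L]) {
      h <- grid[k] - grid[k - 1L]
      u <- input_at(input, grid[k - 1L])
      # augmented propagator handles singular A exactly
      M <- rbind(cbind(model$A, model$b * u), 0)
      P <- as.matrix(Matrix::expm(M * h))
      state <- (P %*% c(state, 1))[seq_len(n)]
      if (!all(is.finite(state)) || max(abs(state)) > bound) {
        stop_("unstable model: simulation diverged")
      }
      out[, k] <- state
    }
    x[] <- out[, keep, drop = FALSE]
  } else {
    deriv <- function(t, y, parms) {
      list(as.vector(model$A %*% y + model$b * input_at(input, t)))
    }
    sol <- deSolve::ode(y = stats::setNames(numeric(n), model$nodes),
                        times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    x <- t(sol[, -1L, drop = FALSE])
    rownames(x) <- model$nodes
    if (!all(is.finite(x)) || max(abs(x)) > bound) {
      stop_("unstable model: simulation diverged")
    }
  }
  grn_ts(x, times, classes = model$classes, standardized = FALSE)
}

#' Per-series simulation error
#'
#' Mean squared deviation between a simulated and a measured series on the
#' standardized scale; the quantity compared against the `allowedError`
#' budget during structure search.
#'
#' @param sim,meas numeric vectors on the same time grid.
#' @return scalar e >= 0, 0 iff the fit is exact.
#' @export
series_error <- function(sim, meas) {
  sim <- as.numeric(sim); meas <- as.numeric(meas)
  if (length(sim) != length(meas)) stop_("time grid mismatch")
  mean((sim - meas)^2)
}

#' Total model error J
#'
#' Aggregates the per-series errors into the model error J: the mean of
#' [series_error()] over components. Components are matched by name, so J
#' is invariant under reordering.
#'
#' @param sim,meas [grn_ts()] matrices over the same components and grid.
#' @return scalar J >= 0.
#' @export
model_error <- function(sim, meas) {
  stopifnot(inherits(sim, "grn_ts"), inherits(meas, "grn_ts"))
  if (!setequal(rownames(sim), rownames(meas))) stop_("component mismatch")
  if (ncol(sim) != ncol(meas)) stop_("time grid mismatch")
  s <- unclass_ts(sim)[rownames(meas), , drop = FALSE]
  m <- unclass_ts(meas)
  mean(vapply(seq_len(nrow(m)),
              function(i) series_error(s[i, ], m[i, ]), 0))
}
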