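#' Teleporting random-walk transition matrix
#'
#' Row-stochastic transition matrix of the random walk with teleportation
#' on a weighted directed graph:
#' `B = lambda * M + (1/N) * ((1 - lambda) * I + lambda * diag(a)) %*% 11'`,
#' where `M = Kout^-1 G` normalises each row of the weight matrix by its
#' out-strength (out-strength set to 1 on dangling nodes), and `a` marks
#' the dangling nodes, which teleport with probability one. Teleportation
#' makes the walk ergodic on directed graphs that are not strongly
#' connected, so the stationary distribution is unique.
#'
#' @param graph a `reaction_graph` (or a non-negative weight matrix).
#' @param lambda probability of following an outgoing edge rather than
#'   teleporting; default 0.85.
#' @return An N x N row-stochastic matrix.
#' @export
transition_matrix <- function(graph, lambda = 0.85) {
  G <- if (inherits(graph, "reaction_graph")) graph$W else as.matrix(graph)
  if (any(G < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  N <- nrow(G)
  kout <- rowSums(G)
  dangling <- kout == 0
  kout[dangling] <- 1
  M <- G / kout
  B <- lambda * M
  shift <- ((1 - lambda) + lambda * dangling) / N
  B + matrix(shift, N, N)
}

#' PageRank centrality of a reaction graph
#'
#' The stationary distribution `pi` of the teleporting random walk: the
#' leading left eigenvector of [transition_matrix()], computed by power
#' iteration. Scores sum to 1; percentiles are reported on a 0-100 scale
#' with average-rank tie handling, so the top node sits at (or near) 100.
#' On graphs with unfolded reversible reactions, each direction node
#' carries its own score.
#'
#' @param graph a `reaction_graph` or non-negative weight matrix.
#' @param lambda teleportation retention probability (default 0.85).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the residual.
#' @return An object of class `pagerank_result`: `scores` (named, sums to
#'   1), `percentiles`, `lambda`.
#' @export
pagerank <- function(graph, lambda = 0.85, tol = 1e-12, max_iter = 1e5) {
  B <- transition_matrix(graph, lambda)
  N <- nrow(B)
  if (N == 0) stop("graph is empty", call. = FALSE)
  ids <- if (inherits(graph, "reaction_graph")) graph$nodes$node_id else
    rownames(B) %||% as.character(seq_len(N))
  x <- rep(1 / N, N)
  tB <- t(B)
  for (it in seq_len(max_iter)) {
    x_new <- as.vector(tB %*% x)
    x_new <- x_new / sum(x_new)
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      pct <- 100 * rank(x, ties.method = "average") / N
      return(structure(list(
        scores = stats::setNames(x, ids),
        percentiles = stats::setNames(pct, ids),
        lambda = lambda, iterations = it), class = "pagerank_result"))
    }
    x <- x_new
  }
  stop("PageRank power iteration did not converge in ", max_iter,
       " iterations; L1 residual ", format(sum(abs(as.vector(tB %*% x) - x))),
       call. = FALSE)
}

#' @export
print.pagerank_result <- function(x, ...) {
  cat("<pagerank_result> ", length(x$scores), " nodes, lambda = ",
      x$lambda, "\n", sep = "")
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top: ", paste(sprintf("%s (%.4f)", names(top), top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Cumulative pathway PageRank
#'
#' Sums node PageRank scores by pathway. The totals sum to 1, so the
#' result reads as the share of random-walk occupation each pathway
#' attracts -- a global measure of pathway importance that shifts with
#' growth conditions when computed on Mass Flow Graphs.
#'
#' @param result a [pagerank()] result.
#' @param subsystem named character vector mapping node id to pathway, or a
#'   `reaction_graph` whose node table carries the labels. Unlabelled nodes
#'   count under `"unassigned"`.
#' @return named numeric vector of cumulative scores, decreasing.
#' @export
pathway_pagerank <- function(result, subsystem) {
  stopifnot(inherits(result, "pagerank_result"))
  if (inherits(subsystem, "reaction_graph")) {
    subsystem <- stats::setNames(subsystem$nodes$subsystem,
                                 subsystem$nodes$node_id)
  }
  lab <- subsystem[names(result$scores)]
  lab <- ifelse(is.na(lab), "unassigned", lab)
  out <- tapply(result$scores, lab, sum)
  sort(stats::setNames(as.numeric(out), names(out)), decreasing = TRUE)
}
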