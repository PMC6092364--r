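#' Unfold a model into forward and backward reaction directions
#'
#' Each reaction is split into a forward and a backward direction column,
#' giving the n x 2m unfolded stoichiometric matrix
#' `S2m = [S, -S diag(r)]` where `r` is the reversibility indicator. The
#' backward columns of irreversible reactions are therefore identically
#' zero. The production and consumption splits are
#' `Splus = (abs(S2m) + S2m) / 2` and `Sminus = (abs(S2m) - S2m) / 2`, and
#' `wplus`/`wminus` are their row totals: the number of molecules of each
#' metabolite produced/consumed across all unfolded reaction columns.
#'
#' @param model a [metabolic_model()].
#' @return An object of class `unfolded_system` with elements `S2m`,
#'   `Splus`, `Sminus`, `wplus`, `wminus`, `nodes` (a data frame with one
#'   row per unfolded column: `node_id`, `reaction`, `direction`), and
#'   `active` (indices of the non-zero columns: all forward columns plus
#'   the backward columns of reversible reactions).
#' @export
unfold <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- model$S
  m <- ncol(S)
  S2m <- cbind(S, -S %*% diag(as.numeric(model$reversible), m, m))
  node_id <- c(model$reaction_ids, paste0(model$reaction_ids, "__rev"))
  colnames(S2m) <- node_id
  Splus <- (abs(S2m) + S2m) / 2
  Sminus <- (abs(S2m) - S2m) / 2
  nodes <- data.frame(
    node_id = node_id,
    reaction = rep(model$reaction_ids, 2),
    direction = rep(c("fwd", "rev"), each = m),
    stringsAsFactors = FALSE)
  structure(list(
    S2m = S2m,
    Splus = Splus,
    Sminus = Sminus,
    wplus = rowSums(Splus),
    wminus = rowSums(Sminus),
    nodes = nodes,
    active = which(colSums(abs(S2m)) > 0)
  ), class = "unfolded_system")
}

#' @export
print.unfolded_system <- function(x, ...) {
  cat("<unfolded_system> ", nrow(x$S2m), " metabolites x ", ncol(x$S2m),
      " direction columns (", length(x$active), " active)\n", sep = "")
  invisible(x)
}

new_reaction_graph <- function(W, nodes, directed, weight_semantics) {
  dimnames(W) <- list(nodes$node_id, nodes$node_id)
  structure(list(W = W, nodes = nodes, directed = directed,
                 weight_semantics = weight_semantics),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat("<reaction_graph> ", nrow(x$W), " nodes, ", n_edges(x),
      if (x$directed) " directed" else " undirected", " edges; weights: ",
      x$weight_semantics, "\n", sep = "")
  invisible(x)
}

#' Count the edges of a reaction graph
#'
#' Non-zero weights are counted; for undirected graphs each unordered pair
#' is counted once and self-loops are included (a self-loop in the Reaction
#' Adjacency Graph records the number of metabolites participating in a
#' reaction).
#'
#' @param graph a `reaction_graph`.
#' @param self_loops include the diagonal (default TRUE).
#' @return integer edge count.
#' @export
n_edges <- function(graph, self_loops = TRUE) {
  W <- graph$W != 0
  if (!graph$directed) W[lower.tri(W)] <- FALSE
  if (!self_loops) diag(W) <- FALSE
  sum(W)
}

node_table <- function(model, sys, idx) {
  nodes <- sys$nodes[idx, , drop = FALSE]
  nodes$subsystem <- if (is.null(model$subsystem)) "unassigned" else {
    s <- unname(model$subsystem[nodes$reaction])
    ifelse(is.na(s), "unassigned", s)
  }
  rownames(nodes) <- NULL
  nodes
}

#' Reaction Adjacency Graph
#'
#' The classical undirected reaction graph `A = t(Shat) %*% Shat`, where
#' `Shat` is the boolean stoichiometric matrix. Two reactions are connected
#' if they share metabolites, either as reactants or products; the diagonal
#' entry of a reaction is the number of metabolites that participate in it.
#' No unfolding is applied: the graph has one node per reaction and is
#' blind to directionality -- it is the baseline the flow graphs improve on.
#'
#' @param model a [metabolic_model()].
#' @return A `reaction_graph` with integer `shared_metabolite_count`
#'   weights.
#' @export
build_rag <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  Shat <- (model$S != 0) * 1
  W <- crossprod(Shat)
  nodes <- data.frame(
    node_id = model$reaction_ids,
    reaction = model$reaction_ids,
    direction = "fwd",
    stringsAsFactors = FALSE)
  nodes$subsystem <- if (is.null(model$subsystem)) "unassigned" else {
    s <- unname(model$subsystem[nodes$reaction]); ifelse(is.na(s), "unassigned", s)
  }
  new_reaction_graph(W, nodes, directed = FALSE,
                     weight_semantics = "shared_metabolite_count")
}

diag_pinv <- function(w) {
  # Moore-Penrose pseudoinverse of a diagonal matrix: reciprocal of the
  # non-zero entries, zero elsewhere
  ifelse(w > 0, 1 / ifelse(w > 0, w, 1), 0)
}

#' Normalised Flow Graph
#'
#' The directed probabilistic blueprint of a metabolic network. The edge
#' weight from reaction direction i to reaction direction j is the
#' probability that a metabolite molecule chosen uniformly at random from
#' the stoichiometric matrix is produced by i and consumed by j:
#' `D[i, j] = (1/n) * sum_k (splus[k, i] / wplus[k]) * (sminus[k, j] / wminus[k])`.
#' Metabolites never produced (or never consumed) contribute nothing, via
#' the pseudoinverse convention on the diagonal weight matrices; when every
#' metabolite is both produced and consumed the weights sum to exactly 1.
#' Pool metabolites (ATP, water, protons, ...) are automatically
#' down-weighted by the `1/(wplus * wminus)` normalisation, without
#' removing them from the network.
#'
#' Backward columns of irreversible reactions are all-zero and dropped, so
#' the node count is m + (number of reversible reactions).
#'
#' @param model a [metabolic_model()].
#' @param threshold weights strictly below this are not materialised
#'   (default 1e-15); documented because it can affect edge counts.
#' @return A directed `reaction_graph` with probability weights.
#' @export
build_nfg <- function(model, threshold = 1e-15) {
  stopifnot(inherits(model, "metabolic_model"))
  sys <- unfold(model)
  n <- nrow(sys$S2m)
  P <- diag_pinv(sys$wplus) * sys$Splus   # rows scaled
  C <- diag_pinv(sys$wminus) * sys$Sminus
  D <- crossprod(P, C) / n
  D[D < threshold] <- 0
  idx <- sys$active
  new_reaction_graph(D[idx, idx, drop = FALSE], node_table(model, sys, idx),
                     directed = TRUE, weight_semantics = "probability")
}

#' Competition and synergy graphs
#'
#' Undirected probabilistic companions of the Normalised Flow Graph. The
#' competition graph weight between two reaction directions is the
#' probability that both consume a metabolite molecule chosen uniformly at
#' random, `Dc = (1/n) t(Sminus) %*% Wminus_pinv^2 %*% Sminus`; the synergy
#' graph is the same construction on the production side.
#'
#' @param model a [metabolic_model()].
#' @param threshold weights strictly below this are dropped.
#' @return A symmetric `reaction_graph` with probability weights.
#' @export
build_competition_graph <- function(model, threshold = 1e-15) {
  build_cs_graph(model, side = "minus", threshold)
}

#' @rdname build_competition_graph
#' @export
build_synergy_graph <- function(model, threshold = 1e-15) {
  build_cs_graph(model, side = "plus", threshold)
}

build_cs_graph <- function(model, side, threshold) {
  stopifnot(inherits(model, "metabolic_model"))
  sys <- unfold(model)
  n <- nrow(sys$S2m)
  Sx <- if (side == "plus") sys$Splus else sys$Sminus
  w <- if (side == "plus") sys$wplus else sys$wminus
  Scaled <- diag_pinv(w) * Sx
  W <- crossprod(Scaled) / n
  W[W < threshold] <- 0
  idx <- sys$active
  new_reaction_graph(W[idx, idx, drop = FALSE], node_table(model, sys, idx),
                     directed = FALSE, weight_semantics = "probability")
}

#' Pairwise metabolite flow between two reaction directions
#'
#' The mass of metabolite `k` produced by unfolded reaction column `i` is
#' distributed among the columns that consume it in proportion to their
#' consumption flux:
#' `flow = (splus[k, i] * v2m[i]) * (sminus[k, j] * v2m[j]) / (total consumption of k)`.
#' When nothing consumes metabolite `k` the flow is zero (pseudoinverse
#' convention).
#'
#' @param k metabolite index (row of the unfolded system).
#' @param i,j unfolded column indices (producer and consumer).
#' @param sys an [unfold()]ed system.
#' @param v2m length-2m non-negative unfolded flux vector.
#' @return flux carried from i to j via metabolite k, in mmol/gDW/h.
#' @export
pairwise_flow <- function(k, i, j, sys, v2m) {
  stopifnot(inherits(sys, "unfolded_system"))
  total <- sum(sys$Sminus[k, ] * v2m)
  if (total <= 0) return(0)
  unname((sys$Splus[k, i] * v2m[i]) * (sys$Sminus[k, j] * v2m[j]) / total)
}

#' Mass Flow Graph
#'
#' The context-specific flow graph computed from a balanced flux vector
#' (typically an FBA optimum). The edge weight from reaction direction i to
#' j is the total mass flow of metabolites produced by i and consumed by j,
#' in mmol/gDW/h, allocating each metabolite's production to its consumers
#' proportionally to their consumption flux:
#' `M = t(Splus V) %*% Jv_pinv %*% (Sminus V)` with `V = diag(v2m)` and
#' `Jv = diag(j)` the metabolite flux. Reaction directions carrying
#' (numerically) zero flux are removed from the node set, so MFGs have
#' fewer nodes than the blueprint graph; self-loops are retained, as they
#' describe the flux of autocatalytic reactions.
#'
#' @param model a [metabolic_model()].
#' @param solution a [flux_solution][solve_fba()], or a bare length-m flux
#'   vector that satisfies `S v = 0`.
#' @param zero_tol relative threshold below which a direction's flux counts
#'   as zero and its node is pruned (default `1e-9 * max(abs(v))`).
#' @param balance_tol relative tolerance on `max(abs(S v))` before the
#'   solution is rejected as unbalanced.
#' @param threshold edge weights strictly below this are dropped.
#' @return A directed `reaction_graph` with `flux_mmol_gDW_h` weights.
#' @export
build_mfg <- function(model, solution, zero_tol = 1e-9,
                      balance_tol = 1e-6, threshold = 1e-15) {
  stopifnot(inherits(model, "metabolic_model"))
  v <- if (inherits(solution, "flux_solution")) solution$v else as.numeric(solution)
  if (length(v) != n_reactions(model)) {
    stop("flux vector length does not match the model", call. = FALSE)
  }
  resid <- abs(model$S %*% v)
  scale <- max(1, abs(v))
  if (max(resid) > balance_tol * scale) {
    worst <- model$metabolite_ids[which.max(resid)]
    stop("flux vector is not balanced: max |S v| = ",
         format(max(resid)), " at metabolite ", worst, call. = FALSE)
  }
  sys <- unfold(model)
  uf <- unfold_fluxes(v, model)
  v2m <- uf$v2m
  jv <- as.vector(sys$Splus %*% v2m)
  Pflux <- sys$Splus * rep(v2m, each = nrow(sys$Splus))    # Splus %*% diag(v2m)
  Cflux <- sys$Sminus * rep(v2m, each = nrow(sys$Sminus))
  M <- crossprod(Pflux, diag_pinv(jv) * Cflux)
  M[M < threshold] <- 0
  keep <- which(v2m > zero_tol * max(abs(v), 1e-300))
  new_reaction_graph(M[keep, keep, drop = FALSE], node_table(model, sys, keep),
                     directed = TRUE, weight_semantics = "flux_mmol_gDW_h")
}

#' Average an ensemble of reaction graphs
#'
#' Edge-wise arithmetic mean over an ensemble of graphs sharing the same
#' weight semantics (e.g. MFGs from many FBA objectives). The node set is
#' the union of the ensembles' node sets; a graph contributes weight 0 for
#' nodes or edges it lacks.
#'
#' @param graphs a list of `reaction_graph`s.
#' @return A `reaction_graph` of the same semantics.
#' @export
average_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1, all(vapply(graphs, inherits, logical(1),
                                            "reaction_graph")))
  sem <- unique(vapply(graphs, function(g) g$weight_semantics, character(1)))
  if (length(sem) != 1) {
    stop("cannot average graphs with mixed weight semantics: ",
         paste(sem, collapse = " vs "), call. = FALSE)
  }
  dir <- unique(vapply(graphs, function(g) g$directed, logical(1)))
  if (length(dir) != 1) stop("cannot average directed with undirected graphs",
                             call. = FALSE)
  all_nodes <- unique(do.call(rbind, lapply(graphs, function(g) g$nodes)))
  all_nodes <- all_nodes[!duplicated(all_nodes$node_id), , drop = FALSE]
  rownames(all_nodes) <- NULL
  N <- nrow(all_nodes)
  W <- matrix(0, N, N, dimnames = list(all_nodes$node_id, all_nodes$node_id))
  for (g in graphs) {
    idx <- match(g$nodes$node_id, all_nodes$node_id)
    W[idx, idx] <- W[idx, idx] + g$W
  }
  new_reaction_graph(W / length(graphs), all_nodes, directed = dir,
                     weight_semantics = sem)
}

#' Convert a reaction graph to an igraph object
#'
#' Node attributes `reaction`, `direction` and `subsystem` and the edge
#' attribute `weight` are carried over.
#'
#' @param graph a `reaction_graph`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  g <- igraph::graph_from_adjacency_matrix(
    graph$W, mode = if (graph$directed) "directed" else "undirected",
    weighted = TRUE, diag = TRUE)
  igraph::V(g)$reaction <- graph$nodes$reaction
  igraph::V(g)$direction <- graph$nodes$direction
  igraph::V(g)$subsystem <- graph$nodes$subsystem
  g
}

#' Write a reaction graph to GraphML or a TSV edge list
#'
#' Weights in the TSV edge list are written with 17 significant digits so
#' they round trip bit-exactly through text.
#'
#' @param graph a `reaction_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(graph, path) {
  idx <- which(graph$W != 0, arr.ind = TRUE)
  if (!graph$directed) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  df <- data.frame(
    from = graph$nodes$node_id[idx[, 1]],
    to = graph$nodes$node_id[idx[, 2]],
    weight = sprintf("%.17g", graph$W[idx]),
    stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
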